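#' Population table
#'
#' Age-band population sizes for one residence stratum, used as the
#' denominators of the reciprocity correction (the `N_i` of the adjustment
#' identity `c'_ij N_i = c'_ji N_j`).
#'
#' @param scheme the [age_band_scheme] of the bands.
#' @param N positive population size per band (same length as the scheme).
#' @param stratum `"urban"`, `"rural"` or `"all"`.
#' @return a list of class `population_table` with elements `scheme`, `N`
#'   (named by band label) and `stratum`.
#' @export
population_table <- function(scheme, N, stratum = "all") {
  stopifnot(inherits(scheme, "age_band_scheme"))
  if (length(N) != n_bands(scheme)) {
    stop("population vector length ", length(N), " does not match the ",
         n_bands(scheme), "-band scheme", call. = FALSE)
  }
  if (any(!is.finite(N) | N <= 0)) {
    stop("all band population sizes must be positive", call. = FALSE)
  }
  names(N) <- scheme$labels
  structure(list(scheme = scheme, N = N, stratum = stratum),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  cat("<population_table> ", x$stratum, ", ", sum(x$N), " people in ",
      n_bands(x$scheme), " bands\n", sep = "")
  invisible(x)
}

#' Combine stratum population tables
#'
#' @param ... population tables on a common scheme.
#' @return a `population_table` with stratum `"all"` and band-wise summed
#'   sizes.
#' @export
combine_populations <- function(...) {
  tabs <- list(...)
  scheme <- tabs[[1L]]$scheme
  for (t in tabs[-1L]) {
    if (!identical(t$scheme$breaks, scheme$breaks)) {
      stop("population tables are on different age band schemes",
           call. = FALSE)
    }
  }
  population_table(scheme, Reduce(`+`, lapply(tabs, `[[`, "N")), "all")
}

# integer allocation by largest remainder, each cell at least `floor_at`
allocate_integer <- function(weights, total, floor_at = 1L) {
  w <- weights / sum(weights)
  raw <- w * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    frac_order <- order(raw - out, decreasing = TRUE)
    out[frac_order[seq_len(rem)]] <- out[frac_order[seq_len(rem)]] + 1
  }
  short <- out < floor_at
  while (any(short) && sum(out) >= floor_at * length(out)) {
    need <- floor_at - out[short]
    out[short] <- floor_at
    donor <- which.max(out)
    out[donor] <- out[donor] - sum(need)
    short <- out < floor_at
  }
  as.integer(out)
}

#' Generate stratified age pyramids
#'
#' Builds per-stratum population tables with a parametric age pyramid:
#' band weights decay geometrically with band index at rate
#' `pyramid_shape`, so `pyramid_shape = 0` is a uniform pyramid and larger
#' values give the progressively younger structure typical of high-fertility
#' populations. Band sizes are integers, each at least 1, summing exactly to
#' the stratum total.
#'
#' @param scheme the [age_band_scheme].
#' @param stratum_shares named shares per stratum (e.g.
#'   `c(urban = 0.25, rural = 0.75)`), summing to 1.
#' @param total_size total population over all strata (> 0).
#' @param pyramid_shape geometric decay rate per band (>= 0); default 0.12
#'   gives roughly a halving of cohort size every six five-year bands.
#' @return named list of [population_table]s, one per stratum.
#' @examples
#' p <- generate_population(standard_scheme("matrix"), c(all = 1),
#'                          14000, pyramid_shape = 0)
#' p$all$N  # all 1000
#' @export
generate_population <- function(scheme, stratum_shares, total_size,
                                pyramid_shape = 0.12) {
  if (total_size <= 0) stop("total population must be positive", call. = FALSE)
  if (abs(sum(stratum_shares) - 1) > 1e-8) {
    stop("stratum shares must sum to 1", call. = FALSE)
  }
  if (pyramid_shape < 0) stop("pyramid_shape must be >= 0", call. = FALSE)
  k <- n_bands(scheme)
  wt <- exp(-pyramid_shape * (seq_len(k) - 1L))
  stratum_totals <- allocate_integer(stratum_shares, total_size)
  out <- lapply(seq_along(stratum_shares), function(s) {
    population_table(scheme, allocate_integer(wt, stratum_totals[s]),
                     names(stratum_shares)[s])
  })
  names(out) <- names(stratum_shares)
  out
}

#' Project a population table onto another band scheme
#'
#' Distributes each band's population uniformly over its integer ages (the
#' open-ended last band is closed at `upper_age`) and re-sums into the
#' bands of the target scheme.
#'
#' @param population a [population_table].
#' @param scheme the target [age_band_scheme].
#' @param upper_age assumed oldest age (default 90).
#' @return a `population_table` on the target scheme.
#' @export
project_population <- function(population, scheme, upper_age = 90L) {
  src <- population$scheme
  lo <- src$breaks
  hi <- c(src$breaks[-1L] - 1L, upper_age)
  per_age <- rep(population$N / (hi - lo + 1L), hi - lo + 1L)
  ages <- sequence(hi - lo + 1L) - 1L + rep(lo, hi - lo + 1L)
  tgt <- assign_age_band(ages, scheme)
  N <- vapply(seq_len(n_bands(scheme)), function(i) sum(per_age[tgt == i]),
              numeric(1))
  population_table(scheme, N, population$stratum)
}

#' Raking margins implied by population tables
#'
#' Builds the four weighting margins (residence, regression-scheme age
#' band, diary day type, employment status) from per-stratum population
#' tables plus assumed day-type and employment-status shares, which age
#' pyramids alone cannot supply.
#'
#' @param populations named list with elements `urban` and `rural`
#'   ([population_table]s).
#' @param employment_targets named shares over
#'   non-working-age/employed/unemployed.
#' @param day_type_targets named shares over weekday/weekend (default the
#'   5:2 calendar split).
#' @param scheme age-band scheme of the age margin (default regression).
#' @return list of [margin_spec]s.
#' @export
population_margins <- function(populations, employment_targets,
                               day_type_targets = c(weekday = 5 / 7,
                                                    weekend = 2 / 7),
                               scheme = standard_scheme("regression")) {
  tot <- vapply(populations[c("urban", "rural")],
                function(p) sum(p$N), numeric(1))
  res_targets <- tot / sum(tot)
  names(res_targets) <- c("urban", "rural")
  all_pop <- combine_populations(populations$urban, populations$rural)
  age_pop <- project_population(all_pop, scheme)
  age_targets <- age_pop$N / sum(age_pop$N)
  list(
    margin_spec("residence", res_targets),
    margin_spec("age_band", age_targets),
    margin_spec("diary_day_type", day_type_targets),
    margin_spec("employment_status", employment_targets)
  )
}
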