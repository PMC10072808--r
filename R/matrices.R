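#' Contact filters
#'
#' Row predicate over diary contacts used to restrict a matrix to a subset
#' of contacts. Criteria combine with AND; the high-intensity flag selects
#' contacts that are physical OR at least 15 minutes long (duration
#' categories `15to59min`, `1to4h`, `gt4h`).
#'
#' @param settings `NULL` or a subset of the canonical setting tokens; a
#'   contact qualifies when any of its reported settings is in the subset.
#' @param physical_only keep only physical contacts.
#' @param min_duration `NULL` or a duration category; keep contacts of that
#'   duration or longer.
#' @param high_intensity keep contacts that are physical or >= 15 min.
#' @return a list of class `contact_filter`.
#' @export
contact_filter <- function(settings = NULL, physical_only = FALSE,
                           min_duration = NULL, high_intensity = FALSE) {
  if (!is.null(settings)) {
    bad <- setdiff(settings, SETTING_LEVELS)
    if (length(bad)) stop("unknown setting token(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(min_duration)) {
    min_duration <- match.arg(min_duration, DURATION_LEVELS)
  }
  structure(list(settings = settings, physical_only = physical_only,
                 min_duration = min_duration,
                 high_intensity = high_intensity),
            class = "contact_filter")
}

apply_contact_filter <- function(contacts, filter) {
  if (is.null(filter)) return(rep(TRUE, nrow(contacts)))
  keep <- rep(TRUE, nrow(contacts))
  if (!is.null(filter$settings)) {
    setting_lists <- strsplit(contacts$settings, ";", fixed = TRUE)
    keep <- keep & vapply(setting_lists,
                          function(s) any(s %in% filter$settings), logical(1))
  }
  if (isTRUE(filter$physical_only)) keep <- keep & contacts$physical
  if (!is.null(filter$min_duration)) {
    keep <- keep & (match(contacts$duration_cat, DURATION_LEVELS) >=
                      match(filter$min_duration, DURATION_LEVELS))
  }
  if (isTRUE(filter$high_intensity)) {
    long <- match(contacts$duration_cat, DURATION_LEVELS) >=
      match("15to59min", DURATION_LEVELS)
    keep <- keep & (contacts$physical | long)
  }
  keep
}

new_contact_matrix <- function(values, scheme, n_participants, sum_weights,
                               stratum, setting_label, adjusted,
                               n_dropped_missing_age = 0L) {
  dimnames(values) <- list(participant = scheme$labels,
                           contactee = scheme$labels)
  structure(list(values = values, scheme = scheme,
                 n_participants = n_participants, sum_weights = sum_weights,
                 stratum = stratum, setting_label = setting_label,
                 adjusted = adjusted,
                 n_dropped_missing_age = n_dropped_missing_age),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", x$stratum, "/", x$setting_label,
      if (x$adjusted) " (reciprocity-adjusted)" else " (raw)",
      ", ", n_bands(x$scheme), " bands, mean degree ",
      format(mean(rowSums(x$values), na.rm = TRUE), digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Weighted mean contact matrix
#'
#' Estimates the age-structured mean contact matrix `c_ij`: the weighted
#' mean number of diary contacts a participant in age band `i` reports with
#' contactees in band `j` per diary day,
#' `c_ij = sum_{p in band i} w_p n_pj / sum_{p in band i} w_p`.
#' Supplementary contacts are never included (their settings and precise
#' ages are not collected). Contacts whose contactee age is missing are
#' excluded and counted in `n_dropped_missing_age`. Bands containing no
#' participants yield `NA` rows (flagged missing, not fabricated zeros).
#'
#' @param survey a [contact_survey].
#' @param weights a [rake_weights] result or numeric vector aligned to the
#'   participants table; `NULL` for unit weights.
#' @param scheme the matrix [age_band_scheme] (default the 14-band standard
#'   `"matrix"` scheme: 0-4, ..., 60-64, 65+).
#' @param filter `NULL` or a [contact_filter].
#' @param stratum `"all"` (default), `"urban"` or `"rural"`: restricts
#'   participants (rows) to a residence stratum.
#' @param setting_label label stored on the result (default `"all"`).
#' @param age_resolution how contactee age ranges are resolved, see
#'   [resolve_contact_age()].
#' @return an unadjusted `contact_matrix` object.
#' @export
mean_contact_matrix <- function(survey, weights = NULL,
                                scheme = standard_scheme("matrix"),
                                filter = NULL, stratum = "all",
                                setting_label = "all",
                                age_resolution = "midpoint") {
  pt <- survey$participants
  if (!nrow(pt)) stop("survey has no participants", call. = FALSE)
  w <- if (is.null(weights)) rep(1, nrow(pt))
       else if (inherits(weights, "weight_vector")) weights$weights
       else weights
  if (length(w) != nrow(pt)) {
    stop("weights do not cover all participants", call. = FALSE)
  }
  keep_p <- if (stratum == "all") rep(TRUE, nrow(pt)) else
    pt$residence == stratum
  pt <- pt[keep_p, , drop = FALSE]
  w <- w[keep_p]
  if (!nrow(pt)) stop("no participants in stratum '", stratum, "'",
                      call. = FALSE)

  k <- n_bands(scheme)
  band_p <- assign_age_band(pt$age, scheme)
  denom <- vapply(seq_len(k), function(i) sum(w[band_p == i]), numeric(1))
  npart <- tabulate(band_p, nbins = k)

  ct <- survey$contacts[survey$contacts$participant_id %in%
                          pt$participant_id, , drop = FALSE]
  ct <- ct[apply_contact_filter(ct, filter), , drop = FALSE]
  cage <- resolve_contact_age(ct, age_resolution)
  dropped <- sum(is.na(cage))
  ct <- ct[!is.na(cage), , drop = FALSE]
  cage <- cage[!is.na(cage)]

  idx <- match(ct$participant_id, pt$participant_id)
  num <- matrix(0, k, k)
  if (nrow(ct)) {
    bi <- band_p[idx]
    bj <- assign_age_band(cage, scheme)
    wc <- w[idx]
    # weighted tally of contact events into band pairs
    tal <- rowsum(wc, group = (bj - 1L) * k + bi)
    num[as.integer(rownames(tal))] <- tal
  }
  values <- sweep(num, 1L, denom, "/")
  values[npart == 0L, ] <- NA_real_

  new_contact_matrix(values, scheme, npart, denom, stratum, setting_label,
                     adjusted = FALSE, n_dropped_missing_age = dropped)
}

#' Reciprocity adjustment of a contact matrix
#'
#' At the population level the total number of contacts that age group `i`
#' makes with age group `j` must equal the total made by `j` with `i`.
#' Survey estimates violate this, so each pair of cells is replaced by the
#' population-size-weighted average
#' `c'_ij = (c_ij N_i + c_ji N_j) / (2 N_i)`,
#' after which `c'_ij N_i = c'_ji N_j` holds exactly and the total number
#' of contact events `sum_ij c_ij N_i` is conserved. When `c_ij` is missing
#' (no participants in band `i`) but `c_ji` is observed, the cell is filled
#' from the transposed term alone (`c'_ij = c_ji N_j / N_i`); cells missing
#' in both directions stay missing.
#'
#' @param matrix_ an unadjusted `contact_matrix` from
#'   [mean_contact_matrix()].
#' @param population a [population_table] on the same scheme.
#' @return an adjusted `contact_matrix`. Adjusting twice is a no-op.
#' @export
reciprocity_adjust <- function(matrix_, population) {
  stopifnot(inherits(matrix_, "contact_matrix"),
            inherits(population, "population_table"))
  if (!identical(matrix_$scheme$breaks, population$scheme$breaks)) {
    stop("matrix and population are on different age band schemes",
         call. = FALSE)
  }
  N <- population$N
  if (any(N <= 0)) stop("population sizes must be positive", call. = FALSE)
  C <- matrix_$values
  total <- sweep(C, 1L, N, "*")   # T_ij = c_ij N_i, total events i -> j
  tot_t <- t(total)
  sym <- (total + tot_t) / 2
  only_fwd <- is.na(tot_t) & !is.na(total)
  only_rev <- is.na(total) & !is.na(tot_t)
  sym[only_fwd] <- total[only_fwd]
  sym[only_rev] <- tot_t[only_rev]
  adj <- sweep(sym, 1L, N, "/")
  out <- matrix_
  out$values <- adj
  out$adjusted <- TRUE
  out
}

SETTING_MATRIX_LABELS <- c("home_household", "home_nonhousehold", "work",
                           "school", "other_transport_leisure")

setting_members <- function(label) {
  if (label == "other_transport_leisure") c("transport", "leisure", "other")
  else label
}

#' Setting-stratified adjusted contact matrices
#'
#' Builds the five canonical setting matrices — at home with household
#' members, at home with non-household members, at work, at school/college,
#' and the merged transport/leisure/other setting — plus the all-settings
#' matrix, for one residence stratum, each reciprocity-adjusted against
#' that stratum's population. Under the default `"each"` attribution a
#' multi-setting contact contributes once to every setting it reports
#' (while the all-settings matrix counts it exactly once); under
#' `"exclusive_multiple"` multi-setting contacts are pooled into a
#' separate `multiple` matrix instead.
#'
#' @inheritParams mean_contact_matrix
#' @param population the [population_table] of the stratum.
#' @param attribution `"each"` (default) or `"exclusive_multiple"`.
#' @param extra_filter optional [contact_filter] applied on top of the
#'   setting split (e.g. the high-intensity filter).
#' @return named list of adjusted `contact_matrix` objects: the five
#'   setting labels plus `"all"` (and `"multiple"` under exclusive
#'   attribution).
#' @export
setting_stratified_matrices <- function(survey, weights = NULL,
                                        scheme = standard_scheme("matrix"),
                                        population, stratum = "all",
                                        attribution = c("each",
                                                        "exclusive_multiple"),
                                        extra_filter = NULL,
                                        age_resolution = "midpoint") {
  attribution <- match.arg(attribution)
  base <- survey
  if (attribution == "exclusive_multiple") {
    multi <- grepl(";", base$contacts$settings, fixed = TRUE)
  }
  out <- list()
  for (label in SETTING_MATRIX_LABELS) {
    f <- contact_filter(settings = setting_members(label),
                        physical_only = isTRUE(extra_filter$physical_only),
                        min_duration = extra_filter$min_duration,
                        high_intensity = isTRUE(extra_filter$high_intensity))
    sv <- base
    if (attribution == "exclusive_multiple") {
      sv$contacts <- sv$contacts[!multi, , drop = FALSE]
    }
    m <- mean_contact_matrix(sv, weights, scheme, filter = f,
                             stratum = stratum, setting_label = label,
                             age_resolution = age_resolution)
    out[[label]] <- reciprocity_adjust(m, population)
  }
  if (attribution == "exclusive_multiple") {
    sv <- base
    sv$contacts <- sv$contacts[multi, , drop = FALSE]
    m <- mean_contact_matrix(sv, weights, scheme, filter = extra_filter,
                             stratum = stratum, setting_label = "multiple",
                             age_resolution = age_resolution)
    out[["multiple"]] <- reciprocity_adjust(m, population)
  }
  m_all <- mean_contact_matrix(base, weights, scheme, filter = extra_filter,
                               stratum = stratum, setting_label = "all",
                               age_resolution = age_resolution)
  out[["all"]] <- reciprocity_adjust(m_all, population)
  out
}

#' Long-form export of contact matrices
#'
#' @param matrices named list of `contact_matrix` objects (raw or adjusted);
#'   raw and adjusted versions of the same stratum/setting are merged on
#'   the `c_raw` / `c_adjusted` columns when both are present.
#' @param population optional [population_table] supplying `N_i`.
#' @return data frame with columns `stratum`, `setting`, `band_i`,
#'   `band_j`, `c_raw`, `c_adjusted`, `n_i`, `N_i`.
#' @export
matrices_to_long <- function(matrices, population = NULL) {
  rows <- lapply(matrices, function(m) {
    k <- n_bands(m$scheme)
    grid <- expand.grid(i = seq_len(k), j = seq_len(k))
    data.frame(
      stratum = m$stratum, setting = m$setting_label,
      band_i = m$scheme$labels[grid$i], band_j = m$scheme$labels[grid$j],
      c_raw = if (m$adjusted) NA_real_ else m$values[cbind(grid$i, grid$j)],
      c_adjusted = if (m$adjusted) m$values[cbind(grid$i, grid$j)]
                   else NA_real_,
      n_i = m$n_participants[grid$i],
      N_i = if (is.null(population)) NA_real_ else population$N[grid$i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
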