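#' Raking margin specification
#'
#' One weighting variable and its target population shares. Supported
#' variables are `residence`, `age_band` (the participant's band on the
#' regression scheme, labels such as `"0-4"`), `diary_day_type` and
#' `employment_status`.
#'
#' @param variable the weighting variable name.
#' @param targets named non-negative shares per level, summing to 1.
#' @return a list of class `margin_spec`.
#' @export
margin_spec <- function(variable, targets) {
  variable <- match.arg(variable, c("residence", "age_band",
                                    "diary_day_type", "employment_status"))
  if (any(targets < 0)) stop("margin targets must be non-negative",
                             call. = FALSE)
  if (abs(sum(targets) - 1) > 1e-6) {
    stop("margin targets for '", variable, "' must sum to 1 (got ",
         format(sum(targets)), ")", call. = FALSE)
  }
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("margin targets must be named by level", call. = FALSE)
  }
  structure(list(variable = variable, targets = targets),
            class = "margin_spec")
}

# participant-level factor for a margin variable
margin_values <- function(survey, variable,
                          scheme = standard_scheme("regression")) {
  pt <- survey$participants
  switch(variable,
    residence = pt$residence,
    diary_day_type = pt$diary_day_type,
    employment_status = pt$employment_status,
    age_band = as.character(band_label(pt$age, scheme)),
    stop("unknown margin variable '", variable, "'", call. = FALSE)
  )
}

#' Derive employment status from occupation and age
#'
#' Children, pre-schoolers, students, retirees and anyone outside working
#' age (15-64) are `non-working-age`; the occupations `unemployed` and
#' `housewife` map to `unemployed`; every other occupation of a working-age
#' adult maps to `employed`. The mapping is overridable.
#'
#' @param occupation,age vectors of canonical occupation tokens and ages.
#' @param mapping named character vector overriding the occupation ->
#'   status map for working-age adults.
#' @return character vector of employment statuses.
#' @export
derive_employment_status <- function(occupation, age, mapping = NULL) {
  default_map <- c(
    child_at_home = "non-working-age", pre_schooler = "non-working-age",
    student = "non-working-age", retired = "non-working-age",
    unemployed = "unemployed", housewife = "unemployed",
    professional_office = "employed", shop_worker_trader = "employed",
    manual_labour_nonagri = "employed", agriculture_fishing = "employed",
    others = "employed"
  )
  if (!is.null(mapping)) default_map[names(mapping)] <- mapping
  out <- unname(default_map[occupation])
  out[age < 15 | age >= 65] <- "non-working-age"
  out
}

#' Rake participant weights to population margins
#'
#' Iterative proportional fitting: starting from unit weights, each pass
#' rescales the weights of every level of every margin variable so that
#' weighted sample shares match the target shares, repeating until the
#' largest relative margin deviation falls below `tol`. Weights are
#' normalised to mean 1. Optional trimming clamps weights to multiples of
#' the mean weight and re-rakes, for up to `trim_cycles` rounds, to limit
#' the design effect of extreme weights.
#'
#' @param survey a [contact_survey].
#' @param margin_specs list of [margin_spec]s.
#' @param tol relative margin error required for convergence (default 1e-8).
#' @param max_iter maximum raking passes (default 1000).
#' @param trim_bounds `NULL` (no trimming, default) or `c(lo, hi)` bounds as
#'   multiples of the mean weight, e.g. `c(0.2, 5)`.
#' @param trim_cycles maximum trim/re-rake rounds (default 5).
#' @param scheme age-band scheme used for the `age_band` margin (default
#'   the regression scheme).
#' @param init optional initial weights (defaults to 1; only their relative
#'   sizes matter).
#' @return a list of class `weight_vector`: `weights` (named by
#'   participant id, mean 1), `iterations_used`, `converged`,
#'   `max_margin_error`.
#' @export
rake_weights <- function(survey, margin_specs, tol = 1e-8, max_iter = 1000L,
                         trim_bounds = NULL, trim_cycles = 5L,
                         scheme = standard_scheme("regression"),
                         init = NULL) {
  pt <- survey$participants
  n <- nrow(pt)
  vars <- lapply(margin_specs, function(m) {
    v <- margin_values(survey, m$variable, scheme)
    if (anyNA(v)) {
      stop("participants not classifiable on margin '", m$variable, "'",
           call. = FALSE)
    }
    extra <- setdiff(unique(v), names(m$targets))
    if (length(extra)) {
      stop("sample level(s) ", paste0("'", extra, "'", collapse = ", "),
           " of margin '", m$variable, "' absent from targets",
           call. = FALSE)
    }
    empty <- names(m$targets)[m$targets > 0 &
                                !(names(m$targets) %in% unique(v))]
    if (length(empty)) {
      stop("no sampled participants in level '", empty[1L], "' of margin '",
           m$variable, "' which has positive target", call. = FALSE)
    }
    factor(v, levels = names(m$targets))
  })

  w <- if (is.null(init)) rep(1, n) else init / mean(init)
  rake_pass <- function(w) {
    for (k in seq_along(margin_specs)) {
      tgt <- margin_specs[[k]]$targets
      share <- tapply(w, vars[[k]], sum, default = 0) / sum(w)
      ratio <- ifelse(share > 0, tgt / share, 1)
      w <- w * ratio[as.integer(vars[[k]])]
    }
    w
  }
  max_err <- function(w) {
    errs <- vapply(seq_along(margin_specs), function(k) {
      tgt <- margin_specs[[k]]$targets
      share <- tapply(w, vars[[k]], sum, default = 0) / sum(w)
      dev <- abs(share - tgt)
      rel <- ifelse(tgt > 0, dev / tgt, ifelse(share > 0, Inf, 0))
      max(rel)
    }, numeric(1))
    max(errs)
  }

  run_rake <- function(w) {
    iter <- 0L
    err <- max_err(w)
    while (err > tol && iter < max_iter) {
      w <- rake_pass(w)
      iter <- iter + 1L
      err <- max_err(w)
    }
    list(w = w, iter = iter, err = err)
  }

  res <- run_rake(w)
  total_iter <- res$iter
  if (!is.null(trim_bounds)) {
    # IPF has a unique fixed point, so re-raking alone cannot keep weights
    # inside the bounds; each cycle clamps then re-rakes, and the final
    # clamp wins (bounds guaranteed, margins then only approximate, which
    # the reported max_margin_error and converged flag reflect)
    lo <- trim_bounds[1L]; hi <- trim_bounds[2L]
    for (cycle in seq_len(trim_cycles)) {
      w <- res$w / mean(res$w)
      if (all(w >= lo - 1e-12 & w <= hi + 1e-12)) break
      w <- pmin(pmax(w, lo), hi)
      res <- run_rake(w)
      total_iter <- total_iter + res$iter
    }
    # enforce the bounds (expressed as multiples of the mean weight) and
    # mean-1 normalisation jointly
    w <- res$w / mean(res$w)
    for (pass in 1:50) {
      w2 <- pmin(pmax(w, lo), hi)
      w2 <- w2 / mean(w2)
      if (max(abs(w2 - w)) < 1e-12) { w <- w2; break }
      w <- w2
    }
    res$w <- pmin(pmax(w, lo), hi)
    res$err <- max_err(res$w)
  }

  w <- as.numeric(res$w) / mean(res$w)
  names(w) <- pt$participant_id
  structure(list(weights = w, iterations_used = total_iter,
                 converged = res$err <= tol, max_margin_error = max_err(w)),
            class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("<weight_vector> n = ", length(x$weights),
      ", converged = ", x$converged,
      ", max margin error = ", format(x$max_margin_error, digits = 3),
      ", range = [", format(min(x$weights), digits = 3), ", ",
      format(max(x$weights), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' Maximum relative margin deviation of a weight vector
#'
#' @param weights a [rake_weights] result or bare numeric weight vector
#'   aligned to the participants table.
#' @inheritParams rake_weights
#' @return max over margin variables and levels of
#'   `|weighted share - target| / target`; a zero target with non-zero
#'   weighted share reports `Inf`.
#' @export
margin_deviation <- function(weights, survey, margin_specs,
                             scheme = standard_scheme("regression")) {
  w <- if (inherits(weights, "weight_vector")) weights$weights else weights
  errs <- vapply(margin_specs, function(m) {
    v <- factor(margin_values(survey, m$variable, scheme),
                levels = names(m$targets))
    share <- tapply(w, v, sum, default = 0) / sum(w)
    dev <- abs(share - m$targets)
    rel <- ifelse(m$targets > 0, dev / m$targets, ifelse(share > 0, Inf, 0))
    max(rel)
  }, numeric(1))
  max(errs)
}
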