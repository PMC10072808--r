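#' Multivariable negative binomial regression of contact outcomes
#'
#' Fits a log-link negative binomial model of either a participant's total
#' degree (diary + supplementary contacts) or total contact hours
#' (diary-only; the continuous hours response is converted to rounded
#' integer minutes before fitting, so relative rates are unit-free) on the
#' standard covariate set, with dispersion estimated by maximum likelihood
#' jointly with the coefficients. Sampling weights enter as analytic
#' (frequency-style) weights in the likelihood.
#'
#' Reference levels: urban, weekday, male, 1 room, the youngest age band,
#' and `child_at_home`; household size enters per unit.
#'
#' @param survey a [contact_survey].
#' @param weights weight vector or [rake_weights] result (`NULL` = unit).
#' @param response `"degree_total"` or `"contact_hours"`.
#' @param covariates subset of `c("residence", "day_type", "sex",
#'   "household_size", "n_rooms", "age_band", "occupation")`.
#' @param scheme age-band scheme of the `age_band` covariate (default the
#'   standard regression scheme 0-4, 5-14, ..., 65+).
#' @return a list of class `nb_fit`: `model` (the `glm.nb` object),
#'   `response`, `coefficients`, `relative_rates` (data frame of level,
#'   estimate, CI bounds), `dispersion`, `loglik`, `reference_levels`,
#'   `data` (the model frame, for refits).
#' @export
fit_nb_model <- function(survey, weights = NULL,
                         response = c("degree_total", "contact_hours"),
                         covariates = c("residence", "day_type", "sex",
                                        "household_size", "n_rooms",
                                        "age_band", "occupation"),
                         scheme = standard_scheme("regression")) {
  response <- match.arg(response)
  covariates <- match.arg(covariates, several.ok = TRUE)
  pt <- survey$participants
  ps <- participant_summaries(survey)
  y <- switch(response,
    degree_total = ps$degree_total,
    contact_hours = as.integer(round(ps$total_contact_hours * 60))
  )
  w <- if (is.null(weights)) rep(1, nrow(pt))
       else if (inherits(weights, "weight_vector")) weights$weights
       else weights

  df <- data.frame(
    y = y,
    residence = factor(pt$residence, RESIDENCE_LEVELS),
    day_type = factor(pt$diary_day_type, DAY_TYPE_LEVELS),
    sex = factor(pt$sex, SEX_LEVELS),
    household_size = pt$household_size,
    n_rooms = factor(pt$n_rooms, N_ROOMS_LEVELS),
    age_band = band_label(pt$age, scheme),
    occupation = factor(pt$occupation, OCCUPATION_LEVELS),
    .w = unname(w)
  )
  df <- droplevels(df)
  for (v in covariates) {
    if (is.factor(df[[v]]) && nlevels(df[[v]]) < 2L) {
      stop("covariate '", v, "' is degenerate: only level '",
           levels(df[[v]]), "' observed", call. = FALSE)
    }
  }
  form <- stats::reformulate(covariates, response = "y")
  fit <- withCallingHandlers(
    MASS::glm.nb(form, data = df, weights = .w),
    warning = function(wrn) {
      if (grepl("iteration limit reached", conditionMessage(wrn))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("negative binomial fit did not converge (deviance ",
         format(fit$deviance), ")", call. = FALSE)
  }

  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  rr <- data.frame(
    term = names(est),
    estimate = exp(est),
    conf_low = exp(est - stats::qnorm(0.975) * se),
    conf_high = exp(est + stats::qnorm(0.975) * se),
    stringsAsFactors = FALSE
  )
  refs <- vapply(covariates, function(v) {
    if (is.factor(df[[v]])) levels(df[[v]])[1L] else NA_character_
  }, character(1))

  structure(list(model = fit, response = response, coefficients = est,
                 relative_rates = rr, dispersion = fit$theta,
                 loglik = as.numeric(stats::logLik(fit)),
                 reference_levels = refs, covariates = covariates,
                 data = df),
            class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("<nb_fit> response = ", x$response, ", dispersion = ",
      format(x$dispersion, digits = 4), ", logLik = ",
      format(x$loglik, digits = 6), "\n", sep = "")
  print(x$relative_rates, digits = 3)
  invisible(x)
}

#' Per-term likelihood-ratio ANOVA of a negative binomial fit
#'
#' For each covariate, refits the model with that term removed
#' (re-estimating the dispersion) and reports the likelihood-ratio
#' statistic, its degrees of freedom (number of non-reference levels, or 1
#' for a continuous term) and the upper-tail chi-squared p-value. A
#' reduced model that fails to converge flags the term with `NA` rather
#' than fabricating a statistic.
#'
#' @param fit an [fit_nb_model()] result.
#' @return data frame with columns `term`, `statistic`, `df`, `p`.
#' @export
term_anova <- function(fit) {
  stopifnot(inherits(fit, "nb_fit"))
  df_data <- fit$data
  rows <- lapply(fit$covariates, function(v) {
    reduced_terms <- setdiff(fit$covariates, v)
    form <- if (length(reduced_terms)) {
      stats::reformulate(reduced_terms, response = "y")
    } else {
      y ~ 1
    }
    red <- tryCatch(
      withCallingHandlers(
        MASS::glm.nb(form, data = df_data, weights = .w),
        warning = function(wrn) {
          if (grepl("iteration limit reached", conditionMessage(wrn))) {
            invokeRestart("muffleWarning")
          }
        }),
      error = function(e) NULL)
    ddf <- if (is.factor(df_data[[v]])) nlevels(df_data[[v]]) - 1L else 1L
    if (is.null(red) || !red$converged) {
      return(data.frame(term = v, statistic = NA_real_, df = ddf,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    stat <- 2 * (fit$loglik - as.numeric(stats::logLik(red)))
    data.frame(term = v, statistic = stat, df = ddf,
               p = stats::pchisq(stat, ddf, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regression summary table
#'
#' Assembles the familiar survey-report layout: per covariate level, the
#' unweighted N (and %), the relative rate with 95% CI, and the per-term
#' ANOVA p-value.
#'
#' @param fit an [fit_nb_model()] result.
#' @param anova optional precomputed [term_anova()] table.
#' @return data frame with columns `covariate`, `level`, `n`, `pct`,
#'   `relative_rate`, `conf_low`, `conf_high`, `anova_p`.
#' @export
nb_summary_table <- function(fit, anova = term_anova(fit)) {
  df <- fit$data
  rows <- list()
  for (v in fit$covariates) {
    ap <- anova$p[anova$term == v]
    if (is.factor(df[[v]])) {
      levs <- levels(df[[v]])
      for (l in levs) {
        term <- paste0(v, l)
        hit <- fit$relative_rates[fit$relative_rates$term == term, ]
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = v, level = l, n = sum(df[[v]] == l),
          pct = 100 * mean(df[[v]] == l),
          relative_rate = if (nrow(hit)) hit$estimate else 1,
          conf_low = if (nrow(hit)) hit$conf_low else NA_real_,
          conf_high = if (nrow(hit)) hit$conf_high else NA_real_,
          reference = !nrow(hit), anova_p = ap, stringsAsFactors = FALSE)
      }
    } else {
      hit <- fit$relative_rates[fit$relative_rates$term == v, ]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = v, level = "per unit", n = nrow(df), pct = 100,
        relative_rate = hit$estimate, conf_low = hit$conf_low,
        conf_high = hit$conf_high, reference = FALSE, anova_p = ap,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
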