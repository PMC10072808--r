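#' Quota sampling design
#'
#' Describes a quota-sampled recruitment: a fixed number of participants per
#' age-band x sex x residence stratum. The default mirrors the common
#' community-survey design of seven recruitment age bands, two sexes and an
#' urban/rural split with an equal per-stratum quota.
#'
#' @param scheme the recruitment [age_band_scheme] (default the standard
#'   `"sampling"` scheme with bands 0-5, 6-12, 13-19, 20-29, 30-39, 40-59,
#'   60+).
#' @param total_target total target sample size; must be divisible by the
#'   number of strata. A design of 2016 participants over 7 x 2 x 2 strata
#'   yields a per-stratum quota of 72.
#' @param quota_per_stratum alternatively, the per-stratum quota directly;
#'   exactly one of `total_target` and `quota_per_stratum` is given.
#' @return a list of class `sampling_design` with elements `scheme`,
#'   `quota_per_stratum`, `total_target`, `sexes`, `residences`.
#' @examples
#' d <- sampling_design(total_target = 2016)
#' d$quota_per_stratum  # 72
#' @export
sampling_design <- function(scheme = standard_scheme("sampling"),
                            total_target = NULL, quota_per_stratum = NULL) {
  n_strata <- n_bands(scheme) * length(SEX_LEVELS) * length(RESIDENCE_LEVELS)
  if (is.null(quota_per_stratum)) {
    if (is.null(total_target)) {
      stop("give either total_target or quota_per_stratum", call. = FALSE)
    }
    if (total_target %% n_strata != 0) {
      stop("total_target ", total_target, " is not divisible by the ",
           n_strata, " strata", call. = FALSE)
    }
    quota_per_stratum <- total_target / n_strata
  } else if (is.null(total_target)) {
    total_target <- quota_per_stratum * n_strata
  }
  structure(list(scheme = scheme, quota_per_stratum = quota_per_stratum,
                 total_target = total_target, sexes = SEX_LEVELS,
                 residences = RESIDENCE_LEVELS),
            class = "sampling_design")
}

report_row <- function(table, locator, rule, message) {
  data.frame(table = table, locator = as.character(locator), rule = rule,
             message = message, stringsAsFactors = FALSE)
}

#' Validate a contact survey
#'
#' Checks every record-level invariant of the survey layout (age range,
#' household size, exclusive exact-age/age-range reporting, non-empty
#' setting lists, ordered age ranges, non-negative supplementary counts, at
#' most one supplementary record per participant/band/physicality) and
#' tabulates achieved versus target sample counts for each recruitment
#' stratum. Findings are returned, never thrown: an empty `errors` table
#' means the survey is loadable by every downstream stage.
#'
#' @param survey a [contact_survey].
#' @param design a [sampling_design], or `NULL` to skip the quota table.
#' @return a list of class `validation_report` with data-frame elements
#'   `errors` and `warnings` (columns `table`, `locator`, `rule`,
#'   `message`) and `quota_table` (achieved vs target per age band x sex x
#'   residence stratum, `NULL` when no design is supplied).
#' @export
validate_survey <- function(survey, design = NULL) {
  pt <- survey$participants
  ct <- survey$contacts
  sp <- survey$supplementary
  errors <- list()
  warnings <- list()

  bad_age <- which(is.na(pt$age) | pt$age < 0 | pt$age > 120)
  if (length(bad_age)) {
    errors[[length(errors) + 1L]] <- report_row(
      "participants", pt$participant_id[bad_age], "participant.age",
      paste0("age ", pt$age[bad_age], " outside [0, 120]"))
  }
  bad_hh <- which(is.na(pt$household_size) | pt$household_size < 1)
  if (length(bad_hh)) {
    errors[[length(errors) + 1L]] <- report_row(
      "participants", pt$participant_id[bad_hh], "participant.household_size",
      "household_size must be >= 1")
  }
  dup <- pt$participant_id[duplicated(pt$participant_id)]
  if (length(dup)) {
    errors[[length(errors) + 1L]] <- report_row(
      "participants", unique(dup), "participant.id_unique",
      "duplicated participant_id")
  }

  has_exact <- !is.na(ct$contact_age_exact)
  has_range <- !is.na(ct$contact_age_min) | !is.na(ct$contact_age_max)
  both <- which(has_exact & has_range)
  if (length(both)) {
    errors[[length(errors) + 1L]] <- report_row(
      "contacts", both, "contact.age_exclusive",
      "both exact age and age range reported")
  }
  neither <- which(!has_exact & !has_range)
  if (length(neither)) {
    warnings[[length(warnings) + 1L]] <- report_row(
      "contacts", neither, "contact.age_missing",
      "contactee age not reported; excluded from matrices")
  }
  bad_range <- which(!is.na(ct$contact_age_min) & !is.na(ct$contact_age_max) &
                       ct$contact_age_min > ct$contact_age_max)
  if (length(bad_range)) {
    errors[[length(errors) + 1L]] <- report_row(
      "contacts", bad_range, "contact.age_range_order",
      "age range min exceeds max")
  }
  empty_setting <- which(is.na(ct$settings) | !nzchar(ct$settings))
  if (length(empty_setting)) {
    errors[[length(errors) + 1L]] <- report_row(
      "contacts", empty_setting, "contact.settings_nonempty",
      "contact reports no setting")
  }

  neg <- which(is.na(sp$count) | sp$count < 0)
  if (length(neg)) {
    errors[[length(errors) + 1L]] <- report_row(
      "supplementary", neg, "supplementary.count_nonneg",
      "supplementary count must be >= 0")
  }
  key <- paste(sp$participant_id, sp$band, sp$physical)
  dup_s <- which(duplicated(key))
  if (length(dup_s)) {
    errors[[length(errors) + 1L]] <- report_row(
      "supplementary", dup_s, "supplementary.unique",
      "duplicated participant/band/physicality supplementary record")
  }

  quota_table <- NULL
  if (!is.null(design)) {
    band <- band_label(pt$age, design$scheme)
    achieved <- as.data.frame(table(
      age_band = band,
      sex = factor(pt$sex, design$sexes),
      residence = factor(pt$residence, design$residences)
    ), responseName = "achieved")
    achieved$target <- design$quota_per_stratum
    achieved$deficit <- achieved$target - achieved$achieved
    quota_table <- achieved
  }

  structure(list(
    errors = do.call(rbind, errors) %||%
      report_row(character(0), character(0), character(0), character(0)),
    warnings = do.call(rbind, warnings) %||%
      report_row(character(0), character(0), character(0), character(0)),
    quota_table = quota_table
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", nrow(x$errors), " error(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  if (!is.null(x$quota_table)) {
    met <- sum(x$quota_table$achieved >= x$quota_table$target)
    cat("  quota: ", met, "/", nrow(x$quota_table),
        " strata at or above target\n", sep = "")
  }
  invisible(x)
}
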