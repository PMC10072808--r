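#' Duration category midpoints
#'
#' Contact duration is reported in one of five ranges; for total contact
#' hours each range is replaced by its midpoint in minutes, right-truncated
#' at 4 h so the open-ended top category contributes 240 minutes.
#'
#' @param duration_cat character vector of canonical duration categories.
#' @return numeric minutes: `lt5min` 2.5, `5to14min` 9.5, `15to59min` 37,
#'   `1to4h` 150, `gt4h` 240.
#' @export
duration_midpoint_minutes <- function(duration_cat) {
  mid <- c(lt5min = 2.5, `5to14min` = 9.5, `15to59min` = 37,
           `1to4h` = 150, gt4h = 240)
  bad <- !is.na(duration_cat) & !(duration_cat %in% names(mid))
  if (any(bad)) {
    stop("unknown duration category '", duration_cat[bad][1L], "'",
         call. = FALSE)
  }
  unname(mid[duration_cat])
}

#' Per-participant contact summaries
#'
#' Degree (number of contacts) split into diary and supplementary
#' components, and total contact hours from diary durations via category
#' midpoints. Contact hours are diary-only because duration is not
#' collected for supplementary contacts.
#'
#' @param survey a [contact_survey].
#' @return data frame with one row per participant: `participant_id`,
#'   `degree_diary`, `degree_supplementary`, `degree_total`,
#'   `total_contact_hours`.
#' @export
participant_summaries <- function(survey) {
  pt <- survey$participants
  ids <- pt$participant_id
  ct <- survey$contacts
  diary <- tabulate(match(ct$participant_id, ids), nbins = length(ids))
  supp_by_id <- tapply(survey$supplementary$count,
                       survey$supplementary$participant_id, sum)
  supp <- rep(0L, length(ids))
  hit <- match(names(supp_by_id), ids)
  supp[hit] <- as.integer(supp_by_id)
  minutes <- duration_midpoint_minutes(ct$duration_cat)
  min_by_id <- tapply(minutes, ct$participant_id, sum)
  hours <- rep(0, length(ids))
  hit <- match(names(min_by_id), ids)
  hours[hit] <- min_by_id / 60
  data.frame(participant_id = ids, degree_diary = diary,
             degree_supplementary = supp, degree_total = diary + supp,
             total_contact_hours = hours, stringsAsFactors = FALSE)
}

#' Weighted quantiles
#'
#' Left-continuous inverse of the weighted empirical distribution function
#' (the weighted analogue of `type = 1` quantiles):
#' `Q(p) = inf { x : F_w(x) >= p }`. With equal weights this reproduces the
#' unweighted type-1 quantile.
#'
#' @param x numeric values.
#' @param w positive weights (default equal).
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per probability.
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)),
                              probs = c(0.25, 0.5, 0.75)) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' @rdname weighted_quantile
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  weighted_quantile(x, w, 0.5)
}

## ---- setting proportions ----------------------------------------------

DISPLAY_SETTING_LEVELS <- c("home_household", "home_nonhousehold", "work",
                            "school", "other", "multiple")

# exclusive display setting: transport/leisure merged into "other";
# multi-setting contacts form their own bucket
display_setting <- function(settings) {
  lists <- strsplit(settings, ";", fixed = TRUE)
  vapply(lists, function(s) {
    s <- unique(ifelse(s %in% c("transport", "leisure"), "other", s))
    if (length(s) > 1L) "multiple" else s
  }, character(1))
}

#' Weighted setting proportions of diary contacts
#'
#' The proportion of diary contacts reported in each setting, weighted by
#' the reporting participant's sampling weight, overall or split by a
#' participant grouping variable. For this display, multi-setting contacts
#' are pooled into an exclusive `multiple` category and transport/leisure
#' are merged into `other`.
#'
#' @param survey a [contact_survey].
#' @param weights weight vector or [rake_weights] result (`NULL` = unit).
#' @param groupby `NULL` or one of `"age_band"`, `"residence"`, `"sex"`,
#'   `"day_type"`, `"occupation"`.
#' @param scheme age-band scheme used when `groupby = "age_band"` (default
#'   the 14-band matrix scheme).
#' @return a list of class `crosstab`: `counts` (weighted contact counts,
#'   groups x settings), `proportions` (rows summing to 1), `weighted`.
#' @export
setting_proportions <- function(survey, weights = NULL, groupby = NULL,
                                scheme = standard_scheme("matrix")) {
  pt <- survey$participants
  ct <- survey$contacts
  w <- if (is.null(weights)) rep(1, nrow(pt))
       else if (inherits(weights, "weight_vector")) weights$weights
       else weights
  idx <- match(ct$participant_id, pt$participant_id)
  wc <- w[idx]
  setting <- factor(display_setting(ct$settings), DISPLAY_SETTING_LEVELS)
  group <- if (is.null(groupby)) factor(rep("all", nrow(ct))) else {
    gvals <- switch(groupby,
      age_band = as.character(band_label(pt$age, scheme)),
      residence = pt$residence,
      sex = pt$sex,
      day_type = pt$diary_day_type,
      occupation = pt$occupation,
      stop("unknown groupby '", groupby, "'", call. = FALSE))
    gl <- switch(groupby, age_band = scheme$labels, residence =
                   RESIDENCE_LEVELS, sex = SEX_LEVELS, day_type =
                   DAY_TYPE_LEVELS, occupation = OCCUPATION_LEVELS)
    factor(gvals[idx], gl)
  }
  counts <- tapply(wc, list(group, setting), sum, default = 0)
  props <- counts / rowSums(counts)
  structure(list(counts = counts, proportions = props,
                 weighted = !is.null(weights),
                 row_variable = groupby %||% "all",
                 col_variable = "setting"),
            class = "crosstab")
}

## ---- chi-squared machinery --------------------------------------------

#' Pearson chi-squared test of independence
#'
#' Plain Pearson test without continuity correction:
#' `X^2 = sum (O - E)^2 / E` with `df = (r - 1)(c - 1)` and an upper-tail
#' p-value. All expected counts must be positive.
#'
#' @param tab a numeric matrix (or table) of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-squared test undefined: zero row or column marginal",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Chi-squared test for trend
#'
#' Cochran-Armitage test of a linear trend in a binary outcome across
#' ordered categories (e.g. proportion of physical contacts across ordered
#' duration bins), with integer scores `1..k` by default. One degree of
#' freedom; invariant to affine transformation (including reversal) of the
#' scores.
#'
#' @param successes,totals integer vectors per ordered level.
#' @param scores numeric scores (default `1..k`).
#' @return list with `statistic`, `df` (always 1), `p`.
#' @export
chi2_trend <- function(successes, totals, scores = seq_along(successes)) {
  if (length(successes) < 2L) {
    stop("trend test needs at least 2 ordered levels", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::prop.trend.test(successes, totals, score = scores))
  list(statistic = unname(res$statistic), df = 1L, p = res$p.value)
}

## ---- reporting-method comparison --------------------------------------

#' Compare diary and supplementary contact reporting
#'
#' Coarsens diary contactee ages to the four supplementary reporting bands
#' (0-4, 5-15, 16-64, 65+) and tests whether (a) the age distribution and
#' (b) the physical/non-physical split differ between the two reporting
#' methods, using Pearson chi-squared tests (df 3 and df 1). Also returns
#' coarse-band participant x contactee matrices per method for visual
#' comparison.
#'
#' @param survey a [contact_survey].
#' @return a list of class `reporting_comparison`: `age_table` (4 x 2),
#'   `age_test`, `physical_table` (2 x 2), `physical_test`,
#'   `coarse_matrix_diary`, `coarse_matrix_supplementary` (4 x 4 counts),
#'   `applicable`.
#' @export
reporting_method_comparison <- function(survey) {
  sp <- survey$supplementary
  if (!nrow(sp) || sum(sp$count) == 0) {
    return(structure(list(applicable = FALSE), class =
                       "reporting_comparison"))
  }
  scheme <- standard_scheme("supplementary")
  ct <- survey$contacts
  cage <- resolve_contact_age(ct)
  ok <- !is.na(cage)
  diary_band <- band_label(cage[ok], scheme)
  diary_age <- table(band = diary_band)
  supp_age <- tapply(sp$count, factor(sp$band, SUPP_BAND_LEVELS), sum,
                     default = 0)
  age_table <- cbind(diary = as.numeric(diary_age),
                     supplementary = as.numeric(supp_age))
  rownames(age_table) <- SUPP_BAND_LEVELS

  phys_table <- rbind(
    diary = c(physical = sum(ct$physical, na.rm = TRUE),
              nonphysical = sum(!ct$physical, na.rm = TRUE)),
    supplementary = c(sum(sp$count[sp$physical]),
                      sum(sp$count[!sp$physical]))
  )

  pt <- survey$participants
  p_band_diary <- band_label(
    pt$age[match(ct$participant_id[ok], pt$participant_id)], scheme)
  coarse_diary <- table(participant = p_band_diary, contactee = diary_band)
  p_band_supp <- band_label(
    pt$age[match(sp$participant_id, pt$participant_id)], scheme)
  coarse_supp <- tapply(sp$count,
                        list(participant = p_band_supp,
                             contactee = factor(sp$band, SUPP_BAND_LEVELS)),
                        sum, default = 0)

  structure(list(
    applicable = TRUE,
    age_table = age_table,
    age_test = chi2_independence(age_table),
    physical_table = phys_table,
    physical_test = chi2_independence(phys_table),
    coarse_matrix_diary = unclass(coarse_diary),
    coarse_matrix_supplementary = coarse_supp
  ), class = "reporting_comparison")
}

#' @export
print.reporting_comparison <- function(x, ...) {
  if (!x$applicable) {
    cat("<reporting_comparison> not applicable (no supplementary contacts)\n")
    return(invisible(x))
  }
  cat("<reporting_comparison>\n  age distribution: X2 = ",
      format(x$age_test$statistic, digits = 5), ", df = ", x$age_test$df,
      ", p = ", format.pval(x$age_test$p), "\n  physical proportion: X2 = ",
      format(x$physical_test$statistic, digits = 5), ", df = ",
      x$physical_test$df, ", p = ", format.pval(x$physical_test$p), "\n",
      sep = "")
  invisible(x)
}

## ---- distance and mobility --------------------------------------------

#' Distance-band and travel-frequency tables
#'
#' Weighted distribution of diary contacts over distance-from-home bands
#' (missing distance is reported as its own category, never dropped), and,
#' when the participants table carries travel-frequency columns
#' (`travel_commune`, `travel_district`, `travel_province`,
#' `travel_country`), the weighted distribution of usual travel frequency
#' outside each administrative level by age band and residence.
#'
#' @param survey a [contact_survey].
#' @param weights weight vector or [rake_weights] result (`NULL` = unit).
#' @param scheme age-band scheme for the mobility table rows (default the
#'   regression scheme).
#' @return list with `distance` (weighted counts and shares per distance
#'   band, including `missing`) and `mobility` (long data frame, `NULL`
#'   when no travel columns are present).
#' @export
distance_mobility_tables <- function(survey, weights = NULL,
                                     scheme = standard_scheme("regression")) {
  pt <- survey$participants
  ct <- survey$contacts
  w <- if (is.null(weights)) rep(1, nrow(pt))
       else if (inherits(weights, "weight_vector")) weights$weights
       else weights
  wc <- w[match(ct$participant_id, pt$participant_id)]
  dist <- factor(ifelse(is.na(ct$distance_cat), "missing", ct$distance_cat),
                 c(DISTANCE_LEVELS, "missing"))
  counts <- tapply(wc, dist, sum, default = 0)
  distance <- data.frame(distance = names(counts),
                         weighted_count = as.numeric(counts),
                         share = as.numeric(counts) / sum(counts),
                         stringsAsFactors = FALSE)

  travel_cols <- intersect(paste0("travel_", TRAVEL_SCOPES), names(pt))
  mobility <- NULL
  if (length(travel_cols)) {
    band <- band_label(pt$age, scheme)
    rows <- lapply(travel_cols, function(col) {
      lev <- factor(ifelse(is.na(pt[[col]]), "missing", pt[[col]]),
                    c(TRAVEL_LEVELS, "missing"))
      tab <- tapply(w, list(band, pt$residence, lev), sum, default = 0)
      long <- as.data.frame.table(tab, responseName = "weighted_count",
                                  stringsAsFactors = FALSE)
      names(long)[1:3] <- c("age_band", "residence", "frequency")
      long$admin_level <- sub("^travel_", "", col)
      long
    })
    mobility <- do.call(rbind, rows)
    tot <- stats::ave(mobility$weighted_count,
                      mobility$age_band, mobility$residence,
                      mobility$admin_level, FUN = sum)
    mobility$share <- ifelse(tot > 0, mobility$weighted_count / tot, NA)
  }
  list(distance = distance, mobility = mobility)
}
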