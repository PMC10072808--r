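## Canonical categorical levels of the two-table contact-survey layout.

#' Canonical categorical levels
#'
#' Level sets used throughout the package, in canonical order.
#' @name survey_levels
#' @keywords internal
NULL

SEX_LEVELS <- c("male", "female")
RESIDENCE_LEVELS <- c("urban", "rural")
DAY_TYPE_LEVELS <- c("weekday", "weekend")
EMPLOYMENT_LEVELS <- c("non-working-age", "employed", "unemployed")
OCCUPATION_LEVELS <- c(
  "child_at_home", "pre_schooler", "student", "professional_office",
  "shop_worker_trader", "manual_labour_nonagri", "agriculture_fishing",
  "housewife", "retired", "unemployed", "others"
)
SETTING_LEVELS <- c("home_household", "home_nonhousehold", "work", "school",
                    "transport", "leisure", "other")
DURATION_LEVELS <- c("lt5min", "5to14min", "15to59min", "1to4h", "gt4h")
FREQUENCY_LEVELS <- c("daily", "often", "occasional", "rarely", "first_time")
DISTANCE_LEVELS <- c("lt1km", "1to9km", "gt9km")
N_ROOMS_LEVELS <- c("1", "2", "3", "4", "5+")
SUPP_BAND_LEVELS <- c("0-4", "5-15", "16-64", "65+")
TRAVEL_LEVELS <- c("never", "yearly", "monthly", "weekly", "daily")
TRAVEL_SCOPES <- c("commune", "district", "province", "country")

PARTICIPANT_COLS <- c(
  "participant_id", "age", "sex", "residence", "district_id", "occupation",
  "household_size", "n_rooms", "diary_day_type", "employment_status",
  "diary_complete"
)
CONTACT_COLS <- c(
  "participant_id", "contact_age_exact", "contact_age_min", "contact_age_max",
  "settings", "physical", "duration_cat", "frequency_cat", "distance_cat"
)
SUPP_COLS <- c("participant_id", "band", "physical", "count")

#' Construct a contact survey object
#'
#' Bundles the three tables of the conventional diary-survey layout:
#' one row per participant, one row per diary-reported contact, and
#' long-form counts of supplementary contacts (contacts the participant
#' recalled omitting from the diary, reported only as counts in four coarse
#' age bands split by physical/non-physical).
#'
#' @param participants data frame with columns `participant_id`, `age`,
#'   `sex`, `residence`, `district_id`, `occupation`, `household_size`,
#'   `n_rooms`, `diary_day_type`, `employment_status`, `diary_complete`
#'   (optional travel-frequency columns `travel_commune`, `travel_district`,
#'   `travel_province`, `travel_country` are kept when present).
#' @param contacts data frame with columns `participant_id`,
#'   `contact_age_exact`, `contact_age_min`, `contact_age_max` (exactly one
#'   of exact or min/max range per row), `settings` (one or more canonical
#'   setting tokens separated by `";"`), `physical`, `duration_cat`,
#'   `frequency_cat`, `distance_cat`.
#' @param supplementary long-form data frame with columns `participant_id`,
#'   `band` (one of `0-4`, `5-15`, `16-64`, `65+`), `physical`, `count`.
#' @return A list of class `contact_survey` with elements `participants`,
#'   `contacts`, `supplementary`.
#' @export
contact_survey <- function(participants, contacts,
                           supplementary = empty_supplementary()) {
  missing_p <- setdiff(PARTICIPANT_COLS, names(participants))
  if (length(missing_p)) {
    stop("participants table is missing required column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  missing_c <- setdiff(CONTACT_COLS, names(contacts))
  if (length(missing_c)) {
    stop("contacts table is missing required column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  missing_s <- setdiff(SUPP_COLS, names(supplementary))
  if (length(missing_s)) {
    stop("supplementary table is missing required column(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(contacts$participant_id),
                     participants$participant_id)
  if (length(unknown)) {
    stop("contacts reference unknown participant id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_s <- setdiff(unique(supplementary$participant_id),
                       participants$participant_id)
  if (length(unknown_s)) {
    stop("supplementary contacts reference unknown participant id(s): ",
         paste(unknown_s, collapse = ", "), call. = FALSE)
  }
  structure(
    list(participants = as.data.frame(participants),
         contacts = as.data.frame(contacts),
         supplementary = as.data.frame(supplementary)),
    class = "contact_survey"
  )
}

#' @export
print.contact_survey <- function(x, ...) {
  cat("<contact_survey> ", nrow(x$participants), " participants, ",
      nrow(x$contacts), " diary contacts, ",
      sum(x$supplementary$count), " supplementary contacts\n", sep = "")
  invisible(x)
}

empty_supplementary <- function() {
  data.frame(participant_id = character(0), band = character(0),
              physical = logical(0), count = integer(0),
              stringsAsFactors = FALSE)
}

#' Resolve contactee age to a single value
#'
#' Contacts report either an exact contactee age or an age range. Ranges are
#' resolved to `floor((min + max) / 2)` by default, or to a uniform integer
#' draw within the range when `mode = "uniform"` (seed the RNG beforehand
#' for reproducibility).
#'
#' @param contacts the `contacts` table of a [contact_survey].
#' @param mode `"midpoint"` (default) or `"uniform"`.
#' @return numeric vector of resolved contactee ages; `NA` where neither
#'   exact age nor range is present.
#' @export
resolve_contact_age <- function(contacts, mode = c("midpoint", "uniform")) {
  mode <- match.arg(mode)
  age <- contacts$contact_age_exact
  has_range <- is.na(age) & !is.na(contacts$contact_age_min)
  if (any(has_range)) {
    lo <- contacts$contact_age_min[has_range]
    hi <- contacts$contact_age_max[has_range]
    age[has_range] <- if (mode == "midpoint") {
      floor((lo + hi) / 2)
    } else {
      lo + floor(stats::runif(length(lo)) * (hi - lo + 1))
    }
  }
  age
}

## ---- dialect-aware reading --------------------------------------------

#' Default file dialect
#'
#' A dialect maps file column names and level labels onto the canonical
#' survey layout. The default dialect is the identity: canonical column
#' names and canonical level tokens. A dialect is a list with elements
#' `columns` (per-table named lists mapping canonical name -> file name),
#' `levels` (per-variable named lists mapping file label -> canonical
#' token) and `settings_sep` (separator of multi-setting strings).
#'
#' @return a dialect list.
#' @export
default_dialect <- function() {
  list(columns = list(participants = list(), contacts = list(),
                      supplementary = list()),
       levels = list(),
       settings_sep = ";")
}

#' Read a dialect configuration from YAML
#'
#' @param path path to a YAML file with any of the keys `columns`, `levels`,
#'   `settings_sep`; missing keys fall back to [default_dialect()].
#' @return a dialect list.
#' @export
read_dialect <- function(path) {
  d <- utils::modifyList(default_dialect(), yaml::read_yaml(path))
  d
}

map_levels <- function(x, variable, dialect) {
  m <- dialect$levels[[variable]]
  if (is.null(m) || !length(m)) return(x)
  from <- names(m)
  to <- unlist(m, use.names = FALSE)
  hit <- match(x, from)
  out <- x
  out[!is.na(hit)] <- to[hit[!is.na(hit)]]
  out
}

rename_cols <- function(df, table, dialect, path) {
  m <- dialect$columns[[table]]
  if (!is.null(m) && length(m)) {
    for (canonical in names(m)) {
      file_col <- m[[canonical]]
      if (!file_col %in% names(df)) {
        stop("file '", path, "' is missing required column '", file_col,
             "' (mapped to '", canonical, "')", call. = FALSE)
      }
      names(df)[names(df) == file_col] <- canonical
    }
  }
  df
}

check_levels <- function(x, allowed, variable, table) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (!any(bad)) return(NULL)
  data.frame(
    table = table, row = which(bad), rule = paste0("level:", variable),
    message = paste0("unrecognised ", variable, " level '", x[bad], "'"),
    stringsAsFactors = FALSE
  )
}

#' Load a contact survey from delimited text files
#'
#' Reads the canonical UTF-8 comma-separated trio (participants, contacts,
#' supplementary counts), canonicalises categorical levels through the
#' dialect, and collects unparseable rows into a `problems` attribute
#' instead of silently dropping them. Missing required columns and
#' unresolvable participant ids are hard errors.
#'
#' @param participants_path,contacts_path,supplementary_path CSV file paths;
#'   `supplementary_path` may be `NULL` when no supplementary counts were
#'   collected.
#' @param dialect a dialect list as returned by [default_dialect()] or
#'   [read_dialect()], mapping file column names and level labels onto the
#'   canonical layout.
#' @return a [contact_survey]; rows whose categorical labels could not be
#'   canonicalised are reported in `attr(survey, "problems")`.
#' @export
load_survey <- function(participants_path, contacts_path,
                        supplementary_path = NULL,
                        dialect = default_dialect()) {
  pt <- rename_cols(utils::read.csv(participants_path,
                                    stringsAsFactors = FALSE),
                    "participants", dialect, participants_path)
  ct <- rename_cols(utils::read.csv(contacts_path, stringsAsFactors = FALSE),
                    "contacts", dialect, contacts_path)
  sp <- if (is.null(supplementary_path)) empty_supplementary() else {
    rename_cols(utils::read.csv(supplementary_path,
                                stringsAsFactors = FALSE),
                "supplementary", dialect, supplementary_path)
  }
  if ("participant_id" %in% names(pt)) {
    pt$participant_id <- as.character(pt$participant_id)
  }
  if ("participant_id" %in% names(ct)) {
    ct$participant_id <- as.character(ct$participant_id)
  }
  if ("participant_id" %in% names(sp)) {
    sp$participant_id <- as.character(sp$participant_id)
  }

  missing_p <- setdiff(PARTICIPANT_COLS, names(pt))
  if (length(missing_p)) {
    stop("participants file is missing required column(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  missing_c <- setdiff(setdiff(CONTACT_COLS, c("contact_age_exact",
                                               "contact_age_min",
                                               "contact_age_max",
                                               "distance_cat",
                                               "frequency_cat")),
                       names(ct))
  if (length(missing_c)) {
    stop("contacts file is missing required column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  for (col in c("contact_age_exact", "contact_age_min", "contact_age_max")) {
    if (!col %in% names(ct)) ct[[col]] <- NA_real_
  }
  for (col in c("frequency_cat", "distance_cat")) {
    if (!col %in% names(ct)) ct[[col]] <- NA_character_
  }

  # canonicalise categorical labels
  for (v in c("sex", "residence", "occupation", "n_rooms", "diary_day_type",
              "employment_status")) {
    pt[[v]] <- map_levels(as.character(pt[[v]]), v, dialect)
  }
  for (v in c("duration_cat", "frequency_cat", "distance_cat")) {
    ct[[v]] <- map_levels(as.character(ct[[v]]), v, dialect)
  }
  sep <- dialect$settings_sep %||% ";"
  setting_lists <- strsplit(as.character(ct$settings), sep, fixed = TRUE)
  setting_lists <- lapply(setting_lists, function(s) {
    map_levels(trimws(s), "settings", dialect)
  })
  ct$settings <- vapply(setting_lists, paste, "", collapse = ";")
  sp$band <- map_levels(as.character(sp$band), "band", dialect)

  problems <- rbind(
    check_levels(pt$sex, SEX_LEVELS, "sex", "participants"),
    check_levels(pt$residence, RESIDENCE_LEVELS, "residence", "participants"),
    check_levels(pt$occupation, OCCUPATION_LEVELS, "occupation",
                 "participants"),
    check_levels(pt$diary_day_type, DAY_TYPE_LEVELS, "diary_day_type",
                 "participants"),
    check_levels(pt$employment_status, EMPLOYMENT_LEVELS, "employment_status",
                 "participants"),
    check_levels(pt$n_rooms, N_ROOMS_LEVELS, "n_rooms", "participants"),
    check_levels(ct$duration_cat, DURATION_LEVELS, "duration_cat",
                 "contacts"),
    check_levels(ct$frequency_cat, FREQUENCY_LEVELS, "frequency_cat",
                 "contacts"),
    check_levels(ct$distance_cat, DISTANCE_LEVELS, "distance_cat",
                 "contacts"),
    check_levels(unlist(lapply(seq_along(setting_lists), function(i) {
      s <- setting_lists[[i]]
      if (all(s %in% SETTING_LEVELS)) NA_character_ else s[!(s %in%
        SETTING_LEVELS)][1L]
    })), SETTING_LEVELS, "settings", "contacts"),
    check_levels(sp$band, SUPP_BAND_LEVELS, "band", "supplementary")
  )

  pt$age <- as.numeric(pt$age)
  pt$household_size <- as.integer(pt$household_size)
  pt$diary_complete <- as.logical(pt$diary_complete)
  ct$physical <- as.logical(ct$physical)
  sp$physical <- as.logical(sp$physical)
  sp$count <- as.integer(sp$count)

  survey <- contact_survey(pt, ct, sp)
  attr(survey, "problems") <- problems
  survey
}

#' Write a contact survey in the canonical dialect
#'
#' Writes the UTF-8 comma-separated trio with canonical column names and
#' level tokens. `load_survey()` followed by `write_survey()` reproduces a
#' canonical-dialect file byte-identically.
#'
#' @param survey a [contact_survey].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix; files are named
#'   `<prefix>participants.csv`, `<prefix>contacts.csv`,
#'   `<prefix>supplementary.csv`.
#' @return invisibly, the three file paths.
#' @export
write_survey <- function(survey, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("participants.csv",
                                           "contacts.csv",
                                           "supplementary.csv")))
  pt <- survey$participants
  travel_cols <- intersect(paste0("travel_", TRAVEL_SCOPES), names(pt))
  utils::write.csv(pt[, c(PARTICIPANT_COLS, travel_cols)], paths[1L],
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(survey$contacts[, CONTACT_COLS], paths[2L],
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(survey$supplementary[, SUPP_COLS], paths[3L],
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
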