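#' Age band schemes
#'
#' An age band scheme is a named partition of non-negative integer age into
#' contiguous bands. Bands are half-open intervals `[lower, next_lower)` on
#' integer age, with the last band open-ended. Three schemes recur in
#' diary-based contact-survey analysis and are available by name:
#'
#' * `"matrix"`: five-year bands from 0 to 64 plus a single 65+ band
#'   (14 bands), used for mixing matrices.
#' * `"sampling"`: the recruitment-quota bands 0-5, 6-12, 13-19, 20-29,
#'   30-39, 40-59, 60+ (7 bands). Printed labels such as "0-5" are inclusive
#'   of both endpoints, i.e. the next lower bound is 6.
#' * `"regression"`: 0-4, 5-14, 15-24, ..., 55-64, 65+ (8 bands), used as a
#'   covariate in degree/contact-hours regressions and for weighting margins.
#' * `"supplementary"`: the coarse reporting bands 0-4, 5-15, 16-64, 65+
#'   (4 bands) in which supplementary (non-diary) contacts are counted.
#'
#' @param breaks strictly ascending integer lower bounds; the first must be 0.
#' @param name a short token naming the scheme.
#' @return An object of class `age_band_scheme`: a list with elements
#'   `name`, `breaks` and `labels`.
#' @examples
#' sc <- age_band_scheme(c(0, 5, 10), "toy")
#' sc$labels  # "0-4"  "5-9"  "10+"
#' @export
age_band_scheme <- function(breaks, name = "custom") {
  breaks <- as.integer(breaks)
  if (length(breaks) < 1L || breaks[1L] != 0L) {
    stop("age band breaks must start at 0", call. = FALSE)
  }
  if (any(diff(breaks) <= 0L)) {
    stop("age band breaks must be strictly ascending", call. = FALSE)
  }
  n <- length(breaks)
  labels <- c(
    if (n > 1L) paste0(breaks[-n], "-", breaks[-1L] - 1L),
    paste0(breaks[n], "+")
  )
  structure(list(name = name, breaks = breaks, labels = labels),
            class = "age_band_scheme")
}

#' @export
print.age_band_scheme <- function(x, ...) {
  cat("<age_band_scheme> ", x$name, ": ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname age_band_scheme
#' @param scheme_name one of `"matrix"`, `"sampling"`, `"regression"`,
#'   `"supplementary"`.
#' @export
standard_scheme <- function(scheme_name = c("matrix", "sampling",
                                            "regression", "supplementary")) {
  scheme_name <- match.arg(scheme_name)
  breaks <- switch(scheme_name,
    matrix        = c(seq(0L, 60L, by = 5L), 65L),
    sampling      = c(0L, 6L, 13L, 20L, 30L, 40L, 60L),
    regression    = c(0L, seq(5L, 65L, by = 10L)),
    supplementary = c(0L, 5L, 16L, 65L)
  )
  age_band_scheme(breaks, scheme_name)
}

#' Assign ages to bands of a scheme
#'
#' Returns the 1-based index of the unique band whose half-open interval
#' `[lower, next_lower)` contains each age; the last band is open-ended.
#' Assignment is total on non-negative age and monotone in age.
#'
#' @param age_years numeric vector of ages in years (>= 0); `NA` passes
#'   through as `NA`.
#' @param scheme an [age_band_scheme].
#' @return integer vector of band indices in `1..length(scheme$breaks)`.
#' @examples
#' assign_age_band(c(4, 64, 65), standard_scheme("matrix"))  # 1, 13, 14
#' @export
assign_age_band <- function(age_years, scheme) {
  stopifnot(inherits(scheme, "age_band_scheme"))
  if (any(age_years < 0, na.rm = TRUE)) {
    stop("negative age cannot be assigned to an age band", call. = FALSE)
  }
  findInterval(age_years, scheme$breaks)
}

#' @rdname assign_age_band
#' @return `band_label()`: factor of band labels with scheme-ordered levels.
#' @export
band_label <- function(age_years, scheme) {
  idx <- assign_age_band(age_years, scheme)
  factor(scheme$labels[idx], levels = scheme$labels)
}

n_bands <- function(scheme) length(scheme$breaks)

#' Band midpoints in years
#'
#' Midpoint of each closed integer band; the open-ended last band is closed
#' at `upper_age` for the purpose of taking a midpoint.
#'
#' @inheritParams assign_age_band
#' @param upper_age assumed oldest age for the open-ended band (default 90).
#' @return numeric vector, one midpoint per band.
#' @export
band_midpoints <- function(scheme, upper_age = 90) {
  b <- scheme$breaks
  up <- c(b[-1L] - 1L, upper_age)
  (b + up) / 2
}
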