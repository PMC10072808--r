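# In-code fixtures and independent brute-force oracles shared across tests.

# minimal valid participant row(s)
make_participants <- function(n, age = 30, sex = "male", residence = "urban",
                              day_type = "weekday",
                              employment = "employed",
                              occupation = "agriculture_fishing",
                              household_size = 4L) {
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = rep_len(age, n), sex = rep_len(sex, n),
    residence = rep_len(residence, n),
    district_id = rep_len("D1", n),
    occupation = rep_len(occupation, n),
    household_size = rep_len(household_size, n),
    n_rooms = rep_len("2", n),
    diary_day_type = rep_len(day_type, n),
    employment_status = rep_len(employment, n),
    diary_complete = rep_len(TRUE, n),
    stringsAsFactors = FALSE
  )
}

make_contacts <- function(participant_id, contact_age, settings = "other",
                          physical = TRUE, duration = "15to59min",
                          frequency = "daily", distance = "lt1km") {
  n <- max(length(participant_id), length(contact_age))
  data.frame(
    participant_id = rep_len(participant_id, n),
    contact_age_exact = as.numeric(rep_len(contact_age, n)),
    contact_age_min = rep_len(NA_real_, n),
    contact_age_max = rep_len(NA_real_, n),
    settings = rep_len(settings, n), physical = rep_len(physical, n),
    duration_cat = rep_len(duration, n),
    frequency_cat = rep_len(frequency, n),
    distance_cat = rep_len(distance, n),
    stringsAsFactors = FALSE
  )
}

# survey whose participant degrees are encoded as supplementary counts,
# for regression tests that need arbitrary response values cheaply
degree_survey <- function(degrees, residence = "urban", sex = "male",
                          age = 30) {
  n <- length(degrees)
  pt <- make_participants(n, age = age, sex = sex, residence = residence)
  pos <- degrees > 0
  sp <- data.frame(participant_id = pt$participant_id[pos],
                   band = "16-64", physical = TRUE,
                   count = as.integer(degrees[pos]),
                   stringsAsFactors = FALSE)
  contact_survey(pt, make_contacts(character(0), numeric(0)), sp)
}

## ---- independent oracles ----------------------------------------------

# interval-membership search, independent of findInterval
band_oracle <- function(age, breaks) {
  upper <- c(breaks[-1L], Inf)
  for (i in seq_along(breaks)) {
    if (age >= breaks[i] && age < upper[i]) return(i)
  }
  NA_integer_
}

# classical IPF on the joint contingency table of margin variables;
# returns per-cell weight factors (fitted / observed)
ipf_oracle <- function(joint, targets, tol = 1e-12, max_iter = 10000L) {
  fitted <- joint
  total <- sum(joint)
  nd <- length(dim(joint))
  for (iter in seq_len(max_iter)) {
    for (d in seq_len(nd)) {
      marg <- apply(fitted, d, sum)
      factor_d <- ifelse(marg > 0, targets[[d]] * total / marg, 1)
      fitted <- sweep(fitted, d, factor_d, "*")
    }
    err <- max(vapply(seq_len(nd), function(d) {
      max(abs(apply(fitted, d, sum) / total - targets[[d]]))
    }, numeric(1)))
    if (err < tol) break
  }
  ifelse(joint > 0, fitted / joint, NA)
}

# textbook Pearson chi-squared
chi2_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - E)^2 / E),
       df = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}

# Cochran-Armitage trend statistic from its defining formula
trend_oracle <- function(successes, totals, scores = seq_along(successes)) {
  N <- sum(totals)
  p <- sum(successes) / N
  num <- sum(successes * scores) - p * sum(totals * scores)
  den <- p * (1 - p) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  num^2 / den
}

# weighted quantile via sample expansion (integer weights only)
expanded_quantile <- function(x, w, p) {
  expanded <- sort(rep(x, w))
  expanded[max(1L, ceiling(p * length(expanded)))]
}

# per-contact tally of the mean contact matrix, nested loops, no weights
# vectorisation shared with the implementation
matrix_oracle <- function(survey, weights, scheme) {
  pt <- survey$participants
  k <- length(scheme$breaks)
  num <- matrix(0, k, k)
  denom <- numeric(k)
  for (p in seq_len(nrow(pt))) {
    bi <- band_oracle(pt$age[p], scheme$breaks)
    denom[bi] <- denom[bi] + weights[p]
  }
  for (r in seq_len(nrow(survey$contacts))) {
    row <- survey$contacts[r, ]
    p <- which(pt$participant_id == row$participant_id)
    bi <- band_oracle(pt$age[p], scheme$breaks)
    age <- if (!is.na(row$contact_age_exact)) row$contact_age_exact else
      floor((row$contact_age_min + row$contact_age_max) / 2)
    if (is.na(age)) next
    bj <- band_oracle(age, scheme$breaks)
    num[bi, bj] <- num[bi, bj] + weights[p]
  }
  out <- num / denom
  out[denom == 0, ] <- NA
  out
}

# hand application of the reciprocity formula, elementwise
reciprocity_oracle <- function(C, N) {
  k <- nrow(C)
  out <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- (C[i, j] * N[i] + C[j, i] * N[j]) / (2 * N[i])
    }
  }
  out
}

# wrap a bare matrix as an unadjusted contact_matrix object
new_cm_for_test <- function(C, scheme) {
  k <- length(scheme$breaks)
  dimnames(C) <- list(participant = scheme$labels,
                      contactee = scheme$labels)
  structure(list(values = C, scheme = scheme, n_participants = rep(1L, k),
                 sum_weights = rep(1, k), stratum = "all",
                 setting_label = "all", adjusted = FALSE,
                 n_dropped_missing_age = 0L),
            class = "contact_matrix")
}

unadjust_for_test <- function(m) { m$adjusted <- FALSE; m }
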