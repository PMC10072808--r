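## Synthetic contact-survey generator with known ground truth.
##
## The generator emulates the statistical structure of a quota-sampled,
## diary-based contact survey in a young, majority-rural population:
## recruitment quotas by age band x sex x residence, negative-binomial
## contact degrees, an age-assortative mixing kernel with intergenerational
## side-bands, per-setting duration/physicality/distance sub-models, and
## relegation of a (non-physical-biased) subset of contacts to coarse-band
## supplementary reporting.

# deterministic sub-seed per generation stage, derived from one master seed
substream <- function(seed, k) {
  set.seed((as.integer(seed) %% 1000000L) * 1009L + 7919L * k)
}

#' Generator configuration
#'
#' All tunable parameters of the synthetic-survey generator. Defaults
#' describe the reference study conditions: 2016 participants recruited to
#' an equal quota of 72 per age-band x sex x residence stratum (7 x 2 x 2
#' strata), a young, 75% rural population, a mean total contact degree of
#' about 30 per day with NB overdispersion, rural and weekend multiplicative
#' effects on degree, and about half of contacts relegated to supplementary
#' reporting with relegation biased toward non-physical contacts.
#'
#' @param n_participants total sample size (must fill the quota design
#'   exactly).
#' @param seed master seed; every sub-model draws from a named substream
#'   derived from it.
#' @param population_total,urban_share,pyramid_shape population-table
#'   parameters (see [generate_population()]).
#' @param kernel list of mixing-kernel parameters: `assort_sd` (years,
#'   bandwidth of the age-assortative ridge), `intergen_offset` (years,
#'   parent-child generation gap), `intergen_amp` and `background`
#'   (amplitudes relative to the assortative ridge), `mean_degree`
#'   (population-mean total contacts per day).
#' @param degree_model list: `coefficients` (named log-rate effects `rural`,
#'   `weekend`, `female` added to the kernel-implied band mean) and
#'   `dispersion` (NB size parameter, > 0).
#' @param supplementary_model list: `p_physical`, `p_nonphysical` —
#'   probability that a (non-)physical contact is relegated from the diary
#'   to supplementary reporting. Set both to 0 to disable relegation.
#' @param multi_setting_prob probability a contact reports a second setting.
#' @param school_ages,work_ages inclusive age ranges within which the school
#'   and work settings are offered (work additionally requires an employed
#'   participant and contactee of working age).
#' @param employment_targets assumed population shares of employment status
#'   (used as the raking target margin of the synthetic world).
#' @param prop_weekday probability a diary day is a weekday.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 2016,
                             seed = 1L,
                             population_total = 1000000L,
                             urban_share = 0.25,
                             pyramid_shape = 0.12,
                             kernel = list(assort_sd = 7.5,
                                           intergen_offset = 27,
                                           intergen_amp = 0.5,
                                           background = 0.15,
                                           mean_degree = 30),
                             degree_model = list(
                               coefficients = c(rural = log(1.23),
                                                weekend = log(0.81),
                                                female = 0),
                               dispersion = 1.5),
                             supplementary_model = list(p_physical = 0.30,
                                                        p_nonphysical = 0.55),
                             multi_setting_prob = 0.03,
                             school_ages = c(3, 24),
                             work_ages = c(15, 64),
                             employment_targets = c(`non-working-age` = 0.45,
                                                    employed = 0.45,
                                                    unemployed = 0.10),
                             prop_weekday = 0.852) {
  if (degree_model$dispersion <= 0) {
    stop("NB dispersion must be positive", call. = FALSE)
  }
  probs <- c(supplementary_model$p_physical,
             supplementary_model$p_nonphysical, multi_setting_prob,
             urban_share, prop_weekday)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(unlist(kernel[c("assort_sd", "intergen_amp", "background",
                          "mean_degree")]) < 0)) {
    stop("kernel rates must be non-negative", call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

# base setting weights; roughly: over half of contacts at home, few on
# transport/leisure, a large unspecified-'other' share
SETTING_BASE_WEIGHTS <- c(home_household = 0.30, home_nonhousehold = 0.26,
                          work = 0.09, school = 0.12, transport = 0.004,
                          leisure = 0.003, other = 0.223)

DURATION_BY_SETTING <- rbind(
  home_household    = c(0.05, 0.10, 0.25, 0.30, 0.30),
  home_nonhousehold = c(0.15, 0.25, 0.30, 0.20, 0.10),
  work              = c(0.10, 0.15, 0.25, 0.30, 0.20),
  school            = c(0.05, 0.10, 0.20, 0.30, 0.35),
  transport         = c(0.40, 0.30, 0.20, 0.08, 0.02),
  leisure           = c(0.20, 0.30, 0.30, 0.15, 0.05),
  other             = c(0.30, 0.30, 0.25, 0.10, 0.05)
)

FREQUENCY_BY_SETTING <- rbind(
  home_household    = c(0.95, 0.03, 0.01, 0.005, 0.005),
  home_nonhousehold = c(0.35, 0.30, 0.20, 0.10, 0.05),
  work              = c(0.60, 0.25, 0.10, 0.03, 0.02),
  school            = c(0.75, 0.15, 0.06, 0.02, 0.02),
  transport         = c(0.10, 0.15, 0.25, 0.25, 0.25),
  leisure           = c(0.20, 0.25, 0.25, 0.15, 0.15),
  other             = c(0.20, 0.20, 0.25, 0.20, 0.15)
)

DISTANCE_BY_SETTING <- rbind(
  home_household    = c(0.995, 0.004, 0.001),
  home_nonhousehold = c(0.97, 0.025, 0.005),
  work              = c(0.50, 0.42, 0.08),
  school            = c(0.55, 0.40, 0.05),
  transport         = c(0.30, 0.50, 0.20),
  leisure           = c(0.70, 0.25, 0.05),
  other             = c(0.75, 0.20, 0.05)
)

# physical | duration: logistic trend so longer contacts are more often
# physical; setting-specific intercepts make home/school high-intensity
PHYSICAL_INTERCEPTS <- c(home_household = 0.8, home_nonhousehold = -0.2,
                         work = -0.8, school = 0.4, transport = -1.2,
                         leisure = -0.4, other = -0.8)
PHYSICAL_DURATION_SLOPE <- 0.55

#' Construct a reciprocity-consistent mixing kernel
#'
#' Builds the ground-truth mean contact matrix on a band scheme as a
#' mixture of an age-assortative Gaussian ridge, two intergenerational
#' side-bands at +/- the generation offset, and a uniform background, then
#' symmetrises it against the population via
#' `M_ij = (K_ij N_i + K_ji N_j) / (2 N_i)` so that `M_ij N_i = M_ji N_j`
#' holds by construction, and finally rescales so the population-weighted
#' mean row sum equals `mean_degree`.
#'
#' @param population a [population_table] on the target scheme.
#' @param kernel kernel parameter list (see [generator_config()]).
#' @return a band x band matrix satisfying the reciprocity identity.
#' @export
ground_truth_kernel <- function(population, kernel) {
  scheme <- population$scheme
  a <- band_midpoints(scheme)
  d <- outer(a, a, "-")
  K <- exp(-d^2 / (2 * kernel$assort_sd^2)) +
    kernel$intergen_amp * (exp(-(d - kernel$intergen_offset)^2 / (2 * 8^2)) +
                           exp(-(d + kernel$intergen_offset)^2 / (2 * 8^2))) +
    kernel$background
  N <- population$N
  M <- (sweep(K, 1L, N, "*") + t(sweep(K, 1L, N, "*"))) / 2
  M <- sweep(M, 1L, N, "/")
  mean_deg <- sum(N * rowSums(M)) / sum(N)
  M <- M * kernel$mean_degree / mean_deg
  dimnames(M) <- list(participant = scheme$labels, contactee = scheme$labels)
  M
}

# per-contact setting weights given participant age/employment and
# contactee age; household affinity concentrates home-household contacts on
# same-age and one-generation-apart pairs (multigenerational households)
setting_weights <- function(p_age, employed, c_age, config) {
  d <- p_age - c_age
  hh_aff <- exp(-d^2 / (2 * 6^2)) +
    0.9 * exp(-(abs(d) - 27)^2 / (2 * 8^2)) + 0.15
  sa <- config$school_ages
  wa <- config$work_ages
  W <- cbind(
    home_household = SETTING_BASE_WEIGHTS["home_household"] * hh_aff / 0.6,
    home_nonhousehold = SETTING_BASE_WEIGHTS["home_nonhousehold"],
    work = SETTING_BASE_WEIGHTS["work"] *
      (employed & c_age >= wa[1] & c_age <= wa[2]),
    school = SETTING_BASE_WEIGHTS["school"] * 2.5 *
      (p_age >= sa[1] & p_age <= sa[2] & c_age >= sa[1] & c_age <= sa[2]),
    transport = SETTING_BASE_WEIGHTS["transport"],
    leisure = SETTING_BASE_WEIGHTS["leisure"],
    other = SETTING_BASE_WEIGHTS["other"]
  )
  colnames(W) <- SETTING_LEVELS
  W
}

sample_categorical <- function(prob_matrix) {
  # one draw per row; Gumbel-max over log-probabilities
  G <- -log(-log(matrix(stats::runif(length(prob_matrix)),
                        nrow(prob_matrix))))
  max.col(log(prob_matrix) + G)
}

uniform_age_in_band <- function(band_idx, scheme, upper_age = 90L) {
  lo <- scheme$breaks[band_idx]
  hi <- c(scheme$breaks[-1L] - 1L, upper_age)[band_idx]
  lo + floor(stats::runif(length(band_idx)) * (hi - lo + 1L))
}

assign_occupation <- function(age) {
  n <- length(age)
  occ <- character(n)
  occ[age < 3] <- "child_at_home"
  pre <- age >= 3 & age <= 5
  occ[pre] <- ifelse(stats::runif(sum(pre)) < 0.7, "pre_schooler",
                     "child_at_home")
  sch <- age >= 6 & age <= 18
  occ[sch] <- "student"
  young <- age >= 19 & age <= 24
  occ[young] <- sample(c("student", "professional_office",
                         "shop_worker_trader", "manual_labour_nonagri",
                         "agriculture_fishing", "housewife", "unemployed",
                         "others"),
                       sum(young), replace = TRUE,
                       prob = c(0.35, 0.05, 0.10, 0.08, 0.25, 0.05, 0.07,
                                0.05))
  adult <- age >= 25 & age < 65
  occ[adult] <- sample(c("professional_office", "shop_worker_trader",
                         "manual_labour_nonagri", "agriculture_fishing",
                         "housewife", "retired", "unemployed", "others"),
                       sum(adult), replace = TRUE,
                       prob = c(0.07, 0.14, 0.10, 0.40, 0.14, 0.01, 0.08,
                                0.06))
  old <- age >= 65
  occ[old] <- sample(c("retired", "agriculture_fishing", "housewife",
                       "others"),
                     sum(old), replace = TRUE,
                     prob = c(0.65, 0.15, 0.15, 0.05))
  occ
}

sample_travel <- function(residence, scope) {
  p_never <- switch(scope,
    commune = c(urban = 0.05, rural = 0.15),
    district = c(urban = 0.20, rural = 0.35),
    province = c(urban = 0.45, rural = 0.68),
    country = c(urban = 0.89, rural = 0.98)
  )
  cond <- if (scope %in% c("commune", "district")) c(0.2, 0.3, 0.3, 0.2)
          else c(0.55, 0.30, 0.10, 0.05)
  n <- length(residence)
  never <- stats::runif(n) < p_never[residence]
  out <- rep(NA_character_, n)
  out[never] <- "never"
  k <- sum(!never)
  if (k) {
    out[!never] <- sample(c("yearly", "monthly", "weekly", "daily"), k,
                          replace = TRUE, prob = cond)
  }
  out
}

#' Generate a synthetic contact survey with known ground truth
#'
#' Produces a quota-exact participant sample, negative-binomial diary
#' degrees, contactee ages drawn from the row of the reciprocity-consistent
#' ground-truth kernel for the participant's band, per-contact settings /
#' duration / physicality / frequency / distance from the configured
#' sub-models, and a seed-reproducible relegation of contacts to coarse-band
#' supplementary reporting. Runs with the same config (including seed) are
#' identical.
#'
#' @param config a [generator_config()].
#' @return list with elements `survey` (a [contact_survey]) and
#'   `ground_truth` (class `ground_truth`: `true_matrix`, the expected
#'   total mixing matrix on the 14-band scheme satisfying the reciprocity
#'   identity; `degree_coefficients`; `dispersion`; `populations` (urban,
#'   rural, all [population_table]s); `weights_target_margins` (list of
#'   [margin_spec]s of the synthetic world); `config`).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  design <- sampling_design(total_target = config$n_participants)
  mscheme <- standard_scheme("matrix")

  pops <- generate_population(
    mscheme, c(urban = config$urban_share, rural = 1 - config$urban_share),
    config$population_total, config$pyramid_shape)
  pop_all <- combine_populations(pops$urban, pops$rural)
  M <- ground_truth_kernel(pop_all, config$kernel)

  # quota feasibility: each sampling band x residence stratum must contain
  # at least the number of people recruited from it
  per_band_needed <- design$quota_per_stratum * length(design$sexes)
  for (res in RESIDENCE_LEVELS) {
    band_pop <- project_population(pops[[res]], design$scheme)$N
    if (any(band_pop < per_band_needed)) {
      stop("quota of ", per_band_needed, " per band exceeds the ", res,
           " population of band '",
           design$scheme$labels[which(band_pop < per_band_needed)[1L]],
           "'", call. = FALSE)
    }
  }

  ## -- participants (quota met exactly, by construction) ----------------
  cells <- expand.grid(band = seq_len(n_bands(design$scheme)),
                       sex = SEX_LEVELS, residence = RESIDENCE_LEVELS,
                       stringsAsFactors = FALSE)
  q <- design$quota_per_stratum
  n <- nrow(cells) * q
  band_s <- rep(cells$band, each = q)
  sex <- rep(cells$sex, each = q)
  residence <- rep(cells$residence, each = q)

  substream(config$seed, 1L)
  age <- uniform_age_in_band(band_s, design$scheme, upper_age = 85L)
  district <- paste0(ifelse(residence == "urban", "U", "R"),
                     sample(1:3, n, replace = TRUE))
  day_type <- ifelse(stats::runif(n) < config$prop_weekday,
                     "weekday", "weekend")
  occupation <- assign_occupation(age)
  employment <- derive_employment_status(occupation, age)
  household_size <- 1L + stats::rpois(n, 3.6)
  n_rooms <- sample(N_ROOMS_LEVELS, n, replace = TRUE,
                    prob = c(0.57, 0.23, 0.11, 0.055, 0.035))
  diary_complete <- stats::runif(n) < 0.42

  participants <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age = age, sex = sex, residence = residence, district_id = district,
    occupation = occupation, household_size = household_size,
    n_rooms = n_rooms, diary_day_type = day_type,
    employment_status = employment, diary_complete = diary_complete,
    stringsAsFactors = FALSE
  )
  substream(config$seed, 2L)
  for (scope in TRAVEL_SCOPES) {
    participants[[paste0("travel_", scope)]] <- sample_travel(residence,
                                                              scope)
  }

  ## -- degrees and contactee bands --------------------------------------
  substream(config$seed, 3L)
  band_m <- assign_age_band(age, mscheme)
  beta <- config$degree_model$coefficients
  eta <- log(rowSums(M))[band_m] +
    beta["rural"] * (residence == "rural") +
    beta["weekend"] * (day_type == "weekend") +
    beta["female"] * (sex == "female")
  mu <- exp(unname(eta))
  degree <- stats::rnbinom(n, size = config$degree_model$dispersion, mu = mu)

  substream(config$seed, 4L)
  pid <- rep(participants$participant_id, degree)
  p_band <- rep(band_m, degree)
  p_age <- rep(age, degree)
  p_emp <- rep(employment == "employed", degree)
  nc <- length(pid)
  # contactee band: multinomial along the participant's kernel row
  c_band <- integer(nc)
  for (i in seq_len(n_bands(mscheme))) {
    sel <- p_band == i
    if (any(sel)) {
      c_band[sel] <- sample.int(n_bands(mscheme), sum(sel), replace = TRUE,
                                prob = M[i, ])
    }
  }
  c_age <- uniform_age_in_band(c_band, mscheme, upper_age = 90L)

  ## -- settings, duration, physicality, frequency, distance -------------
  substream(config$seed, 5L)
  W <- setting_weights(p_age, p_emp, c_age, config)
  s1 <- sample_categorical(W)
  settings <- SETTING_LEVELS[s1]
  multi <- stats::runif(nc) < config$multi_setting_prob
  if (any(multi)) {
    W2 <- W[multi, , drop = FALSE]
    W2[cbind(seq_len(nrow(W2)), s1[multi])] <- 0
    ok2 <- rowSums(W2) > 0
    s2 <- rep(NA_integer_, nrow(W2))
    s2[ok2] <- sample_categorical(W2[ok2, , drop = FALSE])
    add <- !is.na(s2)
    settings[multi][add] <- paste(settings[multi][add],
                                  SETTING_LEVELS[s2[add]], sep = ";")
  }

  substream(config$seed, 6L)
  dur_idx <- sample_categorical(DURATION_BY_SETTING[s1, , drop = FALSE])
  duration <- DURATION_LEVELS[dur_idx]
  p_phys <- stats::plogis(PHYSICAL_INTERCEPTS[s1] +
                            PHYSICAL_DURATION_SLOPE * (dur_idx - 3))
  physical <- stats::runif(nc) < p_phys
  freq_idx <- sample_categorical(FREQUENCY_BY_SETTING[s1, , drop = FALSE])
  dist_idx <- sample_categorical(DISTANCE_BY_SETTING[s1, , drop = FALSE])

  contacts <- data.frame(
    participant_id = pid,
    contact_age_exact = as.numeric(c_age),
    contact_age_min = NA_real_, contact_age_max = NA_real_,
    settings = settings, physical = physical,
    duration_cat = duration,
    frequency_cat = FREQUENCY_LEVELS[freq_idx],
    distance_cat = DISTANCE_LEVELS[dist_idx],
    stringsAsFactors = FALSE
  )

  ## -- relegation to supplementary reporting ----------------------------
  substream(config$seed, 7L)
  pr <- ifelse(physical, config$supplementary_model$p_physical,
               config$supplementary_model$p_nonphysical)
  relegated <- stats::runif(nc) < pr
  supp <- empty_supplementary()
  if (any(relegated)) {
    sscheme <- standard_scheme("supplementary")
    sb <- band_label(c_age[relegated], sscheme)
    agg <- stats::aggregate(
      list(count = rep(1L, sum(relegated))),
      by = list(participant_id = pid[relegated], band = as.character(sb),
                physical = physical[relegated]),
      FUN = sum)
    agg <- agg[order(agg$participant_id, agg$band, agg$physical), ,
               drop = FALSE]
    supp <- agg[, SUPP_COLS]
  }
  contacts <- contacts[!relegated, , drop = FALSE]
  rownames(contacts) <- NULL
  rownames(supp) <- NULL

  survey <- contact_survey(participants, contacts, supp)

  margins <- population_margins(
    pops, employment_targets = config$employment_targets,
    day_type_targets = c(weekday = config$prop_weekday,
                         weekend = 1 - config$prop_weekday))

  ground_truth <- structure(list(
    true_matrix = M,
    degree_coefficients = beta,
    dispersion = config$degree_model$dispersion,
    populations = c(pops, list(all = pop_all)),
    weights_target_margins = margins,
    config = config
  ), class = "ground_truth")

  list(survey = survey, ground_truth = ground_truth)
}

#' Expected per-setting mixing matrices of the generator
#'
#' Exact conditional expectation (given the realised participants, unit
#' weights, no relegation) of each setting-stratified mean contact matrix,
#' integrating the setting sub-model over contactee age within each band.
#' Used to verify structural properties such as the confinement of school
#' contacts to school ages.
#'
#' @param survey the generated [contact_survey].
#' @param ground_truth the matching `ground_truth` object.
#' @return named list of band x band expected matrices, one per canonical
#'   setting token, plus `total` (equal to `true_matrix` when degree
#'   covariate effects are zero).
#' @export
expected_setting_matrices <- function(survey, ground_truth) {
  config <- ground_truth$config
  M <- ground_truth$true_matrix
  mscheme <- standard_scheme("matrix")
  k <- n_bands(mscheme)
  pt <- survey$participants
  band_m <- assign_age_band(pt$age, mscheme)
  emp <- pt$employment_status == "employed"
  beta <- ground_truth$degree_coefficients
  mu <- exp(log(rowSums(M))[band_m] +
              beta["rural"] * (pt$residence == "rural") +
              beta["weekend"] * (pt$diary_day_type == "weekend") +
              beta["female"] * (pt$sex == "female"))
  p_alloc <- sweep(M, 1L, rowSums(M), "/")

  lo <- mscheme$breaks
  hi <- c(mscheme$breaks[-1L] - 1L, 90L)
  out <- lapply(SETTING_LEVELS, function(s) matrix(0, k, k,
    dimnames = dimnames(M)))
  names(out) <- SETTING_LEVELS
  total <- matrix(0, k, k, dimnames = dimnames(M))

  # group participants by (exact age, employed) within each band
  for (i in seq_len(k)) {
    sel <- which(band_m == i)
    if (!length(sel)) {
      for (s in SETTING_LEVELS) out[[s]][i, ] <- NA
      total[i, ] <- NA
      next
    }
    groups <- stats::aggregate(list(mu_sum = mu[sel]),
                               by = list(age = pt$age[sel], emp = emp[sel]),
                               FUN = sum)
    for (j in seq_len(k)) {
      ages_j <- lo[j]:hi[j]
      for (g in seq_len(nrow(groups))) {
        Wg <- setting_weights(rep(groups$age[g], length(ages_j)),
                              groups$emp[g], ages_j, config)
        Pg <- colMeans(sweep(Wg, 1L, rowSums(Wg), "/"))
        contrib <- groups$mu_sum[g] * p_alloc[i, j] / length(sel)
        for (s in SETTING_LEVELS) {
          out[[s]][i, j] <- out[[s]][i, j] + contrib * Pg[s]
        }
      }
      total[i, j] <- sum(groups$mu_sum) * p_alloc[i, j] / length(sel)
    }
  }
  c(out, list(total = total))
}
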