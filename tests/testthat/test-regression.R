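test_that("an intercept-only-like fit recovers the NB mean", {
  set.seed(51)
  n <- 5000
  y <- rnbinom(n, size = 1, mu = 18)
  sv <- degree_survey(y, sex = rep(c("male", "female"), n / 2))
  fit <- fit_nb_model(sv, response = "degree_total", covariates = "sex")
  mu_hat <- exp(fit$coefficients[["(Intercept)"]])
  se <- sqrt((18 + 18^2 / 1) / n)  # NB variance of the sample mean
  expect_lt(abs(mu_hat - 18), 3 * se * 2)  # intercept is the male mean
  # null covariate: relative rate CI covers 1
  rr <- fit$relative_rates[fit$relative_rates$term == "sexfemale", ]
  expect_gt(rr$conf_high, 1)
  expect_lt(rr$conf_low, 1)
  expect_equal(fit$reference_levels[["sex"]], "male")
})

test_that("estimates are invariant to row permutation", {
  set.seed(52)
  n <- 400
  res <- rep(c("urban", "rural"), each = n / 2)
  y <- rnbinom(n, size = 2, mu = ifelse(res == "rural", 15, 12))
  sv <- degree_survey(y, residence = res,
                      sex = sample(c("male", "female"), n, TRUE))
  fit1 <- fit_nb_model(sv, covariates = c("residence", "sex"))
  perm <- sample(n)
  sv2 <- sv
  sv2$participants <- sv2$participants[perm, ]
  fit2 <- fit_nb_model(sv2, covariates = c("residence", "sex"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("contact hours respond as rounded minutes with unit-free rates", {
  pt <- make_participants(60, residence = rep(c("urban", "rural"), 30))
  set.seed(53)
  deg <- rpois(60, 8) + 1
  ct <- make_contacts(rep(pt$participant_id, deg),
                      sample(10:50, sum(deg), TRUE),
                      duration = sample(c("15to59min", "1to4h", "gt4h"),
                                        sum(deg), TRUE))
  sv <- contact_survey(pt, ct)
  fit <- fit_nb_model(sv, response = "contact_hours",
                      covariates = "residence")
  ps <- participant_summaries(sv)
  # fitted mean response is on the minutes scale
  expect_equal(mean(fit$data$y), mean(round(ps$total_contact_hours * 60)))
  expect_true(all(fit$relative_rates$conf_low <=
                    fit$relative_rates$estimate))
  expect_true(all(fit$relative_rates$conf_high >=
                    fit$relative_rates$estimate))
})

test_that("term ANOVA has the right df and detects strong effects", {
  set.seed(54)
  n <- 800
  age <- sample(c(2, 10, 20, 30, 40, 50, 60, 70), n, TRUE)  # 8 bands
  res <- sample(c("urban", "rural"), n, TRUE)
  y <- rnbinom(n, size = 2, mu = exp(log(10) + log(3) * (res == "rural")))
  sv <- degree_survey(y, residence = res, age = age)
  fit <- fit_nb_model(sv, covariates = c("residence", "age_band"))
  an <- term_anova(fit)
  expect_equal(an$df[an$term == "age_band"], 7L)
  expect_equal(an$df[an$term == "residence"], 1L)
  # a tripling of degree dwarfs the 0.1% critical value at df 1
  expect_gt(an$statistic[an$term == "residence"], qchisq(0.999, 1))
  expect_gt(an$p[an$term == "age_band"], 0.001)  # null age term
})

test_that("likelihood-ratio p-values are calibrated under the null", {
  set.seed(55)
  n_reps <- 200
  n <- 300
  pvals <- vapply(seq_len(n_reps), function(r) {
    sex <- rep(c("male", "female"), n / 2)
    res <- sample(c("urban", "rural"), n, TRUE)
    y <- rnbinom(n, size = 1.5, mu = ifelse(res == "rural", 14, 10))
    sv <- degree_survey(y, residence = res, sex = sex)
    fit <- fit_nb_model(sv, covariates = c("residence", "sex"))
    an <- term_anova(fit)
    an$p[an$term == "sex"]  # sex has no true effect
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate single-level covariates are refused", {
  sv <- degree_survey(rpois(50, 5) + 1)
  expect_error(fit_nb_model(sv, covariates = c("residence", "sex")),
               "degenerate")
})

test_that("weighted fits shift estimates toward up-weighted strata", {
  set.seed(56)
  n <- 600
  res <- rep(c("urban", "rural"), each = n / 2)
  y <- rnbinom(n, size = 3, mu = ifelse(res == "rural", 20, 10))
  sv <- degree_survey(y, residence = res,
                      sex = sample(c("male", "female"), n, TRUE))
  w_rural <- ifelse(res == "rural", 2, 0.5)
  fit_u <- fit_nb_model(sv, covariates = c("residence", "sex"))
  fit_w <- fit_nb_model(sv, weights = w_rural,
                        covariates = c("residence", "sex"))
  # the rural/urban contrast is unchanged, but its SE reflects the weights
  expect_equal(unname(fit_w$coefficients["residencerural"]),
               unname(fit_u$coefficients["residencerural"]),
               tolerance = 0.05)
  expect_gt(fit_w$dispersion, 0)
})
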