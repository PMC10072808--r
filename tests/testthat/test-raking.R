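test_that("a sample already at the targets is a fixed point", {
  pt <- make_participants(4, residence = c("urban", "urban", "rural",
                                           "rural"))
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  w <- rake_weights(sv, list(margin_spec("residence",
                                         c(urban = 0.5, rural = 0.5))))
  expect_equal(unname(w$weights), rep(1, 4))
  expect_true(w$converged)
})

test_that("a single margin has the closed-form solution in one pass", {
  pt <- make_participants(10, residence = c(rep("urban", 8),
                                            rep("rural", 2)))
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  w <- rake_weights(sv, list(margin_spec("residence",
                                         c(urban = 0.6, rural = 0.4))))
  # target share / sample share: 0.6/0.8 and 0.4/0.2, normalised to mean 1
  expect_equal(unname(w$weights), c(rep(0.75, 8), rep(2, 2)))
  expect_lte(margin_deviation(w, sv, list(margin_spec("residence",
             c(urban = 0.6, rural = 0.4)))), 1e-8)
})

test_that("two crossed margins match the classical IPF solution", {
  counts <- matrix(c(30, 10, 10, 50), 2, byrow = TRUE,
                   dimnames = list(c("urban", "rural"),
                                   c("weekday", "weekend")))
  pt <- make_participants(100)
  pt$residence <- rep(c("urban", "urban", "rural", "rural"),
                      times = c(30, 10, 10, 50))
  pt$diary_day_type <- rep(c("weekday", "weekend", "weekday", "weekend"),
                           times = c(30, 10, 10, 50))
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  specs <- list(margin_spec("residence", c(urban = 0.5, rural = 0.5)),
                margin_spec("diary_day_type",
                            c(weekday = 0.5, weekend = 0.5)))
  w <- rake_weights(sv, specs, tol = 1e-12)
  oracle <- ipf_oracle(counts, list(c(0.5, 0.5), c(0.5, 0.5)))
  oracle <- oracle / stats::weighted.mean(oracle, counts)  # mean-1 normalise
  cell <- oracle[cbind(match(pt$residence, rownames(counts)),
                       match(pt$diary_day_type, colnames(counts)))]
  expect_equal(unname(w$weights), unname(cell), tolerance = 1e-10)
})

test_that("raking equals brute-force IPF on random 3-variable instances", {
  set.seed(41)
  for (rep_i in 1:12) {
    n_age <- sample(2:5, 1)
    ages <- c(2, 10, 20, 30, 47)[seq_len(n_age)]  # distinct regression bands
    pt <- make_participants(300,
      residence = sample(c("urban", "rural"), 300, TRUE),
      day_type = sample(c("weekday", "weekend"), 300, TRUE))
    pt$age <- sample(ages, 300, TRUE)
    sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
    rscheme <- standard_scheme("regression")
    age_levels <- levels(droplevels(band_label(pt$age, rscheme)))
    rt <- function(k) { x <- runif(k) + 0.2; x / sum(x) }
    t_res <- rt(2); names(t_res) <- c("urban", "rural")
    t_day <- rt(2); names(t_day) <- c("weekday", "weekend")
    t_age <- rt(n_age); names(t_age) <- age_levels
    specs <- list(margin_spec("residence", t_res),
                  margin_spec("diary_day_type", t_day),
                  margin_spec("age_band", t_age))
    w <- rake_weights(sv, specs, tol = 1e-12, max_iter = 5000)
    joint <- table(factor(pt$residence, names(t_res)),
                   factor(pt$diary_day_type, names(t_day)),
                   factor(as.character(band_label(pt$age, rscheme)),
                          names(t_age)))
    oracle <- ipf_oracle(joint, list(t_res, t_day, t_age))
    oracle <- oracle / stats::weighted.mean(oracle[joint > 0],
                                            joint[joint > 0])
    cell <- oracle[cbind(match(pt$residence, names(t_res)),
                         match(pt$diary_day_type, names(t_day)),
                         match(as.character(band_label(pt$age, rscheme)),
                               names(t_age)))]
    expect_equal(unname(w$weights), unname(cell), tolerance = 1e-8)
  }
})

test_that("raking is idempotent and scale-invariant", {
  set.seed(7)
  pt <- make_participants(120,
    residence = sample(c("urban", "rural"), 120, TRUE),
    day_type = sample(c("weekday", "weekend"), 120, TRUE))
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  specs <- list(margin_spec("residence", c(urban = 0.3, rural = 0.7)),
                margin_spec("diary_day_type",
                            c(weekday = 5 / 7, weekend = 2 / 7)))
  w1 <- rake_weights(sv, specs)
  w2 <- rake_weights(sv, specs, init = w1$weights)
  expect_equal(w1$weights, w2$weights, tolerance = 1e-7)
  w3 <- rake_weights(sv, specs, init = rep(17, 120))
  expect_equal(w1$weights, w3$weights, tolerance = 1e-7)
})

test_that("margin deviation reports hand-computable and degenerate cases", {
  pt <- make_participants(10, residence = c(rep("urban", 6),
                                            rep("rural", 4)))
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  spec <- list(margin_spec("residence", c(urban = 0.5, rural = 0.5)))
  # weighted share 0.6 vs target 0.5 -> |0.6 - 0.5| / 0.5 = 0.2
  expect_equal(margin_deviation(rep(1, 10), sv, spec), 0.2)

  balanced <- make_participants(10, residence = rep(c("urban", "rural"), 5))
  svb <- contact_survey(balanced, make_contacts(character(0), numeric(0)))
  expect_equal(margin_deviation(rep(1, 10), svb, spec), 0)

  spec0 <- list(margin_spec("residence", c(urban = 1, rural = 0)))
  expect_equal(margin_deviation(rep(1, 10), sv, spec0), Inf)
})

test_that("empty sample levels with positive target are an error", {
  pt <- make_participants(5, residence = "urban")
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  expect_error(
    rake_weights(sv, list(margin_spec("residence",
                                      c(urban = 0.5, rural = 0.5)))),
    "rural")
})

test_that("trimming bounds extreme weights and re-rakes", {
  pt <- make_participants(101, residence = c(rep("urban", 100), "rural"))
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  specs <- list(margin_spec("residence", c(urban = 0.5, rural = 0.5)))
  w_free <- rake_weights(sv, specs)
  expect_gt(max(w_free$weights), 5)
  w_trim <- rake_weights(sv, specs, trim_bounds = c(0.2, 5))
  expect_lte(max(w_trim$weights) / mean(w_trim$weights), 5 * 1.01)
  # the quota this sample cannot meet within bounds is reported honestly
  expect_false(w_trim$converged)
  expect_gt(w_trim$max_margin_error, 1e-8)
})
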