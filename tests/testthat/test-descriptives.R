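test_that("duration midpoints follow the right-truncated convention", {
  expect_equal(duration_midpoint_minutes(
    c("lt5min", "5to14min", "15to59min", "1to4h", "gt4h")),
    c(2.5, 9.5, 37, 150, 240))
  expect_error(duration_midpoint_minutes("forever"), "unknown")
})

test_that("participant summaries decompose degree and sum hours", {
  pt <- make_participants(2)
  ct <- rbind(make_contacts("P001", 20, duration = "15to59min"),
              make_contacts("P001", 30, duration = "gt4h"))
  sp <- data.frame(participant_id = "P001", band = "16-64",
                   physical = TRUE, count = 3L)
  sv <- contact_survey(pt, ct, sp)
  ps <- participant_summaries(sv)
  p1 <- ps[ps$participant_id == "P001", ]
  expect_equal(p1$degree_diary, 2L)
  expect_equal(p1$degree_supplementary, 3L)
  expect_equal(p1$degree_total, 5L)
  expect_equal(p1$total_contact_hours, (37 + 240) / 60)
  p2 <- ps[ps$participant_id == "P002", ]
  expect_equal(p2$degree_total, 0L)
  expect_equal(p2$total_contact_hours, 0)
  # decomposition identity for every participant
  expect_equal(ps$degree_total, ps$degree_diary + ps$degree_supplementary)
})

test_that("weighted quantiles invert the weighted ECDF from the left", {
  # toy case with integer weights: agrees with sample-expansion oracle
  x <- c(1, 2, 10); w <- c(1, 1, 2)
  expect_equal(weighted_median(x, w), expanded_quantile(x, w, 0.5))
  set.seed(13)
  for (rep_i in 1:20) {
    x <- sample(0:50, 9, TRUE)
    w <- sample(1:4, 9, TRUE)
    for (p in c(0.25, 0.5, 0.75)) {
      expect_equal(weighted_quantile(x, w, p), expanded_quantile(x, w, p))
    }
  }
  # equal weights reduce to the unweighted type-1 quantile
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(weighted_quantile(x, probs = c(0.25, 0.5, 0.9)),
               unname(quantile(x, c(0.25, 0.5, 0.9), type = 1)))
})

test_that("setting proportions use the exclusive 'multiple' display", {
  pt <- make_participants(1, age = 10)
  ct <- rbind(
    make_contacts("P001", 12, settings = "home_household"),
    make_contacts("P001", 12, settings = "home_household;school"),
    make_contacts("P001", 40, settings = "transport"),
    make_contacts("P001", 40, settings = "work"))
  sv <- contact_survey(pt, ct)
  tab <- setting_proportions(sv)
  expect_equal(sum(tab$proportions), 1, tolerance = 1e-12)
  expect_equal(tab$proportions[1, "home_household"], 0.25)
  expect_equal(tab$proportions[1, "multiple"], 0.25)   # home+school
  expect_equal(tab$proportions[1, "other"], 0.25)      # transport merged
  expect_equal(tab$proportions[1, "work"], 0.25)

  only_home <- contact_survey(pt, make_contacts("P001", c(12, 14),
                                                settings = "home_household"))
  expect_equal(setting_proportions(only_home)$proportions[1,
               "home_household"], 1)
})

test_that("group-wise proportions are weighted and rows sum to 1", {
  gen <- generate_survey(generator_config(n_participants = 224, seed = 6))
  w <- rake_weights(gen$survey, gen$ground_truth$weights_target_margins)
  tab <- setting_proportions(gen$survey, w, groupby = "residence")
  expect_equal(unname(rowSums(tab$proportions)), c(1, 1), tolerance = 1e-12)
})

test_that("Pearson chi-squared equals the textbook formula", {
  res <- chi2_independence(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$df, 1L)
  expect_equal(res$p, 1)

  res2 <- chi2_independence(matrix(c(20, 10, 10, 20), 2))
  expect_equal(res2$statistic, 4 * 25 / 15, tolerance = 1e-12)  # 6.666...
  expect_equal(res2$df, 1L)

  expect_equal(chi2_independence(matrix(c(5, 1, 7, 2, 9, 1, 4, 4), 4))$df,
               3L)

  set.seed(31)
  for (rep_i in 1:50) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(sample(1:30, r * cc, TRUE), r, cc)
    got <- chi2_independence(tab)
    want <- chi2_oracle(tab)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }

  expect_error(chi2_independence(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("the trend test matches the Cochran-Armitage formula", {
  expect_equal(chi2_trend(c(10, 20, 30), c(100, 200, 300))$statistic, 0,
               tolerance = 1e-12)
  s <- c(5, 15, 40); n <- c(100, 100, 100)
  got <- chi2_trend(s, n)
  expect_equal(got$statistic, trend_oracle(s, n), tolerance = 1e-10)
  expect_equal(got$df, 1L)
  # invariant to reversing the level order
  rev_got <- chi2_trend(rev(s), rev(n))
  expect_equal(rev_got$statistic, got$statistic, tolerance = 1e-10)
  expect_error(chi2_trend(5, 10), "at least 2")
})

test_that("physical share rises with duration in generated diaries", {
  gen <- generate_survey(generator_config(n_participants = 560, seed = 14))
  ct <- gen$survey$contacts
  dur <- factor(ct$duration_cat, c("lt5min", "5to14min", "15to59min",
                                   "1to4h", "gt4h"))
  s <- tapply(ct$physical, dur, sum)
  n <- tapply(rep(1, nrow(ct)), dur, sum)
  res <- chi2_trend(as.numeric(s), as.numeric(n))
  expect_lt(res$p, 0.001)
  props <- s / n
  expect_gt(props[5], props[1])
})

test_that("reporting-method comparison coarsens, tests and flags", {
  # diary ages one per coarse band
  pt <- make_participants(1, age = 30)
  ct <- make_contacts("P001", c(2, 10, 30, 70),
                      physical = c(TRUE, FALSE, TRUE, FALSE))
  sp <- data.frame(participant_id = rep("P001", 4),
                   band = c("0-4", "5-15", "16-64", "65+"),
                   physical = c(TRUE, FALSE, TRUE, FALSE), count = 1L)
  sv <- contact_survey(pt, ct, sp)
  rc <- reporting_method_comparison(sv)
  expect_true(rc$applicable)
  expect_equal(unname(rc$age_table[, "diary"]), c(1, 1, 1, 1))
  # identical age distributions across methods -> zero statistic
  expect_equal(rc$age_test$statistic, 0, tolerance = 1e-12)
  expect_equal(rc$age_test$df, 3L)
  expect_equal(rc$physical_test$df, 1L)

  no_supp <- contact_survey(make_participants(1), make_contacts("P001", 20))
  expect_false(reporting_method_comparison(no_supp)$applicable)
})

test_that("physicality-biased relegation is detected at survey scale", {
  gen <- generate_survey(generator_config(n_participants = 2016, seed = 15))
  rc <- reporting_method_comparison(gen$survey)
  expect_gt(rc$physical_test$statistic, 0)
  expect_lt(rc$physical_test$p, 0.05)
})

test_that("distance tables keep missing as its own category", {
  pt <- make_participants(1)
  ct <- make_contacts("P001", c(20, 20, 20), distance = "lt1km")
  ct$distance_cat[3] <- NA
  sv <- contact_survey(pt, ct)
  dm <- distance_mobility_tables(sv)
  expect_equal(dm$distance$share[dm$distance$distance == "lt1km"], 2 / 3)
  expect_equal(dm$distance$share[dm$distance$distance == "missing"], 1 / 3)
  expect_equal(sum(dm$distance$share), 1)
  expect_null(dm$mobility)  # no travel columns present
})

test_that("mobility tables tally travel frequencies by band and residence", {
  pt <- make_participants(4, age = c(10, 10, 40, 40),
                          residence = c("urban", "urban", "rural", "rural"))
  pt$travel_province <- c("never", "weekly", "never", "never")
  sv <- contact_survey(pt, make_contacts(character(0), numeric(0)))
  dm <- distance_mobility_tables(sv)
  mob <- dm$mobility
  row <- mob[mob$age_band == "5-14" & mob$residence == "urban" &
               mob$frequency == "never" & mob$admin_level == "province", ]
  expect_equal(row$weighted_count, 1)
  expect_equal(row$share, 0.5)
  rural_never <- mob[mob$age_band == "35-44" & mob$residence == "rural" &
                       mob$frequency == "never" &
                       mob$admin_level == "province", ]
  expect_equal(rural_never$share, 1)
})
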