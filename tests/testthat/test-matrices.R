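scheme14 <- standard_scheme("matrix")

test_that("single-participant arithmetic lands in the right band", {
  pt <- make_participants(1, age = 10)
  sv <- contact_survey(pt, make_contacts("P001", c(12, 12, 12)))
  m <- mean_contact_matrix(sv)
  expect_equal(m$values[3, 3], 3)       # ages 10 and 12 both in band 10-14
  expect_equal(sum(m$values, na.rm = TRUE), 3)
  expect_true(all(is.na(m$values[c(1:2, 4:14), ])))  # empty bands flagged
})

test_that("cells are weighted means of per-participant counts", {
  pt <- make_participants(2, age = c(10, 12))
  ct <- make_contacts("P001", c(30, 30, 30, 30))  # 4 contacts into band 30-34
  sv <- contact_survey(pt, ct)
  m <- mean_contact_matrix(sv, weights = c(1, 3))
  expect_equal(m$values[3, 7], 1)       # (1*4 + 3*0) / (1 + 3)
})

test_that("the high-intensity filter keeps physical OR >= 15 min", {
  pt <- make_participants(1, age = 20)
  ct <- rbind(
    make_contacts("P001", 20, physical = TRUE, duration = "lt5min"),
    make_contacts("P001", 20, physical = FALSE, duration = "lt5min"),
    make_contacts("P001", 20, physical = FALSE, duration = "15to59min"),
    make_contacts("P001", 20, physical = FALSE, duration = "5to14min"))
  sv <- contact_survey(pt, ct)
  m <- mean_contact_matrix(sv, filter = contact_filter(high_intensity = TRUE))
  expect_equal(m$values[5, 5], 2)  # physical lt5min kept, the others not
})

test_that("contacts with missing age are excluded with a logged count", {
  pt <- make_participants(1, age = 20)
  ct <- make_contacts("P001", c(20, NA))
  sv <- contact_survey(pt, ct)
  m <- mean_contact_matrix(sv)
  expect_equal(m$values[5, 5], 1)
  expect_equal(m$n_dropped_missing_age, 1L)
})

test_that("reciprocity adjustment reproduces the hand-applied formula", {
  sc <- age_band_scheme(c(0, 5), "two")
  pt <- make_participants(2, age = c(2, 7))
  ct <- make_contacts("P001", c(7, 7))
  sv <- contact_survey(pt, ct)
  m <- mean_contact_matrix(sv, scheme = sc)
  expect_equal(unname(m$values), rbind(c(0, 2), c(0, 0)))
  pop <- population_table(sc, c(100, 50))
  adj <- reciprocity_adjust(m, pop)
  expect_equal(unname(adj$values), rbind(c(0, 1), c(2, 0)))
  expect_true(adj$adjusted)
})

test_that("adjustment is exact, conservative and idempotent on random inputs", {
  set.seed(99)
  for (rep_i in 1:40) {
    k <- sample(2:14, 1)
    sc <- age_band_scheme(seq(0, by = 5, length.out = k), "rand")
    C <- matrix(rexp(k * k), k)
    N <- runif(k, 50, 5000)
    pop <- population_table(sc, N)
    m <- new_cm_for_test(C, sc)
    adj <- reciprocity_adjust(m, pop)
    T_ <- sweep(adj$values, 1, N, "*")
    expect_lt(max(abs(T_ - t(T_)) / (abs(T_) + 1e-300)), 1e-9)
    expect_equal(sum(T_), sum(sweep(C, 1, N, "*")), tolerance = 1e-9)
    expect_equal(unname(adj$values), reciprocity_oracle(C, N),
                 tolerance = 1e-12)
    again <- reciprocity_adjust(unadjust_for_test(adj), pop)
    expect_equal(again$values, adj$values, tolerance = 1e-12)
  }
})

test_that("an input already satisfying reciprocity is a fixed point", {
  sc <- age_band_scheme(c(0, 5, 10), "three")
  N <- c(100, 200, 400)
  C <- rbind(c(1, 2, 4), c(1, 3, 2), c(1, 1, 5))  # c_ij N_i = c_ji N_j
  pop <- population_table(sc, N)
  adj <- reciprocity_adjust(new_cm_for_test(C, sc), pop)
  expect_equal(unname(adj$values), C, tolerance = 1e-12)
})

test_that("missing rows are filled from the transposed term only", {
  sc <- age_band_scheme(c(0, 5), "two")
  pt <- make_participants(1, age = 2)       # nobody in band 5+
  ct <- make_contacts("P001", c(7, 7))
  sv <- contact_survey(pt, ct)
  m <- mean_contact_matrix(sv, scheme = sc)
  expect_true(all(is.na(m$values[2, ])))
  pop <- population_table(sc, c(100, 50))
  adj <- reciprocity_adjust(m, pop)
  # observed c_12 = 2 transposes to c'_21 = c_12 * N_1 / N_2 = 4
  expect_equal(adj$values[2, 1], 4)
  expect_equal(adj$values[1, 2], 2)
  expect_true(is.na(adj$values[2, 2]))  # unobserved in both directions
  T_ <- sweep(adj$values, 1, pop$N, "*")
  expect_equal(T_[1, 2], T_[2, 1])
})

test_that("matrices match a brute-force per-contact tally on small surveys", {
  set.seed(21)
  for (rep_i in 1:10) {
    n <- sample(3:20, 1)
    pt <- make_participants(n, age = sample(0:80, n, TRUE))
    deg <- rpois(n, 3)
    ct <- make_contacts(rep(pt$participant_id, deg),
                        sample(0:85, sum(deg), TRUE))
    sv <- contact_survey(pt, ct)
    w <- runif(n, 0.5, 2)
    m <- mean_contact_matrix(sv, weights = w)
    expect_equal(unname(m$values), matrix_oracle(sv, w, scheme14))
  }
})

test_that("setting stratification partitions contacts correctly", {
  pt <- make_participants(2, age = c(30, 40))
  ct <- make_contacts(c("P001", "P001", "P002"), c(30, 35, 40),
                      settings = "work")
  sv <- contact_survey(pt, ct)
  pop <- population_table(scheme14, rep(1000, 14))
  mats <- setting_stratified_matrices(sv, population = pop)
  expect_gt(sum(mats$work$values, na.rm = TRUE), 0)
  for (lab in c("home_household", "home_nonhousehold", "school",
                "other_transport_leisure")) {
    expect_equal(sum(mats[[lab]]$values, na.rm = TRUE), 0, info = lab)
  }
})

test_that("multi-setting contacts count once per setting but once in total", {
  pt <- make_participants(1, age = 10)
  ct <- make_contacts("P001", 12, settings = "home_household;school")
  sv <- contact_survey(pt, ct)
  pop <- population_table(scheme14, rep(1000, 14))
  mats <- setting_stratified_matrices(sv, population = pop)
  expect_equal(sum(mats$home_household$values, na.rm = TRUE) > 0, TRUE)
  expect_equal(sum(mats$school$values, na.rm = TRUE) > 0, TRUE)
  # all-settings matrix counts the contact exactly once: one contact from
  # band 10-14 into band 10-14, so total events = c_33 * N_3 = 1000
  T_all <- sweep(mats$all$values, 1, pop$N, "*")
  expect_equal(sum(T_all, na.rm = TRUE), 1000)

  excl <- setting_stratified_matrices(sv, population = pop,
                                      attribution = "exclusive_multiple")
  expect_equal(sum(excl$home_household$values, na.rm = TRUE), 0)
  expect_gt(sum(excl$multiple$values, na.rm = TRUE), 0)
})

test_that("matrix recovery from a mid-sized synthetic survey is unbiased", {
  cfg <- generator_config(
    n_participants = 2800, seed = 17,
    degree_model = list(coefficients = c(rural = 0, weekend = 0, female = 0),
                        dispersion = 1.5),
    supplementary_model = list(p_physical = 0, p_nonphysical = 0))
  gen <- generate_survey(cfg)
  M <- gen$ground_truth$true_matrix
  raw <- mean_contact_matrix(gen$survey)
  adj <- reciprocity_adjust(raw, gen$ground_truth$populations$all)
  # overall scale within 5% and strong cellwise correlation with the truth
  expect_lt(abs(mean(rowSums(adj$values)) / mean(rowSums(M)) - 1), 0.05)
  expect_gt(cor(as.vector(adj$values), as.vector(M)), 0.97)
})
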