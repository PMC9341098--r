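test_that("Bland-Altman from summaries reproduces published-style tables", {
  # AL_est vs AL_act, post-cycloplegic validation row
  ba <- ba_from_summary(0.012, 0.486, 650)
  expect_near(ba$loa_lower, -0.940, 1e-3)
  expect_near(ba$loa_upper, 0.965, 1e-3)
  expect_near(ba$mean_diff_ci, c(-0.025, 0.049), 1e-3)
  # FAZA corrected with estimated vs actual AL
  ba2 <- ba_from_summary(0.002, 0.015, 46)
  expect_equal(round(ba2$loa_lower, 3), -0.027)
  expect_equal(round(ba2$loa_upper, 3), 0.031)
  # structural identities
  expect_equal(ba$loa_lower, ba$mean_diff - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_upper - ba$loa_lower, 2 * 1.96 * ba$sd_diff)
})

test_that("Bland-Altman from raw pairs matches its summary form", {
  set.seed(7)
  a <- rnorm(40, 24, 1)
  b <- a + rnorm(40, 0.1, 0.3)
  ba_raw <- bland_altman(a, b)
  d <- a - b
  ba_sum <- ba_from_summary(mean(d), sd(d), 40)
  expect_equal(ba_raw[names(ba_raw) != "n"], ba_sum[names(ba_sum) != "n"],
               tolerance = 1e-12)
})

test_that("constant differences give degenerate limits", {
  a <- c(1, 2, 3, 4)
  ba <- bland_altman(a, a - 0.5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_lower, 0.5)
  expect_equal(ba$loa_upper, 0.5)
  expect_equal(ba$loa_lower_ci, c(0.5, 0.5))
  expect_error(bland_altman(1, 2), "equal length|at least 2")
})

test_that("Bland-Altman is antisymmetric in the two methods", {
  set.seed(13)
  a <- rnorm(30, 0.25, 0.05)
  b <- rnorm(30, 0.24, 0.05)
  ba_ab <- bland_altman(a, b)
  ba_ba <- bland_altman(b, a)
  expect_equal(ba_ba$mean_diff, -ba_ab$mean_diff)
  expect_equal(ba_ba$sd_diff, ba_ab$sd_diff)
  expect_equal(ba_ba$loa_lower, -ba_ab$loa_upper)
  expect_equal(ba_ba$loa_upper, -ba_ab$loa_lower)
  expect_equal(ba_ba$loa_lower_ci, -rev(ba_ab$loa_upper_ci))
})

test_that("halving the SD halves the LoA width", {
  w <- function(sd) {
    ba <- ba_from_summary(0.1, sd, 50)
    ba$loa_upper - ba$loa_lower
  }
  expect_equal(w(0.2), 2 * w(0.1))
})

test_that("LoA confidence intervals use SE = SD * sqrt(3/n)", {
  ci <- loa_confidence_intervals(0.012, 0.486, 650)
  expect_near(ci$lower, c(-1.005, -0.876), 1.5e-3)
  half <- 1.96 * 0.486 * sqrt(3 / 650)
  expect_equal(diff(ci$lower), 2 * half)
  expect_equal(diff(ci$upper), 2 * half)
  # degenerate SD collapses the intervals onto the limits
  ci0 <- loa_confidence_intervals(0.4, 0, 20)
  expect_equal(ci0$lower, c(0.4, 0.4))
  # FAZA-scale fixture
  ci2 <- loa_confidence_intervals(0.002, 0.015, 46)
  expect_near(ci2$upper, c(0.024, 0.039), 1e-3)
})

test_that("paired t from raw pairs equals the summary route", {
  set.seed(19)
  a <- rnorm(25, 10, 2)
  b <- a + rnorm(25, 0.3, 0.5)
  raw <- paired_t(a, b)
  d <- a - b
  summ <- paired_t(mean_diff = mean(d), sd_diff = sd(d), n = 25)
  expect_equal(raw$t_stat, summ$t_stat, tolerance = 1e-10)
  expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
  # cross-check against stats::t.test
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(raw$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(raw$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("paired t reproduces summary-table statistics", {
  expect_equal(paired_t(mean_diff = 0.012, sd_diff = 0.486, n = 650)$t_stat,
               0.632, tolerance = 0.03)
  expect_equal(paired_t(mean_diff = 0.095, sd_diff = 0.519, n = 651)$t_stat,
               4.683, tolerance = 0.03)
  zero <- paired_t(mean_diff = 0, sd_diff = 0.5, n = 30)
  expect_equal(zero$t_stat, 0)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$df, 29L)
  expect_error(paired_t(mean_diff = 0.1, sd_diff = 0, n = 10), "undefined")
})

test_that("ICC of absolute agreement matches hand and aov oracles", {
  fx <- icc_hand_fixture()
  r <- icc_absolute(fx$a, fx$b)
  expect_equal(r$icc, fx$icc, tolerance = 1e-12)
  expect_equal(r$icc, icc_aov_oracle(fx$a, fx$b), tolerance = 1e-8)

  set.seed(23)
  a <- rnorm(6, 20, 3)
  b <- a + rnorm(6, 0.4, 0.6)
  r6 <- icc_absolute(a, b)
  expect_equal(r6$icc, icc_aov_oracle(a, b), tolerance = 1e-8)
  expect_true(r6$ci[1] <= r6$icc && r6$icc <= r6$ci[2])
  expect_lte(r6$icc, 1)
})

test_that("ICC rewards identity and penalizes systematic offsets", {
  a <- c(10, 12, 14, 16)
  perfect <- icc_absolute(a, a)
  expect_equal(perfect$icc, 1)
  # large constant offset with small between-subject spread: near zero
  small <- c(10.0, 10.1, 10.2, 10.3)
  offset <- icc_absolute(small, small + 5)
  expect_lt(offset$icc, 0.05)
  expect_error(icc_absolute(rep(1, 4), rep(1, 4)), "undefined|zero")
  expect_error(icc_absolute(c(1, 2), c(1, 2)), "at least 3")
})

test_that("CR exceedance counts strict exceedances only", {
  expect_equal(cr_exceedance(c(0.2, 0.3), c(0.2, 0.3)), 0)
  ref <- rep(0, 4)
  method <- c(0.06, 0.01, 0.051, 0.053)
  expect_equal(cr_exceedance(method, ref, cr = 0.052), 50)
  expect_equal(cr_exceedance(rep(0.052, 5), rep(0, 5), cr = 0.052), 0)
  expect_error(cr_exceedance(1:3, 1:2), "equal length")
  expect_error(cr_exceedance(1, 1, cr = 0), "positive")
})

test_that("relative change reports per-pair percentages and maxima", {
  rc <- relative_change(0.30, 0.285)
  expect_equal(rc$percent, 5.0)
  expect_equal(relative_change(c(0.2, 0.5), c(0.2, 0.5))$percent, c(0, 0))
  rc2 <- relative_change(c(0.2, 0.4), c(0.25, 0.38))
  expect_equal(rc2$percent, c(25, 5))
  expect_equal(rc2$max_relative, 25)
  expect_equal(rc2$max_absolute, 0.05)
  expect_error(relative_change(c(0.2, 0), c(0.1, 0.1)), "positive")
})

test_that("q differences scale AL differences by the Littmann slope exactly", {
  set.seed(29)
  al_a <- runif(40, 21, 28)
  al_b <- runif(40, 21, 28)
  ba_al <- bland_altman(al_a, al_b)
  ba_q <- bland_altman(ocular_magnification_q(al_a), ocular_magnification_q(al_b))
  expect_equal(ba_q$mean_diff, 0.01306 * ba_al$mean_diff)
  expect_equal(ba_q$sd_diff, 0.01306 * ba_al$sd_diff)
  expect_equal(ba_q$loa_upper, 0.01306 * ba_al$loa_upper)
})

test_that("agreement_report assembles all statistics coherently", {
  set.seed(37)
  b <- rnorm(30, 0.25, 0.06)
  a <- b + rnorm(30, 0.002, 0.01)
  rep <- agreement_report(a, b, cr = 0.052, with_relative_change = TRUE)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$df, 29L)
  expect_true(rep$icc <= 1 && rep$p_value >= 0 && rep$p_value <= 1)
  expect_equal(rep$bland_altman$mean_diff, mean(a - b))
  expect_equal(rep$cr_exceedance_pct,
               100 * mean(abs(a - b) > 0.052))
  expect_equal(rep$relative_change$percent, 100 * abs(b - a) / b)
  out <- capture.output(print(rep))
  expect_true(any(grepl("Lower LoA", out)))
  expect_true(any(grepl("ICC", out)))

  # identical methods: zero bias, perfect ICC, undefined t reported as NA
  x <- c(0.2, 0.25, 0.3, 0.35)
  rep_id <- agreement_report(x, x, cr = 0.052)
  expect_equal(rep_id$bland_altman$mean_diff, 0)
  expect_equal(rep_id$icc, 1)
  expect_true(is.na(rep_id$t_stat))
  expect_equal(rep_id$cr_exceedance_pct, 0)
})

test_that("small p-values print floored at < 0.005, full precision retained", {
  set.seed(41)
  b <- rnorm(60, 0.25, 0.05)
  a <- b + 0.03 + rnorm(60, 0, 0.005)
  rep <- agreement_report(a, b)
  expect_lt(rep$p_value, 0.005)
  expect_gt(rep$p_value, 0)
  out <- capture.output(print(rep))
  expect_true(any(grepl("< 0.005", out, fixed = TRUE)))
})
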