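test_that("keratometry and refraction arithmetic follow their definitions", {
  expect_equal(mean_keratometry(7.5, 8.1), 7.8)
  expect_equal(mean_keratometry(7.76, 7.76), 7.76)
  expect_equal(mean_keratometry(7.11, 8.65), 7.88)
  expect_error(mean_keratometry(0, 7.5), "positive")
  expect_error(mean_keratometry(7.5, -1), "positive")

  expect_equal(spherical_equivalent(-1.0, -0.5), -1.25)
  expect_equal(spherical_equivalent(0, 0), 0)
  expect_equal(spherical_equivalent(-7.0, -2.0), -8.0)

  expect_equal(diopters_to_radius_mm(43.49), 337.5 / 43.49)
  expect_equal(diopters_to_radius_mm(337.5), 1.0)
  expect_equal(diopters_to_radius_mm(42.0), 337.5 / 42.0)
  expect_error(diopters_to_radius_mm(0), "positive")
})

test_that("estimate_axial_length evaluates the default regression", {
  m <- default_al_model()
  expect_equal(m$beta_k, 2.102)
  expect_equal(m$beta_se, -0.4125)
  expect_equal(m$intercept, 7.268)
  expect_equal(m$r_squared, 0.794)

  expect_equal(estimate_axial_length(7.81, -1.51),
               2.102 * 7.81 - 0.4125 * (-1.51) + 7.268)
  expect_equal(estimate_axial_length(7.81, -1.51), 24.3074, tolerance = 1e-4)
  expect_equal(estimate_axial_length(7.74, -0.07), 23.5664, tolerance = 1e-4)
  # vectorised
  expect_equal(estimate_axial_length(c(7.81, 7.74), c(-1.51, -0.07)),
               c(estimate_axial_length(7.81, -1.51),
                 estimate_axial_length(7.74, -0.07)))
})

test_that("out-of-range estimates warn but are still returned", {
  expect_warning(al <- estimate_axial_length(30, -10), "sanity range")
  expect_gt(al, 40)
  expect_silent(estimate_axial_length(30, -10, bounds = c(15, 100)))
  expect_error(estimate_axial_length(0, 0), "positive")
})

test_that("estimate_axial_length is linear: estimate at means equals mean of estimates", {
  set.seed(11)
  k <- rnorm(50, 7.76, 0.26)
  se <- rnorm(50, -0.15, 1.62)
  expect_equal(estimate_axial_length(mean(k), mean(se)),
               mean(estimate_axial_length(k, se)))
})

test_that("more myopic SE at fixed K strictly increases estimated AL", {
  se <- seq(2, -8, by = -0.5)
  al <- estimate_axial_length(rep(7.76, length(se)), se)
  expect_true(all(diff(al) > 0))
})

test_that("fit_al_model recovers a noiseless generating model exactly", {
  set.seed(21)
  d <- data.frame(k_mean_mm = rnorm(40, 7.76, 0.26),
                  se_d = rnorm(40, -0.15, 1.62))
  d$al_act_mm <- 2.102 * d$k_mean_mm - 0.4125 * d$se_d + 7.268
  fit <- suppressWarnings(fit_al_model(d))
  expect_equal(fit$beta_k, 2.102, tolerance = 1e-10)
  expect_equal(fit$beta_se, -0.4125, tolerance = 1e-10)
  expect_equal(fit$intercept, 7.268, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("fit_al_model matches a normal-equations oracle and interpolates 3 points", {
  set.seed(31)
  d <- data.frame(k_mean_mm = rnorm(80, 7.76, 0.26),
                  se_d = rnorm(80, -0.15, 1.62))
  d$al_act_mm <- 2.102 * d$k_mean_mm - 0.4125 * d$se_d + 7.268 +
    rnorm(80, 0, 0.486)
  fit <- fit_al_model(d)
  oracle <- ols_oracle(d)
  expect_equal(c(fit$intercept, fit$beta_k, fit$beta_se), oracle,
               tolerance = 1e-8, ignore_attr = TRUE)
  # fitted values through estimate_axial_length agree with the oracle plane
  fitted_pkg <- estimate_axial_length(d$k_mean_mm, d$se_d, model = fit)
  fitted_oracle <- oracle[1] + oracle[2] * d$k_mean_mm + oracle[3] * d$se_d
  expect_equal(fitted_pkg, fitted_oracle, tolerance = 1e-8)

  d3 <- data.frame(k_mean_mm = c(7.4, 7.8, 8.2), se_d = c(-2, 0, -1))
  d3$al_act_mm <- c(24.9, 23.6, 24.2)
  fit3 <- suppressWarnings(fit_al_model(d3))
  expect_equal(fit3$r_squared, 1, tolerance = 1e-10)
  expect_equal(estimate_axial_length(d3$k_mean_mm, d3$se_d, model = fit3),
               d3$al_act_mm, tolerance = 1e-8)
})

test_that("fit_al_model rejects unusable designs", {
  d <- data.frame(k_mean_mm = c(7.7, 7.8), se_d = c(0, 1),
                  al_act_mm = c(23, 24))
  expect_error(fit_al_model(d), "at least 3")
  d_collinear <- data.frame(k_mean_mm = rep(7.7, 5), se_d = rep(-1, 5),
                            al_act_mm = rnorm(5, 23.5))
  expect_error(fit_al_model(d_collinear))
  expect_error(fit_al_model(data.frame(k_mean_mm = 1:5)), "lacks column")
})

test_that("validate_biometry enforces the record invariants", {
  good <- data.frame(participant_id = "P1", eye = "right", k_mean_mm = 7.8,
                     sphere_d = -1, cylinder_d = -0.5, se_d = -1.25,
                     al_act_mm = 23.5, faza_mm2 = 0.25)
  expect_invisible(validate_biometry(good))
  bad_se <- transform(good, se_d = -1.0)
  expect_error(validate_biometry(bad_se), "inconsistent")
  expect_error(validate_biometry(transform(good, k_mean_mm = -1)), "keratometry")
  expect_error(validate_biometry(transform(good, al_act_mm = 12)), "axial length")
  expect_error(validate_biometry(transform(good, faza_mm2 = -0.1)), "FAZA")
  expect_error(validate_biometry(transform(good, eye = "both")), "eye")
  # configurable sanity bounds
  expect_invisible(validate_biometry(transform(good, al_act_mm = 12),
                                     al_bounds = c(10, 40)))
})
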