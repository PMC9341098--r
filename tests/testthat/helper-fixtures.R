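# Shared fixtures, built in code at test time.

# Absolute-tolerance comparison (expect_equal's tolerance is relative,
# which is too strict for quantities printed near zero).
expect_near <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Three-eye biometry table whose K/SE pairs sit at the means of the cohorts
# the default model is used with (OCTA cohort, training, validation).
three_eye_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "participant_id,eye,k_mean_mm,se_d,cycloplegic,al_act_mm,faza_mm2,sqi",
    "P001,right,7.81,-1.51,FALSE,24.28,0.25,9",
    "P002,right,7.76,-0.15,TRUE,,0.30,8",
    "P003,right,7.74,-0.07,TRUE,23.60,,7"
  ), path)
  path
}

# Hand-computable three-subject ICC fixture. With rows (10,11), (12,12),
# (14,16): MSR = 10.5, MSC = 1.5, MSE = 0.5, so
# ICC(A,1) = (10.5 - 0.5) / (10.5 + 0.5 + 2*(1.5 - 0.5)/3) = 6/7.
icc_hand_fixture <- function() {
  list(a = c(10, 12, 14), b = c(11, 12, 16), icc = 6 / 7)
}

# Independent mean-squares oracle for ICC(A,1) via stats::aov.
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  d <- data.frame(
    y = c(a, b),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- stats::anova(stats::aov(y ~ subject + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Normal-equations oracle for the OLS fit.
ols_oracle <- function(records) {
  x <- cbind(1, records$k_mean_mm, records$se_d)
  solve(crossprod(x), crossprod(x, records$al_act_mm))[, 1]
}
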