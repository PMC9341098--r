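# Per-eye biometry: keratometry/refraction arithmetic and the AL-estimation
# regression. K is the corneal radius of curvature in mm throughout; the
# regression consumes (K mm, SE D) and returns axial length in mm.

#' Mean keratometry from two principal meridians
#'
#' Averages the corneal radius of curvature measured along the two principal
#' meridians (conventionally horizontal and vertical), in mm.
#'
#' @param k_meridian_1,k_meridian_2 Corneal radii of curvature, mm. Vectors
#'   are recycled element-wise.
#' @return Mean corneal radius, mm.
#' @examples
#' mean_keratometry(7.5, 8.1)
#' @export
mean_keratometry <- function(k_meridian_1, k_meridian_2) {
  check_positive(k_meridian_1, "k_meridian_1")
  check_positive(k_meridian_2, "k_meridian_2")
  (k_meridian_1 + k_meridian_2) / 2
}

#' Spherical equivalent from sphere and cylinder
#'
#' SE = sphere + cylinder / 2 (minus-cylinder agnostic: the convention of
#' the cylinder notation does not matter as long as sphere and cylinder use
#' the same one).
#'
#' @param sphere Sphere, dioptres.
#' @param cylinder Cylinder, dioptres.
#' @return Spherical equivalent, dioptres.
#' @examples
#' spherical_equivalent(-1.0, -0.5)
#' @export
spherical_equivalent <- function(sphere, cylinder) {
  sphere + cylinder / 2
}

#' Convert keratometric power to corneal radius
#'
#' Converts corneal power in dioptres to radius of curvature in mm using the
#' standard keratometric index convention r = 337.5 / K. The AL-estimation
#' regression requires K as a radius in mm; use this when an instrument
#' exports dioptric power only.
#'
#' @param k_power Corneal power, dioptres. Must be positive.
#' @return Corneal radius of curvature, mm.
#' @examples
#' diopters_to_radius_mm(43.49)
#' @export
diopters_to_radius_mm <- function(k_power) {
  check_positive(k_power, "k_power")
  337.5 / k_power
}

#' Axial-length estimation model
#'
#' Constructs an `al_model` object holding the coefficients of the linear
#' model AL = beta_k * K + beta_se * SE + intercept, where K is mean corneal
#' radius (mm) and SE spherical equivalent (D). [default_al_model()] returns
#' the shipped model fitted on a post-cycloplegic young-adult training
#' cohort (n = 650): AL_est = 2.102 K - 0.4125 SE + 7.268, R-squared 0.794.
#'
#' @param beta_k Keratometry coefficient, mm per mm.
#' @param beta_se Spherical-equivalent coefficient, mm per D.
#' @param intercept Intercept, mm.
#' @param r_squared Coefficient of determination of the fit, in \[0, 1\].
#' @param n Sample size the model was fitted on (NA if unknown).
#' @param residual_sd Residual standard deviation of the fit, mm.
#' @return An object of class `al_model`.
#' @seealso [fit_al_model()] to refit on a cohort, [estimate_axial_length()]
#'   to apply a model.
#' @export
al_model <- function(beta_k, beta_se, intercept, r_squared = NA_real_,
                     n = NA_integer_, residual_sd = NA_real_) {
  stopifnot(is.numeric(beta_k), is.numeric(beta_se), is.numeric(intercept))
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.na(residual_sd) && residual_sd < 0) {
    stop("`residual_sd` must be non-negative.", call. = FALSE)
  }
  structure(
    list(beta_k = beta_k, beta_se = beta_se, intercept = intercept,
         r_squared = r_squared, n = as.integer(n), residual_sd = residual_sd),
    class = "al_model"
  )
}

#' @rdname al_model
#' @export
default_al_model <- function() {
  al_model(beta_k = 2.102, beta_se = -0.4125, intercept = 7.268,
           r_squared = 0.794, n = 650L, residual_sd = 0.486)
}

#' @export
print.al_model <- function(x, ...) {
  cat("Axial-length estimation model\n")
  cat(sprintf("  AL_est = %.4g K %+.4g SE %+.4g   (K in mm, SE in D, AL in mm)\n",
              x$beta_k, x$beta_se, x$intercept))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared: %.3f\n", x$r_squared))
  if (!is.na(x$n)) cat(sprintf("  fitted on n = %d eyes\n", x$n))
  if (!is.na(x$residual_sd)) cat(sprintf("  residual SD: %.3f mm\n", x$residual_sd))
  invisible(x)
}

#' Estimate axial length from keratometry and spherical equivalent
#'
#' Applies an [al_model()] to mean corneal radius (mm) and spherical
#' equivalent (D). Estimates falling outside `bounds` trigger a warning
#' (never an error), so batch runs survive data-entry mistakes; the values
#' are still returned.
#'
#' @param k_mean Mean corneal radius of curvature, mm. Must be positive.
#' @param se Spherical equivalent, dioptres.
#' @param model An `al_model`; defaults to the shipped model.
#' @param bounds Length-2 numeric sanity range, mm, used only for the
#'   out-of-range warning.
#' @return Estimated axial length, mm (vectorised over `k_mean` and `se`).
#' @examples
#' estimate_axial_length(7.81, -1.51)
#' @export
estimate_axial_length <- function(k_mean, se, model = default_al_model(),
                                  bounds = c(15, 40)) {
  check_positive(k_mean, "k_mean")
  stopifnot(inherits(model, "al_model"), length(bounds) == 2)
  al <- model$beta_k * k_mean + model$beta_se * se + model$intercept
  out <- which(al < bounds[1] | al > bounds[2])
  if (length(out) > 0) {
    warning(sprintf(
      "%d axial-length estimate(s) outside the sanity range [%g, %g] mm (first: %.2f mm).",
      length(out), bounds[1], bounds[2], al[out[1]]), call. = FALSE)
  }
  al
}

#' Fit the axial-length regression on a cohort
#'
#' Ordinary-least-squares fit of measured axial length on mean corneal
#' radius and spherical equivalent with intercept, via [stats::lm()]. The
#' residual SD uses denominator n - 3 (residual degrees of freedom).
#'
#' @param records Data frame with numeric columns `k_mean_mm`, `se_d` and
#'   `al_act_mm` (rows with any of the three missing are dropped). A
#'   `synthetic_cohort` is also accepted.
#' @return An [al_model()] carrying the fitted coefficients, R-squared,
#'   sample size and residual SD.
#' @examples
#' d <- data.frame(k_mean_mm = c(7.5, 7.8, 8.1), se_d = c(-2, 0, 1))
#' d$al_act_mm <- 2.102 * d$k_mean_mm - 0.4125 * d$se_d + 7.268
#' fit_al_model(d)
#' @export
fit_al_model <- function(records) {
  if (inherits(records, "synthetic_cohort")) records <- records$records
  stopifnot(is.data.frame(records))
  need <- c("k_mean_mm", "se_d", "al_act_mm")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("`records` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- records[stats::complete.cases(records[need]), need]
  if (nrow(d) < 3) {
    stop("Need at least 3 complete (K, SE, AL) records to fit; got ",
         nrow(d), ".", call. = FALSE)
  }
  fit <- stats::lm(al_act_mm ~ k_mean_mm + se_d, data = d)
  if (any(is.na(stats::coef(fit)))) {
    stop("Design matrix is rank-deficient; K and SE are collinear.",
         call. = FALSE)
  }
  s <- summary(fit)
  cf <- stats::coef(fit)
  model <- al_model(
    beta_k = unname(cf["k_mean_mm"]),
    beta_se = unname(cf["se_d"]),
    intercept = unname(cf["(Intercept)"]),
    r_squared = s$r.squared,
    n = nrow(d),
    residual_sd = s$sigma
  )
  attr(model, "coef_se") <- s$coefficients[, "Std. Error"]
  model
}

#' Validate a per-eye biometry table
#'
#' Checks the invariants of the canonical biometry layout: positive
#' keratometry radii, axial lengths within sanity bounds, non-negative FAZA,
#' and (where sphere, cylinder and SE all present) SE consistent with
#' sphere + cylinder / 2 to 1e-6 D.
#'
#' @param records Data frame in the canonical layout (see
#'   [read_biometry_csv()]).
#' @param al_bounds Sanity bounds for measured axial length, mm.
#' @return `records`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_biometry <- function(records, al_bounds = c(15, 40)) {
  stopifnot(is.data.frame(records))
  bad <- function(cond) which(!is.na(cond) & cond)
  if ("k_mean_mm" %in% names(records)) {
    i <- bad(records$k_mean_mm <= 0)
    if (length(i)) stop("Non-positive keratometry radius in row(s): ",
                        paste(i, collapse = ", "), call. = FALSE)
  }
  if ("al_act_mm" %in% names(records)) {
    i <- bad(records$al_act_mm < al_bounds[1] | records$al_act_mm > al_bounds[2])
    if (length(i)) stop(sprintf(
      "Measured axial length outside [%g, %g] mm in row(s): %s",
      al_bounds[1], al_bounds[2], paste(i, collapse = ", ")), call. = FALSE)
  }
  if ("faza_mm2" %in% names(records)) {
    i <- bad(records$faza_mm2 < 0)
    if (length(i)) stop("Negative FAZA in row(s): ",
                        paste(i, collapse = ", "), call. = FALSE)
  }
  if (all(c("sphere_d", "cylinder_d", "se_d") %in% names(records))) {
    implied <- records$sphere_d + records$cylinder_d / 2
    i <- bad(abs(implied - records$se_d) > 1e-6)
    if (length(i)) stop(
      "Spherical equivalent inconsistent with sphere + cylinder/2 in row(s): ",
      paste(i, collapse = ", "), call. = FALSE)
  }
  if ("eye" %in% names(records)) {
    ok <- is.na(records$eye) | records$eye %in% c("right", "left")
    if (!all(ok)) stop("`eye` must be 'right' or 'left'; bad row(s): ",
                       paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x) | x <= 0)) {
    stop(sprintf("`%s` must be positive and finite.", name), call. = FALSE)
  }
  invisible(x)
}
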