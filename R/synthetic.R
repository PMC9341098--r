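# Seeded synthetic biometry cohorts. The generative model mirrors the
# structure the analysis assumes: K and post-cycloplegic SE are drawn from
# the cohort marginals, AL is the regression's value plus residual noise,
# non-cycloplegic SE adds an accommodation shift (more myopic on average),
# and the measured FAZA is the true FAZA pushed through the *inverse* of
# the magnification correction at the eye's actual AL - so correcting with
# the actual AL recovers the true FAZA exactly.

#' Specification of a synthetic biometry cohort
#'
#' Generative parameters and seed for [generate_cohort()]. The defaults
#' emulate a young-adult training cohort: mean corneal radius
#' N(7.76, 0.26) mm, post-cycloplegic spherical equivalent N(-0.15, 1.62) D,
#' axial length generated from the default regression with residual SD
#' 0.486 mm, an accommodation shift of N(-0.43, 0.30) D for non-cycloplegic
#' refraction, and true FAZA N(0.25, 0.10) mm^2 truncated below at
#' 0.05 mm^2.
#'
#' @param n Number of eyes; at least 1.
#' @param k_mean_dist (mean, sd) of mean corneal radius, mm.
#' @param se_post_dist (mean, sd) of post-cycloplegic SE, D.
#' @param residual_sd Residual SD of AL around the generating regression, mm.
#' @param accommodation_shift (mean, sd) of the non-cycloplegic SE offset,
#'   D; a negative mean makes non-cycloplegic refraction more myopic.
#' @param faza_true_dist (mean, sd) of true FAZ area, mm^2.
#' @param faza_truncation Lower truncation bound for true FAZA, mm^2
#'   (prevents non-physical near-zero areas); positive.
#' @param faza_noise_sd SD of additive measurement noise on the measured
#'   FAZA, mm^2; default 0 (no replicate-variance data to pin it).
#' @param device [device_profile()] whose inverse correction produces the
#'   measured FAZA.
#' @param model Generating [al_model()].
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        k_mean_dist = c(7.76, 0.26),
                        se_post_dist = c(-0.15, 1.62),
                        residual_sd = 0.486,
                        accommodation_shift = c(-0.43, 0.30),
                        faza_true_dist = c(0.25, 0.10),
                        faza_truncation = 0.05,
                        faza_noise_sd = 0,
                        device = rtvue_avanti(),
                        model = default_al_model(),
                        seed = 1L) {
  if (!is.numeric(n) || n < 1) {
    stop("`n` must be at least 1.", call. = FALSE)
  }
  sds <- c(k_mean_dist[2], se_post_dist[2], residual_sd,
           accommodation_shift[2], faza_true_dist[2], faza_noise_sd)
  if (any(sds < 0)) {
    stop("All standard deviations must be non-negative.", call. = FALSE)
  }
  if (faza_truncation <= 0) {
    stop("`faza_truncation` must be positive.", call. = FALSE)
  }
  stopifnot(inherits(device, "device_profile"), inherits(model, "al_model"))
  structure(
    list(n = as.integer(n), k_mean_dist = k_mean_dist,
         se_post_dist = se_post_dist, residual_sd = residual_sd,
         accommodation_shift = accommodation_shift,
         faza_true_dist = faza_true_dist, faza_truncation = faza_truncation,
         faza_noise_sd = faza_noise_sd, device = device, model = model,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Truncated-normal draws by rejection; deterministic given the RNG state.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate a synthetic biometry cohort
#'
#' Draws a cohort from a [cohort_spec()]. Per eye: K ~ Normal, SE_post ~
#' Normal, AL_act = model(K, SE_post) + Normal(0, residual_sd),
#' SE_noncyclo = SE_post + accommodation shift, true FAZA ~ truncated
#' Normal, and measured FAZA = true FAZA / (p q(AL_act))^2 (+ optional
#' measurement noise) - the exact inverse of [correct_area()] at the actual
#' AL. Scan quality indices are drawn uniformly from 7-10 (the quality
#' range retained for analysis). Regeneration with the same spec and seed
#' is bit-identical; the caller's RNG state is left untouched.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: `records` (a data frame
#'   in the canonical biometry layout with extra synthetic-only columns
#'   `se_noncyclo_d` and `faza_true_mm2`) and `spec` (provenance).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 20, seed = 42))
#' head(cohort$records)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  n <- spec$n
  k <- stats::rnorm(n, spec$k_mean_dist[1], spec$k_mean_dist[2])
  se_post <- stats::rnorm(n, spec$se_post_dist[1], spec$se_post_dist[2])
  al_act <- spec$model$beta_k * k + spec$model$beta_se * se_post +
    spec$model$intercept + stats::rnorm(n, 0, spec$residual_sd)
  se_noncyclo <- se_post + stats::rnorm(n, spec$accommodation_shift[1],
                                        spec$accommodation_shift[2])
  faza_true <- rtruncnorm_lower(n, spec$faza_true_dist[1],
                                spec$faza_true_dist[2], spec$faza_truncation)
  scale2 <- linear_scale(spec$device, al_act)^2
  faza_measured <- faza_true / scale2
  if (spec$faza_noise_sd > 0) {
    faza_measured <- faza_measured + stats::rnorm(n, 0, spec$faza_noise_sd)
  }
  sqi <- sample(7:10, n, replace = TRUE)

  records <- data.frame(
    participant_id = sprintf("S%04d", seq_len(n)),
    eye = "right",
    k_mean_mm = k,
    se_d = se_post,
    cycloplegic = TRUE,
    al_act_mm = al_act,
    faza_mm2 = faza_measured,
    sqi = sqi,
    se_noncyclo_d = se_noncyclo,
    faza_true_mm2 = faza_true,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic biometry cohort: %d eyes (seed %d)\n",
              nrow(x$records), x$spec$seed))
  cat(sprintf("  AL mean (SD): %.2f (%.2f) mm   K mean: %.2f mm   SE mean: %.2f D\n",
              mean(x$records$al_act_mm), stats::sd(x$records$al_act_mm),
              mean(x$records$k_mean_mm), mean(x$records$se_d)))
  invisible(x)
}

#' Monte-Carlo distribution of agreement summaries
#'
#' Repeatedly generates cohorts, runs the full pipeline per replicate -
#' estimate AL from (K, SE), correct the measured FAZA with both the
#' estimated and the actual AL - and collects Bland-Altman summaries for
#' the two comparisons of interest: FAZA corrected with estimated AL vs
#' corrected with actual AL, and uncorrected FAZA vs corrected with actual
#' AL.
#'
#' @param spec A [cohort_spec()]; its `seed` field is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param n_reps Number of replicates, at least 1.
#' @param seed Master seed for the replicate seeds.
#' @param use_noncyclo If `TRUE`, estimate AL from the non-cycloplegic SE
#'   (as when cycloplegia is unavailable); default uses post-cycloplegic.
#' @return A data frame with one row per replicate: mean difference, SD and
#'   LoA for each comparison (`est_vs_act_*`, `uncorr_vs_act_*`).
#' @export
emulate_ba_summaries <- function(spec, n_reps, seed = 1L,
                                 use_noncyclo = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 1)
  seeds <- derive_seeds(seed, n_reps)
  rows <- lapply(seq_len(n_reps), function(i) {
    spec_i <- spec
    spec_i$seed <- seeds[i]
    co <- generate_cohort(spec_i)
    r <- co$records
    se_used <- if (use_noncyclo) r$se_noncyclo_d else r$se_d
    al_est <- estimate_axial_length(r$k_mean_mm, se_used, spec$model)
    faza_est <- correct_area(r$faza_mm2, spec$device, al_est)
    faza_act <- correct_area(r$faza_mm2, spec$device, r$al_act_mm)
    ba1 <- bland_altman(faza_est, faza_act)
    ba2 <- bland_altman(r$faza_mm2, faza_act)
    data.frame(
      replicate = i, seed = seeds[i],
      est_vs_act_mean_diff = ba1$mean_diff, est_vs_act_sd = ba1$sd_diff,
      est_vs_act_loa_lower = ba1$loa_lower, est_vs_act_loa_upper = ba1$loa_upper,
      uncorr_vs_act_mean_diff = ba2$mean_diff, uncorr_vs_act_sd = ba2$sd_diff,
      uncorr_vs_act_loa_lower = ba2$loa_lower,
      uncorr_vs_act_loa_upper = ba2$loa_upper
    )
  })
  do.call(rbind, rows)
}

# Deterministic stream of replicate seeds from one master seed, kept inside
# 32-bit integer range.
derive_seeds <- function(seed, n) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
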