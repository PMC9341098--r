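# CSV ingestion for the canonical biometry dialect. Columns are fixed and
# versioned rather than sniffed; a `col_map` renames user columns on the
# way in. Lines starting with `#` are provenance headers and are skipped.

BIOMETRY_COLUMNS <- c("participant_id", "eye", "k1_mm", "k2_mm", "k_mean_mm",
                      "k_power_d", "sphere_d", "cylinder_d", "se_d",
                      "cycloplegic", "al_act_mm", "faza_mm2", "sqi")

#' Read a per-eye biometry table
#'
#' Reads a CSV in the canonical dialect (UTF-8, comma separator, decimal
#' point, empty cells for missing values) and normalises it: `k_mean_mm` is
#' derived from `k1_mm`/`k2_mm` or from `k_power_d` (via 337.5/K) when not
#' given directly, and `se_d` from `sphere_d` + `cylinder_d`/2 when absent.
#' Recognised columns: participant_id, eye, k1_mm, k2_mm, k_mean_mm,
#' k_power_d, sphere_d, cylinder_d, se_d, cycloplegic, al_act_mm, faza_mm2,
#' sqi. Lines beginning with `#` are treated as comments.
#'
#' @param path CSV path.
#' @param col_map Optional named character vector renaming user columns to
#'   canonical ones, e.g. `c(k_mean_mm = "K")` maps the file's `K` column.
#' @param validate Run [validate_biometry()] on the result (default TRUE).
#' @param al_bounds Sanity bounds for measured axial length, mm, passed to
#'   [validate_biometry()].
#' @return A data frame with canonical columns.
#' @export
read_biometry_csv <- function(path, col_map = NULL, validate = TRUE,
                              al_bounds = c(15, 40)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      user <- col_map[[canonical]]
      if (!user %in% names(d)) {
        stop("Column `", user, "` (mapped to ", canonical,
             ") not found in ", path, call. = FALSE)
      }
      names(d)[names(d) == user] <- canonical
    }
  }
  unknown <- setdiff(names(d), c(BIOMETRY_COLUMNS,
                                 "se_noncyclo_d", "faza_true_mm2", "al_est_mm"))
  if (length(unknown) > 0) {
    warning("Ignoring unrecognised column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- c("k1_mm", "k2_mm", "k_mean_mm", "k_power_d", "sphere_d",
                    "cylinder_d", "se_d", "al_act_mm", "faza_mm2")
  for (col in intersect(numeric_cols, names(d))) {
    d[[col]] <- as.numeric(d[[col]])
  }
  if ("cycloplegic" %in% names(d)) {
    d$cycloplegic <- as.logical(d$cycloplegic)
  }
  if (!"k_mean_mm" %in% names(d) || all(is.na(d$k_mean_mm))) {
    d$k_mean_mm <- rep(NA_real_, nrow(d))
  }
  need_k <- is.na(d$k_mean_mm)
  if (any(need_k) && all(c("k1_mm", "k2_mm") %in% names(d))) {
    both <- need_k & !is.na(d$k1_mm) & !is.na(d$k2_mm)
    d$k_mean_mm[both] <- (d$k1_mm[both] + d$k2_mm[both]) / 2
    need_k <- is.na(d$k_mean_mm)
  }
  if (any(need_k) && "k_power_d" %in% names(d)) {
    conv <- need_k & !is.na(d$k_power_d) & d$k_power_d > 0
    d$k_mean_mm[conv] <- 337.5 / d$k_power_d[conv]
  }
  if (!"se_d" %in% names(d)) d$se_d <- rep(NA_real_, nrow(d))
  need_se <- is.na(d$se_d)
  if (any(need_se) && all(c("sphere_d", "cylinder_d") %in% names(d))) {
    both <- need_se & !is.na(d$sphere_d) & !is.na(d$cylinder_d)
    d$se_d[both] <- d$sphere_d[both] + d$cylinder_d[both] / 2
  }
  if (validate) validate_biometry(d, al_bounds = al_bounds)
  d
}

#' Write a biometry table with a provenance header
#'
#' Writes the canonical CSV dialect preceded by `#`-prefixed provenance
#' comment lines (tool version and any extra entries), which
#' [read_biometry_csv()] skips on re-reading.
#'
#' @param records Data frame to write.
#' @param path Output path.
#' @param provenance Named character vector of extra provenance entries.
#' @return `path`, invisibly.
#' @export
write_biometry_csv <- function(records, path, provenance = character()) {
  header <- c(
    sprintf("# ocumag %s", as.character(utils::packageVersion("ocumag"))),
    if (length(provenance) > 0) {
      sprintf("# %s: %s", names(provenance), unname(provenance))
    }
  )
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(records, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic cohort with its generating spec
#'
#' Writes the cohort records as canonical CSV (including the
#' synthetic-only columns `se_noncyclo_d` and `faza_true_mm2`) and the full
#' generating specification as a sidecar JSON for provenance.
#'
#' @param cohort A [generate_cohort()] result.
#' @param csv_path Output CSV path.
#' @param json_path Sidecar JSON path; defaults to `csv_path` with a
#'   `.spec.json` suffix.
#' @return Invisibly, a list with both paths.
#' @export
write_cohort <- function(cohort, csv_path,
                         json_path = paste0(csv_path, ".spec.json")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write_biometry_csv(cohort$records, csv_path,
                     provenance = c(seed = as.character(cohort$spec$seed),
                                    synthetic = "true"))
  spec <- cohort$spec
  spec_list <- list(
    n = spec$n, k_mean_dist = spec$k_mean_dist,
    se_post_dist = spec$se_post_dist, residual_sd = spec$residual_sd,
    accommodation_shift = spec$accommodation_shift,
    faza_true_dist = spec$faza_true_dist,
    faza_truncation = spec$faza_truncation,
    faza_noise_sd = spec$faza_noise_sd,
    device = list(name = spec$device$name, p_factor = spec$device$p_factor,
                  reference_al_mm = spec$device$reference_al,
                  scan_width_mm = spec$device$scan_width),
    model = list(beta_k = spec$model$beta_k, beta_se = spec$model$beta_se,
                 intercept = spec$model$intercept),
    seed = spec$seed
  )
  jsonlite::write_json(spec_list, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv_path, json = json_path))
}

#' Save and load a fitted axial-length model as JSON
#'
#' Persists an [al_model()] so site-specific refits slot into the same
#' pipeline as the shipped default.
#'
#' @param model An `al_model`.
#' @param path JSON path.
#' @return `write_al_model()` returns `path` invisibly; `read_al_model()`
#'   returns an `al_model`.
#' @export
write_al_model <- function(model, path) {
  stopifnot(inherits(model, "al_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_al_model
#' @export
read_al_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  al_model(beta_k = x$beta_k, beta_se = x$beta_se, intercept = x$intercept,
           r_squared = x$r_squared %||% NA_real_,
           n = x$n %||% NA_integer_,
           residual_sd = x$residual_sd %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
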