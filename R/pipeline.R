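#' Analysis configuration
#'
#' Collects the pipeline's tunable constants. Defaults follow the
#' compensation model and its evaluation design: RFC multiplier 1.25,
#' clinical NBGFR threshold 45 mL/min/1.73 m² with the ROC analysis
#' restricted to patients whose preoperative global GFR exceeds 45, P30
#' tolerance 0.30, and 1000 bootstrap resamples.
#'
#' @param ckd_epi_variant `"2021"` or `"2009"`.
#' @param rfc_multiplier Compensation multiplier; default 1.25.
#' @param nbgfr_threshold ROC label threshold (strict); default 45.
#' @param preop_gfr_subset_threshold ROC subset threshold (strict);
#'   default 45.
#' @param p30_fraction Relative accuracy tolerance; default 0.30.
#' @param n_bootstrap Bootstrap resamples; default 1000.
#' @param seed Integer RNG seed; mandatory for any stochastic step (there is
#'   deliberately no timestamp fallback).
#' @param output_dir Directory for report files, or `NULL` to skip writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ckd_epi_variant = c("2021", "2009"),
                       rfc_multiplier = 1.25,
                       nbgfr_threshold = 45,
                       preop_gfr_subset_threshold = 45,
                       p30_fraction = 0.30,
                       n_bootstrap = 1000,
                       seed = NULL,
                       output_dir = NULL) {
  ckd_epi_variant <- match.arg(ckd_epi_variant)
  if (rfc_multiplier <= 0 || nbgfr_threshold <= 0 ||
      preop_gfr_subset_threshold <= 0) {
    stop("thresholds and the RFC multiplier must be > 0", call. = FALSE)
  }
  if (p30_fraction <= 0 || p30_fraction >= 1) {
    stop("`p30_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(ckd_epi_variant = ckd_epi_variant,
                 rfc_multiplier = rfc_multiplier,
                 nbgfr_threshold = nbgfr_threshold,
                 preop_gfr_subset_threshold = preop_gfr_subset_threshold,
                 p30_fraction = p30_fraction,
                 n_bootstrap = n_bootstrap,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' Run the full SRF method-comparison pipeline
#'
#' Applies the inclusion filter, resolves each method's SRF, predicts NBGFR
#' with the compensation model, computes the metric suite (with bootstrap
#' CIs) per method, and compares each method against the reference method
#' with paired bootstrap tests on every metric. Patients missing a method's
#' inputs are dropped for that method only (counts are logged); pairwise
#' comparisons use the patients with both methods available.
#'
#' @param cohort A cohort data frame or a path to a cohort CSV.
#' @param config A [run_config()]; `config$seed` must be set.
#' @param reference Reference method for the pairwise comparisons; default
#'   `"PVA"`.
#' @param quiet Suppress progress messages.
#' @return A list of class `srf_evaluation`: `metrics` (one row per method),
#'   `comparisons` (one row per method x metric vs the reference),
#'   `predictions` (per-patient observed and per-method predicted NBGFR),
#'   `n_used` (named counts), `config`. If `config$output_dir` is set,
#'   `metrics.csv`, `comparisons.csv`, `predictions.csv` and `report.txt`
#'   are written there.
#' @export
run_pipeline <- function(cohort, config = run_config(seed = 1),
                         reference = "PVA", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$seed)) {
    stop("`config$seed` must be set", call. = FALSE)
  }
  if (is.character(cohort)) {
    cohort <- read_cohort(cohort, ckd_epi_variant = config$ckd_epi_variant)
  }
  cohort <- apply_inclusion_filter(cohort, quiet = quiet)
  if (nrow(cohort) == 0) stop("no patients pass the inclusion filter",
                              call. = FALSE)
  srf <- resolve_srf(cohort)
  available <- vapply(srf, function(s) sum(!is.na(s)), integer(1))
  if (all(available == 0)) {
    stop("no SRF method is resolvable for any patient", call. = FALSE)
  }
  methods <- names(srf)[available > 0]
  if (!quiet) {
    message("patients per method: ",
            paste(sprintf("%s=%d", names(available), available),
                  collapse = ", "))
  }

  pred <- lapply(srf, function(s) {
    ifelse(is.na(s), NA_real_,
           config$rfc_multiplier * cohort$egfr_pre_global * s)
  })
  predictions <- data.frame(patient_id = cohort$patient_id,
                            egfr_pre_global = cohort$egfr_pre_global,
                            observed = cohort$egfr_nbgfr_observed,
                            predicted_pva = pred$PVA,
                            predicted_nrs = pred$NRS,
                            predicted_lwh = pred$LWH,
                            stringsAsFactors = FALSE)

  metrics <- do.call(rbind, lapply(methods, function(m) {
    ok <- !is.na(pred[[m]])
    evaluate_method(cohort$egfr_nbgfr_observed[ok], pred[[m]][ok],
                    cohort$egfr_pre_global[ok], method = m,
                    n_resamples = config$n_bootstrap, seed = config$seed,
                    p30_fraction = config$p30_fraction,
                    nbgfr_threshold = config$nbgfr_threshold,
                    preop_subset_threshold = config$preop_gfr_subset_threshold)
  }))

  others <- setdiff(methods, reference)
  comparisons <- NULL
  if (reference %in% methods && length(others) > 0) {
    rows <- list()
    for (m in others) {
      ok <- !is.na(pred[[reference]]) & !is.na(pred[[m]])
      for (met in metric_choices) {
        cmp <- bootstrap_compare(
          cohort$egfr_nbgfr_observed[ok], pred[[m]][ok],
          pred[[reference]][ok], met,
          egfr_pre_global = cohort$egfr_pre_global[ok],
          method_a = m, method_b = reference,
          n_resamples = config$n_bootstrap, seed = config$seed,
          p30_fraction = config$p30_fraction,
          nbgfr_threshold = config$nbgfr_threshold,
          preop_subset_threshold = config$preop_gfr_subset_threshold)
        rows[[length(rows) + 1]] <- data.frame(
          method = m, reference = reference, metric = met,
          difference = cmp$observed_difference, ci_lower = cmp$ci_lower,
          ci_upper = cmp$ci_upper, p_value = cmp$p_value, n = cmp$n,
          stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, rows)
  }

  out <- structure(list(metrics = metrics, comparisons = comparisons,
                        predictions = predictions, n_used = available,
                        config = config),
                   class = "srf_evaluation")
  if (!is.null(config$output_dir)) write_evaluation(out, config$output_dir)
  out
}

#' Write the evaluation report files
#'
#' Writes `metrics.csv`, `comparisons.csv`, `predictions.csv` and a
#' human-readable `report.txt`. Every number in the text report is formatted
#' from the CSV contents — there is no second computation path.
#'
#' @param x An `srf_evaluation` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(x, dir) {
  stopifnot(inherits(x, "srf_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(x$comparisons)) {
    utils::write.csv(x$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(x$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  writeLines(format_report(x), file.path(dir, "report.txt"))
  invisible(dir)
}

# Table-2-style plain-text rendering of the metrics and comparisons.
format_report <- function(x) {
  fmt <- function(v, lo, hi, digits = 2) {
    ifelse(is.na(v), "unavailable",
           sprintf("%.*f [%.*f, %.*f]", digits, v, digits, lo, digits, hi))
  }
  m <- x$metrics
  lines <- c(
    "Performance of SRF methods for predicting NBGFR after radical nephrectomy",
    sprintf("(RFC multiplier %.2f; NBGFR threshold %g; %d bootstrap resamples, seed %d)",
            x$config$rfc_multiplier, x$config$nbgfr_threshold,
            x$config$n_bootstrap, x$config$seed),
    "")
  for (i in seq_len(nrow(m))) {
    lines <- c(lines,
      sprintf("SRF derived from %s (n = %d):", m$method[i], m$n[i]),
      sprintf("  Correlation (r)        %s", fmt(m$r[i], m$r_lo[i], m$r_hi[i])),
      sprintf("  Bias (ml/min/1.73m2)   %s",
              fmt(m$bias[i], m$bias_lo[i], m$bias_hi[i])),
      sprintf("  Precision (IQR)        %s",
              fmt(m$precision[i], m$precision_lo[i], m$precision_hi[i])),
      sprintf("  Mean-squared error     %s",
              fmt(m$mse[i], m$mse_lo[i], m$mse_hi[i])),
      sprintf("  Accuracy (P30, %%)      %s",
              fmt(m$p30[i], m$p30_lo[i], m$p30_hi[i])),
      sprintf("  AUC (NBGFR > %g)       %s",
              x$config$nbgfr_threshold,
              fmt(m$auc[i], m$auc_lo[i], m$auc_hi[i])),
      "")
  }
  if (!is.null(x$comparisons)) {
    lines <- c(lines, "Paired bootstrap comparisons vs reference:")
    cc <- x$comparisons
    for (i in seq_len(nrow(cc))) {
      lines <- c(lines, sprintf(
        "  %s vs %s, %-9s diff %8.3f [%8.3f, %8.3f]  p = %.4f",
        cc$method[i], cc$reference[i], cc$metric[i], cc$difference[i],
        cc$ci_lower[i], cc$ci_upper[i], cc$p_value[i]))
    }
  }
  lines
}

#' @export
print.srf_evaluation <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
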