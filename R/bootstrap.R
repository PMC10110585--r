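#' @keywords internal
#' @noRd
metric_choices <- c("r", "bias", "precision", "mse", "p30", "auc")

# Builds the scalar metric evaluator used for point estimates and for every
# bootstrap resample. AUC needs the preoperative GFR to apply the subset rule.
make_metric_fn <- function(metric, p30_fraction = 0.30,
                           nbgfr_threshold = 45,
                           preop_subset_threshold = 45) {
  metric <- match.arg(metric, metric_choices)
  switch(metric,
    r         = function(obs, pred, egfr_pre) pearson_r(obs, pred),
    bias      = function(obs, pred, egfr_pre) nbgfr_bias(obs, pred),
    precision = function(obs, pred, egfr_pre) nbgfr_precision(obs, pred),
    mse       = function(obs, pred, egfr_pre) nbgfr_mse(obs, pred),
    p30       = function(obs, pred, egfr_pre)
      p30_accuracy(obs, pred, fraction = p30_fraction),
    auc       = function(obs, pred, egfr_pre)
      roc_auc_nbgfr45(egfr_pre, obs, pred,
                      threshold = nbgfr_threshold,
                      subset_threshold = preop_subset_threshold)$auc
  )
}

#' Percentile bootstrap confidence interval for one prediction metric
#'
#' Resamples patients with replacement and recomputes the metric on each
#' resample; the CI is the percentile interval of the bootstrap distribution.
#' Resamples on which the metric is undefined (e.g. a single-class AUC
#' resample) are dropped and counted.
#'
#' @param observed,predicted Observed and predicted NBGFR vectors.
#' @param metric One of `"r"`, `"bias"`, `"precision"`, `"mse"`, `"p30"`,
#'   `"auc"`.
#' @param egfr_pre_global Preoperative global eGFR; required for
#'   `metric = "auc"` (subset rule).
#' @param n_resamples Number of bootstrap resamples; default 1000.
#' @param seed Integer RNG seed; required — bootstrap output must be
#'   reproducible.
#' @param conf Confidence level; default 0.95.
#' @param ... Passed to the metric (`p30_fraction`, `nbgfr_threshold`,
#'   `preop_subset_threshold`).
#' @return List with `estimate`, `ci_lower`, `ci_upper`, `n`, `n_resamples`,
#'   `n_degenerate`.
#' @export
bootstrap_metric_ci <- function(observed, predicted, metric,
                                egfr_pre_global = NULL,
                                n_resamples = 1000, seed, conf = 0.95, ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_resamples < 1) stop("`n_resamples` must be >= 1", call. = FALSE)
  fn <- make_metric_fn(metric, ...)
  n <- length(observed)
  est <- fn(observed, predicted, egfr_pre_global)
  set.seed(seed)
  stat <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(fn(observed[idx], predicted[idx], egfr_pre_global[idx]),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- stat[!is.na(stat)]
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(estimate = est, ci_lower = ci[1], ci_upper = ci[2], n = n,
       n_resamples = n_resamples, n_degenerate = sum(is.na(stat)))
}

#' Paired bootstrap comparison of two SRF methods on one metric
#'
#' Resamples patients with replacement (the same patients for both methods —
#' a paired design), recomputes the metric difference `method_a - method_b`
#' per resample, and reports a two-sided p-value by the doubled-tail rule
#' \deqn{p = 2 \min\{\#(d \le 0) + 1,\; \#(d \ge 0) + 1\} / (B + 1)}
#' capped at 1 (the add-one correction keeps p strictly positive), plus the
#' percentile CI of the difference.
#'
#' @inheritParams bootstrap_metric_ci
#' @param predicted_a,predicted_b The two methods' predicted NBGFR vectors,
#'   aligned to `observed`.
#' @param method_a,method_b Labels for reporting.
#' @return A list of class `bootstrap_comparison`: `metric`, `method_a`,
#'   `method_b`, `observed_difference`, `p_value`, `ci_lower`, `ci_upper`,
#'   `n`, `n_resamples`, `seed`.
#' @export
bootstrap_compare <- function(observed, predicted_a, predicted_b, metric,
                              egfr_pre_global = NULL,
                              method_a = "A", method_b = "B",
                              n_resamples = 1000, seed, conf = 0.95, ...) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_resamples < 1) stop("`n_resamples` must be >= 1", call. = FALSE)
  if (length(predicted_a) != length(observed) ||
      length(predicted_b) != length(observed)) {
    stop("both methods' predictions must align with `observed`",
         call. = FALSE)
  }
  fn <- make_metric_fn(metric, ...)
  n <- length(observed)
  obs_diff <- fn(observed, predicted_a, egfr_pre_global) -
    fn(observed, predicted_b, egfr_pre_global)
  set.seed(seed)
  diffs <- vapply(seq_len(n_resamples), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(
      fn(observed[idx], predicted_a[idx], egfr_pre_global[idx]) -
        fn(observed[idx], predicted_b[idx], egfr_pre_global[idx]),
      error = function(e) NA_real_)
  }, numeric(1))
  d <- diffs[!is.na(diffs)]
  B <- length(d)
  p <- min(1, 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (B + 1))
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(d, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(
    list(metric = metric, method_a = method_a, method_b = method_b,
         observed_difference = obs_diff, p_value = p,
         ci_lower = ci[1], ci_upper = ci[2], n = n,
         n_resamples = n_resamples, n_degenerate = sum(is.na(diffs)),
         seed = seed),
    class = "bootstrap_comparison"
  )
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf(
    "%s difference (%s - %s): %.4g [%.4g, %.4g], p = %.4g (B = %d, n = %d)\n",
    x$metric, x$method_a, x$method_b, x$observed_difference,
    x$ci_lower, x$ci_upper, x$p_value, x$n_resamples, x$n))
  invisible(x)
}

#' Full metric suite for one SRF method
#'
#' Computes Pearson r, bias, precision (IQR of residuals), MSE, P30 accuracy
#' and the threshold AUC for one method's predictions, each with a percentile
#' bootstrap CI. AUC follows the subset rule (preoperative global GFR above
#' the subset threshold); if the subset degenerates to one outcome class the
#' AUC fields are `NA`.
#'
#' @inheritParams bootstrap_metric_ci
#' @param method Label (`"NRS"`, `"PVA"`, `"LWH"`, ...).
#' @return A one-row data frame: `method`, `n`, then
#'   `<metric>`, `<metric>_lo`, `<metric>_hi` for `r`, `bias`, `precision`,
#'   `mse`, `p30`, `auc`, plus `auc_n` (subset size).
#' @export
evaluate_method <- function(observed, predicted, egfr_pre_global,
                            method = "method", n_resamples = 1000, seed,
                            p30_fraction = 0.30, nbgfr_threshold = 45,
                            preop_subset_threshold = 45) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  out <- data.frame(method = method, n = length(observed),
                    stringsAsFactors = FALSE)
  for (m in metric_choices) {
    res <- tryCatch(
      bootstrap_metric_ci(observed, predicted, m,
                          egfr_pre_global = egfr_pre_global,
                          n_resamples = n_resamples, seed = seed,
                          p30_fraction = p30_fraction,
                          nbgfr_threshold = nbgfr_threshold,
                          preop_subset_threshold = preop_subset_threshold),
      error = function(e) list(estimate = NA_real_, ci_lower = NA_real_,
                               ci_upper = NA_real_))
    out[[m]] <- res$estimate
    out[[paste0(m, "_lo")]] <- res$ci_lower
    out[[paste0(m, "_hi")]] <- res$ci_upper
  }
  out$auc_n <- tryCatch(
    roc_auc_nbgfr45(egfr_pre_global, observed, predicted,
                    threshold = nbgfr_threshold,
                    subset_threshold = preop_subset_threshold)$n,
    error = function(e) NA_integer_)
  out
}
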