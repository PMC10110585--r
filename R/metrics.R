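#' Prediction residuals
#'
#' Elementwise observed minus predicted NBGFR.
#'
#' @param observed,predicted Numeric vectors of equal length, no missing
#'   values; mL/min/1.73 m².
#' @return Numeric vector of residuals.
#' @export
nbgfr_residuals <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(observed) < 1) {
    stop("at least one observation required", call. = FALSE)
  }
  if (anyNA(observed) || anyNA(predicted)) {
    stop("missing values are not allowed in metric inputs", call. = FALSE)
  }
  observed - predicted
}

#' Bias: median residual
#'
#' Median of the residuals (observed - predicted). Positive bias means the
#' model underpredicts.
#' @inheritParams nbgfr_residuals
#' @return Bias in mL/min/1.73 m².
#' @export
nbgfr_bias <- function(observed, predicted) {
  stats::median(nbgfr_residuals(observed, predicted))
}

#' Precision: interquartile range of the residuals
#'
#' Q3 - Q1 of the residual distribution, using linear-interpolation quantiles
#' (R's default type 7). Smaller is more precise.
#' @inheritParams nbgfr_residuals
#' @return IQR in mL/min/1.73 m².
#' @export
nbgfr_precision <- function(observed, predicted) {
  r <- nbgfr_residuals(observed, predicted)
  unname(diff(stats::quantile(r, c(0.25, 0.75), type = 7)))
}

#' Mean squared error
#'
#' \eqn{\frac{1}{n}\sum_i (Y_i - Y^*_i)^2} between observed and predicted
#' NBGFR.
#' @inheritParams nbgfr_residuals
#' @return MSE in (mL/min/1.73 m²)².
#' @export
nbgfr_mse <- function(observed, predicted) {
  mean(nbgfr_residuals(observed, predicted)^2)
}

#' P30 accuracy
#'
#' Percentage of predictions within a relative tolerance of the observed
#' value: \eqn{|pred - obs| \le f \cdot obs} with `fraction = 0.30` by
#' default. The boundary counts as within.
#' @inheritParams nbgfr_residuals
#' @param fraction Relative tolerance; default 0.30.
#' @return Accuracy in percent (0-100).
#' @export
p30_accuracy <- function(observed, predicted, fraction = 0.30) {
  r <- nbgfr_residuals(observed, predicted) # validates inputs
  100 * mean(abs(r) <= fraction * observed)
}

#' Pearson correlation between observed and predicted NBGFR
#'
#' Standard product-moment correlation; errors rather than returning `NA`
#' when either vector is constant.
#' @inheritParams nbgfr_residuals
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(observed, predicted) {
  nbgfr_residuals(observed, predicted) # length/NA validation
  if (length(observed) < 3) {
    stop("Pearson correlation requires at least 3 pairs", call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("correlation undefined: zero variance in observed or predicted",
         call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Rank-statistic AUC with midrank tie handling
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic:
#' \eqn{AUC = (\bar R_1 - (n_1+1)/2) / n_0} where \eqn{\bar R_1} is the mean
#' midrank of the positive scores. Tied score pairs count one half.
#'
#' @param labels Logical (or 0/1) outcome labels; both classes must occur.
#' @param scores Numeric prediction scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have equal length", call. = FALSE)
  }
  if (anyNA(labels) || anyNA(scores)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: only one outcome class present", call. = FALSE)
  }
  ranks <- rank(scores, ties.method = "average")
  (mean(ranks[labels]) - (n1 + 1) / 2) / n0
}

#' Threshold discrimination of predicted NBGFR
#'
#' Evaluates how well predicted NBGFR discriminates observed NBGFR above a
#' clinical threshold (default 45 mL/min/1.73 m²). Following the study
#' design, the analysis is restricted to patients whose preoperative global
#' GFR already exceeds the subset threshold (strict inequalities on both):
#' patients below it can rarely reach the postoperative target, and including
#' them inflates discrimination.
#'
#' @param egfr_pre_global Preoperative global eGFR per patient.
#' @param observed Observed NBGFR per patient.
#' @param predicted Predicted NBGFR per patient (the ROC score).
#' @param threshold Label threshold on observed NBGFR; default 45.
#' @param subset_threshold Preoperative subset threshold; default 45.
#' @return List with `auc`, `n` (subset size), and `n_positive`.
#' @export
roc_auc_nbgfr45 <- function(egfr_pre_global, observed, predicted,
                            threshold = 45, subset_threshold = 45) {
  if (length(unique(c(length(egfr_pre_global), length(observed),
                      length(predicted)))) != 1) {
    stop("inputs must have equal length", call. = FALSE)
  }
  keep <- !is.na(egfr_pre_global) & egfr_pre_global > subset_threshold
  if (sum(keep) == 0) {
    stop("no patients with preoperative global GFR above the subset threshold",
         call. = FALSE)
  }
  labels <- observed[keep] > threshold
  list(auc = roc_auc(labels, predicted[keep]),
       n = sum(keep), n_positive = sum(labels))
}
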