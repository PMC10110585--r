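#' Predict the new baseline GFR after radical nephrectomy
#'
#' The point-of-care compensation model: the kidney that remains after
#' radical nephrectomy carries its preoperative share of global function
#' (the contralateral split renal function, SRF) and then hypertrophies by a
#' renal functional compensation (RFC) multiplier, so
#' \deqn{NBGFR = RFC \times GlobalGFR_{pre} \times SRF_{contralateral}.}
#' RFC defaults to 1.25, the literature average for adult compensatory
#' hypertrophy 3-12 months after nephrectomy (typical range 1.20-1.30).
#'
#' @param global_gfr_pre Preoperative global eGFR, mL/min/1.73 m²; positive.
#' @param srf_contralateral Contralateral kidney's fraction of global
#'   function, in \[0, 1\].
#' @param rfc Renal functional compensation multiplier; positive.
#' @return Predicted new baseline GFR, mL/min/1.73 m².
#' @examples
#' predict_nbgfr(70, 0.557)        # 48.74
#' predict_nbgfr(70, 0.5, rfc = 1) # no compensation: half of global GFR
#' @export
predict_nbgfr <- function(global_gfr_pre, srf_contralateral, rfc = 1.25) {
  if (anyNA(global_gfr_pre) || any(global_gfr_pre <= 0)) {
    stop("`global_gfr_pre` must be positive", call. = FALSE)
  }
  if (anyNA(srf_contralateral) ||
      any(srf_contralateral < 0 | srf_contralateral > 1)) {
    stop("`srf_contralateral` must lie in [0, 1]", call. = FALSE)
  }
  if (anyNA(rfc) || any(rfc <= 0)) {
    stop("`rfc` must be a positive multiplier", call. = FALSE)
  }
  rfc * global_gfr_pre * srf_contralateral
}

#' Renal functional compensation as a percentage
#'
#' Percent change from the preoperative contralateral eGFR to the observed
#' postoperative eGFR:
#' `100 * (egfr_post - egfr_contra_pre) / egfr_contra_pre`. Positive values
#' indicate compensatory hypertrophy of the remaining kidney; negative values
#' are possible when function declines.
#'
#' @param egfr_contra_pre Preoperative contralateral eGFR, mL/min/1.73 m²;
#'   positive.
#' @param egfr_post Postoperative (new baseline) eGFR, mL/min/1.73 m².
#' @return Compensation in percent.
#' @examples
#' rfc_percent(40, 50) # 25% compensation
#' @export
rfc_percent <- function(egfr_contra_pre, egfr_post) {
  if (anyNA(egfr_contra_pre) || any(egfr_contra_pre <= 0)) {
    stop("`egfr_contra_pre` must be positive", call. = FALSE)
  }
  100 * (egfr_post - egfr_contra_pre) / egfr_contra_pre
}

#' Construct a split-renal-function estimate from a pair of raw signals
#'
#' Normalises a (contralateral, ipsilateral) pair of non-negative raw values
#' (parenchymal volumes, tracer uptakes, ...) into complementary fractions
#' that sum to exactly 1.
#'
#' @param contra,ipsi Non-negative raw values; their sum must be positive.
#' @param method Label for how the raw signal was obtained: `"NRS"`,
#'   `"PVA"`, or `"LWH"`.
#' @return A list of class `srf_estimate` with elements `method`,
#'   `srf_contralateral`, `srf_ipsilateral`.
#' @examples
#' srf_estimate(210, 190, method = "PVA")
#' @export
srf_estimate <- function(contra, ipsi, method = c("PVA", "LWH", "NRS")) {
  method <- match.arg(method)
  if (anyNA(c(contra, ipsi)) || contra < 0 || ipsi < 0) {
    stop("raw SRF inputs must be non-negative", call. = FALSE)
  }
  total <- contra + ipsi
  if (total <= 0) {
    stop("raw SRF inputs must have a positive sum", call. = FALSE)
  }
  s <- contra / total
  structure(
    list(method = method, srf_contralateral = s, srf_ipsilateral = 1 - s),
    class = "srf_estimate"
  )
}

#' @export
print.srf_estimate <- function(x, ...) {
  pair <- srf_percent_display(x$srf_contralateral)
  cat(sprintf("SRF (%s): contralateral %d%% / ipsilateral %d%%\n",
              x$method, pair[["contralateral"]], pair[["ipsilateral"]]))
  invisible(x)
}

#' Apply the cohort inclusion filter
#'
#' Retains patients eligible for the prediction analysis: preoperative global
#' eGFR strictly above 15 mL/min/1.73 m² and an observed new baseline GFR on
#' record. Exclusion reasons are returned row-per-exclusion in the
#' `"exclusions"` attribute and summarised with a message.
#'
#' @param cohort A cohort data frame (see [read_cohort()]) with columns
#'   `patient_id`, `egfr_pre_global`, `egfr_nbgfr_observed`.
#' @param min_egfr Inclusion threshold, strict; default 15.
#' @param quiet Suppress the summary message.
#' @return The retained rows, with attribute `"exclusions"`: a data frame of
#'   `patient_id`, `reason`.
#' @export
apply_inclusion_filter <- function(cohort, min_egfr = 15, quiet = FALSE) {
  stopifnot(is.data.frame(cohort))
  need <- c("patient_id", "egfr_pre_global", "egfr_nbgfr_observed")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  low_gfr <- is.na(cohort$egfr_pre_global) | cohort$egfr_pre_global <= min_egfr
  no_nbgfr <- is.na(cohort$egfr_nbgfr_observed)
  reasons <- character(0)
  ids <- character(0)
  if (any(low_gfr)) {
    ids <- c(ids, cohort$patient_id[low_gfr])
    reasons <- c(reasons, rep(
      sprintf("preoperative global eGFR missing or <= %g", min_egfr),
      sum(low_gfr)))
  }
  if (any(no_nbgfr & !low_gfr)) {
    keep <- no_nbgfr & !low_gfr
    ids <- c(ids, cohort$patient_id[keep])
    reasons <- c(reasons, rep("observed NBGFR missing", sum(keep)))
  }
  retained <- cohort[!(low_gfr | no_nbgfr), , drop = FALSE]
  rownames(retained) <- NULL
  exclusions <- data.frame(patient_id = ids, reason = reasons,
                           stringsAsFactors = FALSE)
  if (!quiet && nrow(exclusions) > 0) {
    message(sprintf("inclusion filter: %d retained, %d excluded",
                    nrow(retained), nrow(exclusions)))
  }
  attr(retained, "exclusions") <- exclusions
  retained
}
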