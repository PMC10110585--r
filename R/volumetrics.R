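#' Parenchymal volumes from a software-derived volume triplet
#'
#' Software parenchymal volume analysis (PVA) reports three volumes: the
#' tumor-free contralateral parenchyma, the tumor-bearing ipsilateral
#' parenchyma including the tumor, and the tumor alone. The ipsilateral
#' parenchymal volume is the difference of the last two.
#'
#' @param vol_contra Contralateral parenchymal volume, cm³.
#' @param vol_ipsi_plus_tumor Ipsilateral parenchyma-plus-tumor volume, cm³.
#' @param vol_tumor Tumor volume, cm³; must not exceed `vol_ipsi_plus_tumor`.
#' @return Named numeric vector `c(contra = , ipsi = )` in cm³.
#' @examples
#' pva_parenchymal_volumes(210, 229, 39) # contra 210, ipsi 190
#' @export
pva_parenchymal_volumes <- function(vol_contra, vol_ipsi_plus_tumor,
                                    vol_tumor) {
  v <- c(vol_contra, vol_ipsi_plus_tumor, vol_tumor)
  if (anyNA(v) || any(v < 0)) {
    stop("all volumes must be non-negative and non-missing", call. = FALSE)
  }
  if (any(vol_tumor > vol_ipsi_plus_tumor)) {
    stop("tumor volume exceeds the ipsilateral parenchyma-plus-tumor volume",
         call. = FALSE)
  }
  c(contra = vol_contra, ipsi = vol_ipsi_plus_tumor - vol_tumor)
}

#' Ellipsoid parenchymal volume from linear LWH measurements
#'
#' Approximates a kidney's parenchymal volume from five linear measurements
#' taken on cross-sectional imaging: one maximal coronal length, two axial
#' anterior-posterior thicknesses at the polar line, and two coronal
#' medial-lateral widths at the polar line. The ellipsoid formula is
#' \deqn{V = 0.52 \times L \times \overline{AP} \times \overline{ML}}
#' (0.52 approximates \eqn{\pi/6}).
#'
#' @param length Maximal coronal length, cm.
#' @param ap1,ap2 Anterior-posterior measurements, cm.
#' @param ml1,ml2 Medial-lateral measurements, cm.
#' @return Volume in cm³.
#' @examples
#' lwh_volume(11.0, 4.2, 4.2, 4.1, 4.1) # 98.5 cm^3
#' @export
lwh_volume <- function(length, ap1, ap2, ml1, ml2) {
  m <- cbind(length, ap1, ap2, ml1, ml2)
  if (anyNA(m) || any(m <= 0)) {
    stop("all five LWH measurements must be positive", call. = FALSE)
  }
  short <- length < pmax(ap1, ap2, ml1, ml2)
  if (any(short)) {
    warning("kidney length shorter than a thickness/width measurement; ",
            "anatomically implausible", call. = FALSE)
  }
  0.52 * length * (ap1 + ap2) / 2 * (ml1 + ml2) / 2
}

#' Split renal function from a pair of parenchymal volumes
#'
#' Normalises the contralateral parenchymal volume by the total (contralateral
#' plus ipsilateral) parenchymal volume. This is the volume-share surrogate
#' for the contralateral kidney's share of global filtration.
#'
#' @param vol_contra,vol_ipsi Parenchymal volumes, cm³; non-negative with a
#'   positive sum.
#' @param method Label passed through to [srf_estimate()].
#' @return An `srf_estimate` (fractions summing to 1).
#' @examples
#' srf_from_volumes(210, 190)$srf_contralateral # 0.525
#' @export
srf_from_volumes <- function(vol_contra, vol_ipsi, method = "PVA") {
  srf_estimate(vol_contra, vol_ipsi, method = method)
}

#' Whole-percent display of a split-renal-function pair
#'
#' Rounds `100 * srf` half away from zero (so 52.5 displays as 53) and
#' defines the complement by subtraction, so the displayed pair always sums
#' to exactly 100.
#'
#' @param srf Contralateral SRF fraction in \[0, 1\].
#' @return Named integer vector `c(contralateral = , ipsilateral = )`.
#' @examples
#' srf_percent_display(0.525)  # 53 / 47
#' srf_percent_display(0.4924) # 49 / 51
#' @export
srf_percent_display <- function(srf) {
  if (anyNA(srf) || srf < 0 || srf > 1) {
    stop("`srf` must be a fraction in [0, 1]", call. = FALSE)
  }
  contra <- as.integer(floor(100 * srf + 0.5))
  c(contralateral = contra, ipsilateral = 100L - contra)
}

#' Inter-rater SRF concordance for LWH measurements
#'
#' Compares two raters' LWH measurement sets for the same patients: each
#' rater's per-patient SRF is computed from their own contralateral and
#' ipsilateral measurements, and the discrepancy is the absolute difference
#' in contralateral SRF, reported in percentage points.
#'
#' @param rater_a,rater_b Data frames with one row per patient and columns
#'   `contra_length, contra_ap1, contra_ap2, contra_ml1, contra_ml2` and the
#'   same five with prefix `ipsi_`.
#' @return A list with per-patient `discrepancy_pct` and its `mean`, `min`,
#'   `max` (percentage points of SRF).
#' @export
compare_raters <- function(rater_a, rater_b) {
  stopifnot(is.data.frame(rater_a), is.data.frame(rater_b),
            nrow(rater_a) == nrow(rater_b))
  srf_of <- function(d) {
    vc <- lwh_volume(d$contra_length, d$contra_ap1, d$contra_ap2,
                     d$contra_ml1, d$contra_ml2)
    vi <- lwh_volume(d$ipsi_length, d$ipsi_ap1, d$ipsi_ap2,
                     d$ipsi_ml1, d$ipsi_ml2)
    vc / (vc + vi)
  }
  disc <- 100 * abs(srf_of(rater_a) - srf_of(rater_b))
  list(discrepancy_pct = disc, mean = mean(disc),
       min = min(disc), max = max(disc))
}
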