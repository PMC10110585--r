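#' Estimate GFR from serum creatinine with the CKD-EPI equations
#'
#' Implements the CKD-EPI creatinine equations in their 2009 form (with the
#' Black race coefficient) and the 2021 race-free refit. Both are piecewise
#' power functions of creatinine with a sex-specific knot `kappa` and an
#' exponential age decline.
#'
#' The 2009 equation is
#' \deqn{141 \cdot \min(Scr/\kappa, 1)^{\alpha} \cdot \max(Scr/\kappa, 1)^{-1.209}
#'       \cdot 0.993^{age} \cdot 1.018[\mathrm{female}] \cdot 1.159[\mathrm{Black}]}
#' with \eqn{\kappa = 0.7} (female) or 0.9 (male) and \eqn{\alpha = -0.329}
#' (female) or \eqn{-0.411} (male). The 2021 refit replaces the leading
#' constant with 142, the upper exponent with -1.200, the age base with
#' 0.9938, the female multiplier with 1.012, \eqn{\alpha} with -0.241
#' (female) / -0.302 (male), and drops the race coefficient entirely.
#'
#' @param scr Serum creatinine in mg/dL; positive.
#' @param age Age in years; must be >= 18 (adult equations only).
#' @param sex `"male"` or `"female"`.
#' @param race_black Logical; identifies as Black for the 2009 race
#'   coefficient. Required (non-missing) when `variant = "2009"`; ignored by
#'   the 2021 equation.
#' @param variant `"2021"` (default, race-free) or `"2009"`.
#'
#' @return Estimated GFR in mL/min/1.73 m², same length as the inputs
#'   (recycled to common length).
#'
#' @examples
#' ckd_epi_egfr(0.9, age = 50, sex = "male")
#' ckd_epi_egfr(0.9, age = 50, sex = "male", race_black = FALSE, variant = "2009")
#' @export
ckd_epi_egfr <- function(scr, age, sex, race_black = NA,
                         variant = c("2021", "2009")) {
  variant <- match.arg(variant)
  n <- max(length(scr), length(age), length(sex), length(race_black))
  scr <- rep_len(as.numeric(scr), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  race_black <- rep_len(race_black, n)

  if (anyNA(scr) || any(scr <= 0)) {
    stop("`scr` must be positive serum creatinine in mg/dL", call. = FALSE)
  }
  if (anyNA(age) || any(age < 18)) {
    stop("`age` must be >= 18 years (adult CKD-EPI equations only)",
         call. = FALSE)
  }
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be \"male\" or \"female\"", call. = FALSE)
  }
  female <- sex == "female"

  if (variant == "2009") {
    if (anyNA(race_black)) {
      stop("the 2009 CKD-EPI equation requires a non-missing `race_black`; ",
           "refusing to assume a default", call. = FALSE)
    }
    race_black <- as.logical(race_black)
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.329, -0.411)
    egfr <- 141 *
      pmin(scr / kappa, 1)^alpha *
      pmax(scr / kappa, 1)^-1.209 *
      0.993^age *
      ifelse(female, 1.018, 1) *
      ifelse(race_black, 1.159, 1)
  } else {
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.241, -0.302)
    egfr <- 142 *
      pmin(scr / kappa, 1)^alpha *
      pmax(scr / kappa, 1)^-1.200 *
      0.9938^age *
      ifelse(female, 1.012, 1)
  }
  egfr
}
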