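#' Column schema of the cohort CSV
#'
#' One row per patient. Units are fixed: years (age), mg/dL (creatinine),
#' mL/min/1.73 m² (eGFR), cm³ (volumes), cm (LWH measurements). Empty cells
#' are missing values; `sex` is `male`/`female`; `race_black` is
#' `TRUE`/`FALSE`.
#'
#' @return Character vector of the required column names, in order.
#' @export
cohort_columns <- function() {
  c("patient_id", "age", "sex", "race_black", "scr_pre", "egfr_pre_global",
    "egfr_nbgfr_observed", "srf_nrs",
    "vol_contra", "vol_ipsi_plus_tumor", "vol_tumor",
    paste0("lwh_contra_", c("length", "ap1", "ap2", "ml1", "ml2")),
    paste0("lwh_ipsi_", c("length", "ap1", "ap2", "ml1", "ml2")))
}

#' Write a cohort data frame as CSV
#'
#' RFC-4180 CSV, UTF-8, "." decimal separator, header exactly the schema of
#' [cohort_columns()]. Full floating precision is preserved.
#'
#' @param cohort Cohort data frame.
#' @param path Output file path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(cohort[, cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, na = "")
}

# per-row field checks; returns character vector of problems (empty if ok)
validate_cohort_row <- function(row) {
  bad <- character(0)
  chk <- function(cond, msg) if (isTRUE(cond)) bad <<- c(bad, msg)
  num <- function(f) suppressWarnings(as.numeric(row[[f]]))
  chk(is.na(row[["patient_id"]]) || !nzchar(row[["patient_id"]]),
      "patient_id missing")
  if (!is.na(row[["age"]])) chk(num("age") <= 0, "age must be > 0")
  if (!is.na(row[["sex"]])) {
    chk(!row[["sex"]] %in% c("male", "female"),
        "sex must be 'male' or 'female'")
  }
  if (!is.na(row[["scr_pre"]])) chk(num("scr_pre") <= 0, "scr_pre must be > 0")
  for (f in c("srf_nrs")) {
    v <- num(f)
    if (!is.na(v)) chk(v <= 0 || v >= 1, paste(f, "must lie in (0,1)"))
  }
  vols <- c("vol_contra", "vol_ipsi_plus_tumor", "vol_tumor")
  vv <- vapply(vols, num, numeric(1))
  chk(any(!is.na(vv) & vv < 0), "volumes must be >= 0")
  if (!anyNA(vv)) {
    chk(vv[["vol_tumor"]] > vv[["vol_ipsi_plus_tumor"]],
        "vol_tumor exceeds vol_ipsi_plus_tumor")
  }
  for (side in c("contra", "ipsi")) {
    f <- paste0("lwh_", side, "_", c("length", "ap1", "ap2", "ml1", "ml2"))
    lv <- vapply(f, num, numeric(1))
    chk(any(!is.na(lv) & lv <= 0),
        paste("LWH", side, "measurements must be > 0"))
  }
  bad
}

#' Read and validate a cohort CSV
#'
#' Parses the cohort CSV (schema of [cohort_columns()]), validates every row,
#' and resolves the preoperative global eGFR: an explicit `egfr_pre_global`
#' wins; otherwise it is computed from `scr_pre` via [ckd_epi_egfr()]. When
#' both are present the explicit value is kept and a warning names the rows.
#' Malformed rows are rejected with their line numbers — collected in the
#' `"row_errors"` attribute and reported via warning, never silently dropped.
#'
#' @param path CSV file path.
#' @param ckd_epi_variant `"2021"` (default) or `"2009"`, used when eGFR must
#'   be computed from creatinine.
#' @return Validated cohort data frame; attribute `"row_errors"` is a data
#'   frame of `line`, `patient_id`, `problem` for rejected rows.
#' @export
read_cohort <- function(path, ckd_epi_variant = c("2021", "2009")) {
  ckd_epi_variant <- match.arg(ckd_epi_variant)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  schema <- cohort_columns()
  unknown <- setdiff(names(raw), schema)
  missing_cols <- setdiff(schema, names(raw))
  if (length(unknown) > 0 || length(missing_cols) > 0) {
    stop("cohort header does not match the schema",
         if (length(unknown) > 0)
           paste0("; unknown: ", paste(unknown, collapse = ", ")),
         if (length(missing_cols) > 0)
           paste0("; missing: ", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  raw <- raw[, schema]

  numeric_fields <- setdiff(schema, c("patient_id", "sex", "race_black"))
  errors <- data.frame(line = integer(0), patient_id = character(0),
                       problem = character(0), stringsAsFactors = FALSE)
  note <- function(i, problem) {
    errors <<- rbind(errors, data.frame(
      line = i + 1L, # header occupies line 1
      patient_id = ifelse(is.na(raw$patient_id[i]), "?", raw$patient_id[i]),
      problem = problem, stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(raw))) {
    for (f in numeric_fields) {
      v <- raw[[f]][i]
      if (!is.na(v) && is.na(suppressWarnings(as.numeric(v)))) {
        note(i, paste0("non-numeric value in ", f, ": '", v, "'"))
      }
    }
    if (!is.na(raw$race_black[i]) &&
        !toupper(raw$race_black[i]) %in% c("TRUE", "FALSE")) {
      note(i, "race_black must be TRUE/FALSE")
    }
    bad <- validate_cohort_row(raw[i, ])
    for (b in bad) note(i, b)
  }
  keep <- !(seq_len(nrow(raw)) + 1L) %in% errors$line
  cohort <- raw[keep, , drop = FALSE]
  for (f in numeric_fields) cohort[[f]] <- as.numeric(cohort[[f]])
  cohort$race_black <- as.logical(toupper(cohort$race_black))
  rownames(cohort) <- NULL

  if (anyDuplicated(cohort$patient_id)) {
    stop("duplicate patient_id values in cohort", call. = FALSE)
  }
  if (nrow(errors) > 0) {
    warning(sprintf("rejected %d malformed row(s); see attr(x, 'row_errors')",
                    length(unique(errors$line))), call. = FALSE)
  }

  both <- !is.na(cohort$egfr_pre_global) & !is.na(cohort$scr_pre)
  if (any(both)) {
    warning(sprintf(
      "%d row(s) supply both scr_pre and egfr_pre_global; keeping the ",
      sum(both)), "explicit eGFR", call. = FALSE)
  }
  from_scr <- is.na(cohort$egfr_pre_global) & !is.na(cohort$scr_pre)
  if (any(from_scr)) {
    cohort$egfr_pre_global[from_scr] <- ckd_epi_egfr(
      cohort$scr_pre[from_scr], cohort$age[from_scr], cohort$sex[from_scr],
      cohort$race_black[from_scr], variant = ckd_epi_variant)
  }
  attr(cohort, "row_errors") <- errors
  cohort
}

#' Resolve each method's contralateral SRF from cohort columns
#'
#' Computes, per patient, the contralateral SRF as seen by each method:
#' `NRS` reads the reported `srf_nrs` column; `PVA` normalises the software
#' volume triplet; `LWH` normalises the two ellipsoid volumes. Patients
#' missing a method's inputs get `NA` for that method.
#'
#' @param cohort Cohort data frame.
#' @return Named list (`PVA`, `NRS`, `LWH`) of SRF fraction vectors aligned
#'   with the cohort rows.
#' @export
resolve_srf <- function(cohort) {
  n <- nrow(cohort)
  pva <- rep(NA_real_, n)
  ok <- !is.na(cohort$vol_contra) & !is.na(cohort$vol_ipsi_plus_tumor) &
    !is.na(cohort$vol_tumor)
  if (any(ok)) {
    ipsi <- cohort$vol_ipsi_plus_tumor[ok] - cohort$vol_tumor[ok]
    pva[ok] <- cohort$vol_contra[ok] / (cohort$vol_contra[ok] + ipsi)
  }

  lwh <- rep(NA_real_, n)
  cf <- paste0("lwh_contra_", c("length", "ap1", "ap2", "ml1", "ml2"))
  ifl <- paste0("lwh_ipsi_", c("length", "ap1", "ap2", "ml1", "ml2"))
  ok <- stats::complete.cases(cohort[, c(cf, ifl)])
  if (any(ok)) {
    vc <- lwh_volume(cohort[ok, cf[1]], cohort[ok, cf[2]], cohort[ok, cf[3]],
                     cohort[ok, cf[4]], cohort[ok, cf[5]])
    vi <- lwh_volume(cohort[ok, ifl[1]], cohort[ok, ifl[2]],
                     cohort[ok, ifl[3]], cohort[ok, ifl[4]],
                     cohort[ok, ifl[5]])
    lwh[ok] <- vc / (vc + vi)
  }

  list(PVA = pva, NRS = cohort$srf_nrs, LWH = lwh)
}
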