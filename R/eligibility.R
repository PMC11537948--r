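#' HOMA-IR insulin-resistance index
#'
#' Homeostatic model assessment of insulin resistance from fasting values,
#' using the Matthews formulation
#' `glucose (mg/dL) x insulin (uU/mL) / 405`.
#'
#' @param glucose fasting glucose in mg/dL, > 0.
#' @param insulin fasting insulin in uU/mL, > 0.
#' @return dimensionless index.
#' @examples
#' homa_ir(90, 18)  # 4
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(glucose <= 0) ||
      any(!is.finite(insulin)) || any(insulin <= 0))
    stop("glucose and insulin must be finite and > 0", call. = FALSE)
  glucose * insulin / 405
}

# exclusion thresholds, with the comparators used for each
.elig_thresholds <- list(
  glucose        = "glucose >= 100 mg/dL",
  total_chol     = "total cholesterol >= 200 mg/dL",
  hdl            = "HDL < 40 mg/dL (< 45 mg/dL for post-pubertal girls, Tanner >= 4)",
  triglycerides  = "triglycerides >= 100 mg/dL if age < 10 y, >= 130 mg/dL if 10-19 y",
  blood_pressure = "blood pressure >= 90th percentile for age/sex/height (external reference)",
  homa_ir        = "HOMA-IR > 3.5",
  bmi_z          = "|BMI z-score| >= 3"
)

#' Metabolic-health eligibility screen
#'
#' Applies the exclusion rules that define the clinically-and-metabolically
#' healthy reference sample.  A subject is eligible iff no rule fires.  The
#' rules, with their boundary semantics exactly as stated:
#' glucose `>=` 100 mg/dL; total cholesterol `>=` 200 mg/dL; HDL `<` 40
#' mg/dL (`<` 45 for post-pubertal girls, operationalized as Tanner stage
#' `>=` 4); triglycerides `>=` 100 mg/dL under 10 years, `>=` 130 mg/dL at
#' 10-19 years; blood pressure `>=` the 90th percentile (only when an
#' external percentile reference is supplied); HOMA-IR `>` 3.5; and
#' `|BMI z| >= 3`.  Missing required data is a violation
#' (`incomplete_data`), never an exception.
#'
#' @param records cohort data.frame (see [read_cohort()]); needs `age, sex,
#'   glucose, total_chol, hdl, triglycerides, insulin, tanner, bmi_z` and,
#'   if `bp_reference` is given, `sbp, dbp, height`.
#' @param bp_reference `NULL` (rule skipped, with a message) or a function
#'   `(age, sex, height)` returning a two-column matrix/data.frame of 90th
#'   percentile `sbp` and `dbp` cut-offs.
#' @return data.frame with one logical column per criterion (`glucose`,
#'   `total_chol`, `hdl`, `triglycerides`, `blood_pressure`, `homa_ir`,
#'   `bmi_z`, `incomplete_data`), `eligible`, and a `violations` string.
#'   Attribute `bmi_z_counts` carries the counts under the at-or-beyond
#'   (`|z| >= 3`) and strict (`|z| > 3`) readings of the BMI-z rule.
#' @export
classify_eligibility <- function(records, bp_reference = NULL) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  need <- c("age", "sex", "glucose", "total_chol", "hdl", "triglycerides",
            "insulin", "tanner", "bmi_z")
  if (!is.null(bp_reference)) need <- c(need, "sbp", "dbp", "height")
  miss_cols <- setdiff(need, names(records))
  for (m in miss_cols) records[[m]] <- NA_real_

  have <- !Reduce(`|`, lapply(records[need], is.na))
  g <- records$glucose; tc <- records$total_chol; hdl <- records$hdl
  tg <- records$triglycerides; ins <- records$insulin
  age <- records$age; tanner <- records$tanner; bz <- records$bmi_z
  postpub_girl <- records$sex == "female" & !is.na(tanner) & tanner >= 4

  viol <- data.frame(
    glucose       = !is.na(g) & g >= 100,
    total_chol    = !is.na(tc) & tc >= 200,
    hdl           = !is.na(hdl) & hdl < ifelse(postpub_girl, 45, 40),
    triglycerides = !is.na(tg) & !is.na(age) &
      ((age < 10 & tg >= 100) | (age >= 10 & tg >= 130)),
    blood_pressure = rep(FALSE, n),
    homa_ir       = !is.na(g) & !is.na(ins) & g > 0 & ins > 0 &
      g * ins / 405 > 3.5,
    bmi_z         = !is.na(bz) & abs(bz) >= 3,
    incomplete_data = !have
  )
  if (is.null(bp_reference)) {
    message("no blood-pressure percentile reference configured; BP rule skipped")
  } else {
    cut <- bp_reference(age, records$sex, records$height)
    viol$blood_pressure <- !is.na(records$sbp) & !is.na(records$dbp) &
      (records$sbp >= cut[[1]] | records$dbp >= cut[[2]])
  }
  crit <- names(viol)
  viol$eligible <- !Reduce(`|`, viol[crit])
  viol$violations <- vapply(seq_len(n), function(i) {
    paste(crit[unlist(viol[i, crit])], collapse = ";")
  }, character(1))
  if (!is.null(records$id)) viol <- cbind(id = records$id, viol)
  attr(viol, "bmi_z_counts") <- c(
    at_or_beyond_3 = sum(!is.na(bz) & abs(bz) >= 3),
    beyond_3 = sum(!is.na(bz) & abs(bz) > 3))
  attr(viol, "thresholds") <- .elig_thresholds
  viol
}

#' Robust anthropometric outlier flags
#'
#' Flags subjects whose height, weight or BMI lies more than 4 robust
#' standard deviations from the centre of their sex-by-1-year-age band,
#' using the median and the MAD (consistency constant 1.4826).  Weight and
#' BMI are screened on the log scale: pediatric weight and adiposity are
#' strongly right-skewed, and a symmetric robust z on the raw scale flags
#' the healthy upper tail (4 raw-scale MADs sit near the 99th centile when
#' the Box-Cox power is around -1) rather than data errors; gross errors
#' (for example a 10-fold weight) remain many log-scale MADs out.  Bands
#' with fewer than 8 subjects are skipped with a warning.  A zero MAD
#' within a band yields no flags for values equal to the median; values
#' differing from a zero-MAD median are treated as infinitely outlying.
#'
#' @param records cohort data.frame with `sex`, `age`, `height`, `weight`.
#' @param threshold robust-z cut-off, default 4.
#' @return logical vector, `TRUE` = outlier, ordered as the input rows
#'   (order-independent per subject: flags depend only on band membership).
#' @export
anthropometric_outlier_filter <- function(records, threshold = 4) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  h <- records$height
  w <- log(records$weight)
  bmi <- w - 2 * log(h / 100)
  band <- interaction(records$sex, floor(records$age), drop = TRUE)
  flag <- rep(FALSE, nrow(records))
  for (b in levels(band)) {
    i <- which(band == b)
    if (length(i) < 8L) {
      warning(sprintf("band %s has %d subjects (< 8); outlier screen skipped",
                      b, length(i)), call. = FALSE)
      next
    }
    for (v in list(h, w, bmi)) {
      x <- v[i]
      med <- stats::median(x, na.rm = TRUE)
      mad <- stats::mad(x, na.rm = TRUE)  # constant 1.4826
      rz <- if (mad > 0) abs(x - med) / mad else
        ifelse(abs(x - med) > 0, Inf, 0)
      flag[i] <- flag[i] | (!is.na(rz) & rz > threshold)
    }
  }
  flag
}
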