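#' Slaughter two-site skinfold equation for percent body fat
#'
#' Sex-specific linear prediction of fat-mass percentage from the triceps and
#' calf skinfolds (mm):
#' males `0.735 * (triceps + calf) + 1.0`, females
#' `0.610 * (triceps + calf) + 5.1`.
#'
#' @param sex `"female"` or `"male"` (recycled).
#' @param triceps,calf skinfold thicknesses in mm, >= 0.
#' @return percent fat mass.
#' @examples
#' slaughter_fm_percent("male", 10, 10)    # 15.7
#' slaughter_fm_percent("female", 10, 10)  # 17.3
#' @export
slaughter_fm_percent <- function(sex, triceps, calf) {
  sex <- match_sex(sex)
  if (any(!is.finite(triceps)) || any(!is.finite(calf)) ||
      any(triceps < 0) || any(calf < 0))
    stop("skinfolds must be finite and >= 0", call. = FALSE)
  s <- triceps + calf
  out <- ifelse(sex == "male", 0.735 * s + 1.0, 0.610 * s + 5.1)
  if (any(out >= 100))
    stop("implausible skinfolds: predicted fat percentage >= 100%",
         call. = FALSE)
  out
}

#' Fat mass, fat-free mass and height-normalized indices
#'
#' `fat_mass_kg()` converts a fat fraction to mass (`fm_pct/100 * weight`),
#' `fat_free_mass_kg()` is the complement (`weight - fm_kg`), and
#' `mass_index()` normalizes any component mass for body size as
#' `mass / (height/100)^2` (kg/m^2), the definition of FMI/FFMI/LMI.
#'
#' @param fm_pct percent fat mass, in `[0, 100)`.
#' @param weight body weight in kg, > 0.
#' @param fm_kg fat mass in kg, in `[0, weight]`.
#' @param mass component mass in kg.
#' @param height stature in cm, > 0.
#' @return kg for the masses, kg/m^2 for `mass_index()`.
#' @examples
#' fm <- fat_mass_kg(15.7, 30)      # 4.71 kg
#' fat_free_mass_kg(30, fm)         # 25.29 kg
#' mass_index(fm, 100)              # 4.71 kg/m^2
#' @export
fat_mass_kg <- function(fm_pct, weight) {
  if (any(!is.finite(fm_pct)) || any(fm_pct < 0) || any(fm_pct >= 100))
    stop("fm_pct must be in [0, 100)", call. = FALSE)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be > 0", call. = FALSE)
  fm_pct / 100 * weight
}

#' @rdname fat_mass_kg
#' @export
fat_free_mass_kg <- function(weight, fm_kg) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be > 0", call. = FALSE)
  if (any(!is.finite(fm_kg)) || any(fm_kg < 0) || any(fm_kg > weight))
    stop("fm_kg must be in [0, weight]", call. = FALSE)
  weight - fm_kg
}

#' @rdname fat_mass_kg
#' @export
mass_index <- function(mass, height) {
  if (any(!is.finite(height)) || any(height <= 0))
    stop("height must be > 0 (cm)", call. = FALSE)
  mass / (height / 100)^2
}

#' Mean of per-device multifrequency-BIA estimates
#'
#' Subjects were measured with up to three MF-BIA devices; the subject-level
#' estimate is the arithmetic mean of the available device readings.
#'
#' @param estimates numeric vector of 1-3 per-device values (kg); `NA`s are
#'   dropped.
#' @return the mean of the available values.
#' @examples
#' average_bia(c(4.0, 4.2, 4.4))  # 4.2
#' @export
average_bia <- function(estimates) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0L)
    stop("no device estimates available (missing data)", call. = FALSE)
  if (length(estimates) > 3L)
    stop("at most three device estimates are supported", call. = FALSE)
  if (any(!is.finite(estimates)))
    stop("device estimates must be finite", call. = FALSE)
  mean(estimates)
}

#' Skeletal muscle mass by an injected anthropometric equation
#'
#' Skeletal muscle mass prediction equations of the Lee / Poortmans type are
#' linear in anthropometric covariates; no default coefficient set is shipped
#' (the coefficients live in the original publications, not here), so the
#' equation is a plug-in: supply `coeffs` as a named list with an `intercept`
#' and one coefficient per record field.
#'
#' @param record a one-row data.frame or named list with the covariates the
#'   coefficient set requires.
#' @param coeffs named list: `intercept` plus named covariate coefficients,
#'   or `NULL` (the default) when no equation is configured.
#' @return estimated skeletal muscle mass in kg, or `NA_real_` when `coeffs`
#'   is `NULL`.
#' @examples
#' smm_lee_poortmans(list(height = 150), coeffs = NULL)  # NA
#' smm_lee_poortmans(list(height = 150),
#'                   coeffs = list(intercept = 2, height = 0.1))
#' @export
smm_lee_poortmans <- function(record, coeffs = NULL) {
  if (is.null(coeffs)) return(NA_real_)
  if (is.null(coeffs$intercept))
    stop("coefficient set must include an intercept", call. = FALSE)
  out <- coeffs$intercept
  for (nm in setdiff(names(coeffs), "intercept")) {
    v <- record[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop(sprintf("record is missing field '%s' required by the coefficient set", nm),
           call. = FALSE)
    out <- out + coeffs[[nm]] * v
  }
  out
}

match_sex <- function(sex) {
  sex <- as.character(sex)
  ok <- sex %in% c("female", "male")
  if (any(!ok)) stop("sex must be 'female' or 'male'", call. = FALSE)
  sex
}

#' Derive body-composition rows for a cohort
#'
#' Computes, for every subject and each measurement method, the fat-mass
#' percentage, fat mass, fat-free mass and the height-normalized indices
#' FMI and FFMI (kg/m^2):
#' \describe{
#'   \item{SF}{percent fat from the Slaughter skinfold equation; FM =
#'     fraction x weight; FFM = weight - FM.}
#'   \item{MFBIA}{FM and FFM as the mean over the available devices
#'     (columns `bia1_fm` ... `bia3_fm`, `bia1_ffm` ...).}
#'   \item{DXA}{FM as measured; FFM = lean mass + bone mineral content
#'     (measured components, not derived from weight).}
#' }
#'
#' @param records cohort data.frame; see [read_cohort()] for the column
#'   contract.  Rows with the fields for a method missing yield no row for
#'   that method.
#' @param methods subset of `c("SF", "MFBIA", "DXA")`.
#' @return long data.frame: `id, sex, age, method, fm_pct, fm_kg, ffm_kg,
#'   fmi, ffmi`.
#' @export
derive_body_composition <- function(records,
                                    methods = c("SF", "MFBIA", "DXA")) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.data.frame(records))
  out <- list()
  base <- records[, c("id", "sex", "age")]
  h <- records$height
  w <- records$weight

  if ("SF" %in% methods) {
    ok <- stats::complete.cases(records[, c("triceps_sf", "calf_sf",
                                            "weight", "height")])
    if (any(ok)) {
      pct <- slaughter_fm_percent(records$sex[ok], records$triceps_sf[ok],
                                  records$calf_sf[ok])
      fm <- fat_mass_kg(pct, w[ok])
      ffm <- fat_free_mass_kg(w[ok], fm)
      out$SF <- data.frame(base[ok, ], method = "SF", fm_pct = pct,
                           fm_kg = fm, ffm_kg = ffm,
                           fmi = mass_index(fm, h[ok]),
                           ffmi = mass_index(ffm, h[ok]))
    }
  }
  if ("MFBIA" %in% methods) {
    fm_cols <- intersect(paste0("bia", 1:3, "_fm"), names(records))
    ffm_cols <- intersect(paste0("bia", 1:3, "_ffm"), names(records))
    if (length(fm_cols)) {
      fm_mat <- as.matrix(records[, fm_cols, drop = FALSE])
      ffm_mat <- as.matrix(records[, ffm_cols, drop = FALSE])
      n_dev <- rowSums(!is.na(fm_mat))
      ok <- n_dev > 0 & !is.na(w) & !is.na(h)
      if (any(ok)) {
        fm <- rowMeans(fm_mat[ok, , drop = FALSE], na.rm = TRUE)
        ffm <- rowMeans(ffm_mat[ok, , drop = FALSE], na.rm = TRUE)
        out$MFBIA <- data.frame(base[ok, ], method = "MFBIA",
                                fm_pct = fm / w[ok] * 100,
                                fm_kg = fm, ffm_kg = ffm,
                                fmi = mass_index(fm, h[ok]),
                                ffmi = mass_index(ffm, h[ok]))
      }
    }
  }
  if ("DXA" %in% methods && all(c("dxa_fm", "dxa_lm", "dxa_bmc") %in%
                                names(records))) {
    ok <- stats::complete.cases(records[, c("dxa_fm", "dxa_lm", "dxa_bmc",
                                            "weight", "height")])
    if (any(ok)) {
      fm <- records$dxa_fm[ok]
      ffm <- records$dxa_lm[ok] + records$dxa_bmc[ok]
      out$DXA <- data.frame(base[ok, ], method = "DXA",
                            fm_pct = fm / w[ok] * 100,
                            fm_kg = fm, ffm_kg = ffm,
                            fmi = mass_index(fm, h[ok]),
                            ffmi = mass_index(ffm, h[ok]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a cohort CSV
#'
#' One row per subject; missing values as empty fields.  Expected columns
#' (extra columns pass through): `id, sex, age, weight, height, triceps_sf,
#' calf_sf, thigh_sf, waist, hip, arm_c, thigh_c, calf_c, bia1_fm, bia1_ffm,
#' bia2_fm, bia2_ffm, bia3_fm, bia3_ffm, dxa_fm, dxa_lm, dxa_bmc, glucose,
#' total_chol, hdl, ldl, triglycerides, insulin, sbp, dbp, tanner, bmi_z`.
#' Units: years, kg, cm, mm, mg/dL (insulin in uU/mL), mmHg.
#'
#' @param path CSV file path.
#' @param records cohort data.frame.
#' @return `read_cohort()` a data.frame; `write_cohort()` invisibly `path`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", "weight", "height")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sex <- match_sex(df$sex)
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
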