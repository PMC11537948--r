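.default_levels <- c(1, 3, 5, 15, 25, 50, 75, 85, 95, 97, 99)

#' Generate a centile table from fitted LMS curves
#'
#' Tabulates reference centiles on an age grid: cell(age, p) =
#' `qbccg(p/100, L(age), M(age), S(age))`.  The 50th-centile column equals
#' the M column by construction, and each row is strictly increasing across
#' centile levels.
#'
#' @param curve an `lms_curve` from [fit_lms()], or an LMS table
#'   data.frame (columns `age, L, M, S`) whose parameters are linearly
#'   interpolated in age.
#' @param ages age grid in years; default 5 to 18 by 0.5 (a 0.25-y step is
#'   supported by passing `seq(5, 18, 0.25)`).  Must lie within the curve's
#'   age range.
#' @param levels centile levels in percent.
#' @return data.frame of class `centile_table` with columns `age, L, M, S`
#'   and one `p<level>` column per level; attributes `sex`, `variable`,
#'   `method` copied from the curve when present.
#' @export
make_centile_table <- function(curve, ages = seq(5, 18, by = 0.5),
                               levels = .default_levels) {
  stopifnot(all(levels > 0 & levels < 100), !is.unsorted(levels))
  if (inherits(curve, "lms_curve")) {
    par <- evaluate_curve(curve, ages)
    meta <- curve[c("sex", "variable", "method")]
  } else {
    par <- interpolate_lms(curve, ages)
    meta <- attributes(curve)[c("sex", "variable", "method")]
  }
  z <- stats::qnorm(levels / 100)
  cent <- vapply(seq_along(z), function(j)
    bccg_value(z[j], par$L, par$M, par$S), numeric(length(ages)))
  cent <- matrix(cent, nrow = length(ages))
  colnames(cent) <- paste0("p", levels)
  out <- cbind(par, as.data.frame(cent))
  # the 50th centile is the median parameter itself
  if ("p50" %in% colnames(cent)) out$p50 <- out$M
  structure(out, sex = meta$sex, variable = meta$variable,
            method = meta$method, levels = levels,
            class = c("centile_table", "data.frame"))
}

#' Read / write LMS reference tables (CSV)
#'
#' The interchange format for published LMS tables: a CSV with header
#' `age,L,M,S` and optionally centile columns `p1,p3,...`; ages strictly
#' increasing.  Unicode minus signs (as found in typeset tables) are
#' normalized to ASCII on read.  Values round-trip losslessly at their
#' printed precision.
#'
#' @param path CSV file path.
#' @param table a data.frame with at least `age, L, M, S`.
#' @return `read_lms_table()` a data.frame (attributes `sex`, `variable`,
#'   `method` when guessable from the file name); `write_lms_table()` the
#'   path, invisibly.
#' @export
read_lms_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c("age", "L", "M", "S")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("LMS table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(lapply(raw, function(col) {
    as.numeric(gsub("−", "-", col))
  }))
  names(df) <- names(raw)
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("non-numeric or missing LMS values at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  nonmono <- which(diff(df$age) <= 0)
  if (length(nonmono))
    stop("ages must be strictly increasing; violation at data row ",
         nonmono[1] + 1, call. = FALSE)
  df
}

#' @rdname read_lms_table
#' @export
write_lms_table <- function(table, path) {
  stopifnot(all(c("age", "L", "M", "S") %in% names(table)))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Published LMS reference tables shipped with the package
#'
#' Loads one of the packaged reference blocks: FMI or FFMI, by skinfolds
#' (SF), multifrequency BIA (MFBIA) or DXA, per sex, ages 5-18 y in 0.5-y
#' steps (the printed FFMI blocks lack the age-16.5 row).
#'
#' @param variable `"fmi"` or `"ffmi"`.
#' @param method `"sf"`, `"mfbia"` or `"dxa"` (case-insensitive).
#' @param sex `"female"` or `"male"`.
#' @return data.frame with `age, L, M, S` and centile columns `p1...p99`.
#' @examples
#' tab <- bc_reference("fmi", "dxa", "female")
#' tab[tab$age == 5, c("L", "M", "S", "p97")]
#' @export
bc_reference <- function(variable = c("fmi", "ffmi"),
                         method = c("sf", "mfbia", "dxa"),
                         sex = c("female", "male")) {
  variable <- match.arg(tolower(variable), c("fmi", "ffmi"))
  method <- match.arg(tolower(method), c("sf", "mfbia", "dxa"))
  sex <- match.arg(tolower(sex), c("female", "male"))
  path <- system.file("extdata",
                      sprintf("lms_%s_%s_%s.csv", variable, method, sex),
                      package = "bcref", mustWork = TRUE)
  tab <- read_lms_table(path)
  structure(tab, variable = toupper(variable), method = toupper(method),
            sex = sex)
}

# linear interpolation of L, M, S in age.  extend = FALSE refuses ages
# outside the tabulated range; extend = TRUE continues the edge trends
# linearly (a smooth extension, used by the synthetic-truth curves so the
# truth stays smooth over the whole fitted age range).
interpolate_lms <- function(table, age, extend = FALSE) {
  rng <- range(table$age)
  if (!extend && any(age < rng[1] | age > rng[2])) {
    nearest <- table$age[pmin(pmax(findInterval(age, table$age), 1),
                              nrow(table))]
    stop(sprintf(
      "age outside the table range [%g, %g] (nearest tabulated age: %g); scoring refuses extrapolation",
      rng[1], rng[2], nearest[which(age < rng[1] | age > rng[2])[1]]),
      call. = FALSE)
  }
  interp1 <- function(v) {
    y <- stats::approx(table$age, v, age, rule = 2)$y
    if (extend) {
      k <- nrow(table)
      lo <- age < rng[1]; hi <- age > rng[2]
      s_lo <- (v[2] - v[1]) / (table$age[2] - table$age[1])
      s_hi <- (v[k] - v[k - 1]) / (table$age[k] - table$age[k - 1])
      y[lo] <- v[1] + s_lo * (age[lo] - rng[1])
      y[hi] <- v[k] + s_hi * (age[hi] - rng[2])
    }
    y
  }
  out <- data.frame(age = age, L = interp1(table$L), M = interp1(table$M),
                    S = interp1(table$S))
  if (extend && (any(out$M <= 0) || any(out$S <= 0)))
    stop("truth-curve extension produced non-positive M or S", call. = FALSE)
  out
}

#' Score a measurement against an LMS reference table
#'
#' Linearly interpolates L, M and S between the bracketing tabulated ages
#' (the standard scoring convention for published growth references), then
#' returns the LMS z-score and the corresponding centile `100 * pnorm(z)`.
#' Ages outside the tabulated range are refused (no extrapolation beyond
#' the published 5-18 y range).  Z-scores beyond +-5 are flagged in an
#' `extreme` column.
#'
#' @param value measured value(s), > 0.
#' @param age age(s) in years, within the table's range.
#' @param table an LMS table: data.frame with `age, L, M, S` (e.g. from
#'   [bc_reference()] or [read_lms_table()]).
#' @return data.frame `age, value, L, M, S, z, centile, extreme`.
#' @examples
#' zscore_against_table(6.66, 5, bc_reference("fmi", "dxa", "female"))
#' @export
zscore_against_table <- function(value, age, table) {
  stopifnot(all(c("age", "L", "M", "S") %in% names(table)))
  k <- max(length(value), length(age))
  value <- rep_len(value, k); age <- rep_len(age, k)
  par <- interpolate_lms(table, age)
  z <- as.numeric(bccg_z(value, par$L, par$M, par$S))
  data.frame(age = age, value = value, par[c("L", "M", "S")],
             z = z, centile = 100 * stats::pnorm(z), extreme = abs(z) > 5)
}

#' Check the internal consistency of a published LMS table
#'
#' Recomputes every centile cell of a table from that row's own L, M, S via
#' the LMS quantile formula and reports the signed deviations
#' (recomputed - printed).  The checker reports; it never alters the table.
#' Rows whose maximum absolute deviation stays within the printing
#' tolerance (2-decimal centiles derived from 3-decimal parameters) count
#' as internally consistent.
#'
#' @param table data.frame with `age, L, M, S` and centile columns named
#'   `p<level>`.
#' @param tol consistency tolerance for the summary, default 0.02.
#' @return data.frame of class `lms_consistency`: one row per (age, level)
#'   with `printed`, `recomputed`, `deviation`; attributes `row_max`
#'   (max |deviation| per age), `table_max`, and `consistent_ages` (ages
#'   whose whole row is within `tol`).
#' @export
check_table_consistency <- function(table, tol = 0.02) {
  pcols <- grep("^p[0-9]+$", names(table), value = TRUE)
  if (!length(pcols))
    stop("table has no centile columns (p<level>) to check", call. = FALSE)
  levels <- as.numeric(sub("^p", "", pcols))
  out <- do.call(rbind, lapply(seq_along(pcols), function(j) {
    rec <- qbccg(levels[j] / 100, table$L, table$M, table$S)
    data.frame(age = table$age, level = levels[j],
               printed = table[[pcols[j]]], recomputed = rec,
               deviation = rec - table[[pcols[j]]])
  }))
  out <- out[order(out$age, out$level), ]
  rownames(out) <- NULL
  row_max <- tapply(abs(out$deviation), out$age, max)
  structure(out,
            row_max = row_max,
            table_max = max(abs(out$deviation)),
            consistent_ages = as.numeric(names(row_max))[row_max <= tol],
            tol = tol,
            class = c("lms_consistency", "data.frame"))
}
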