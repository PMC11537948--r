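#' Run the end-to-end reference-value pipeline
#'
#' Executes derive -> eligibility filter -> anthropometric outlier filter ->
#' per sex/variable/method LMS fit -> centile tables, and assembles a run
#' manifest (input hash, configuration snapshot, per-stage record counts and
#' per-criterion exclusion tallies).  All stages are deterministic, so
#' identical inputs and configuration reproduce bit-identical tables and
#' manifest (manifest timestamps are opt-in for that reason).
#'
#' @param cohort a cohort data.frame or path to a cohort CSV
#'   (see [read_cohort()]).
#' @param variables subset of `c("fmi", "ffmi")` to model.
#' @param methods subset of `c("SF", "MFBIA", "DXA")`.
#' @param sexes subset of `c("female", "male")`.
#' @param control an [lms_control()].
#' @param table_ages,table_levels grid for the output centile tables;
#'   tabulated ages may be narrower than the fitted range (edge ages inform
#'   the smoothing but are not published).
#' @param age_range ages used in curve fitting.
#' @param bp_reference optional blood-pressure percentile plug-in,
#'   see [classify_eligibility()].
#' @param min_n minimum eligible subjects per stratum required to fit.
#' @param timestamp include a wall-clock timestamp in the manifest
#'   (default `FALSE` to keep re-runs bit-identical).
#' @param verbose log stage-level record counts and every applied threshold.
#' @return list of class `bcref_pipeline`: `curves` (named list of
#'   `lms_curve`), `tables` (named list of `centile_table`), `eligibility`,
#'   `outlier_flags`, and `manifest`.
#' @export
run_pipeline <- function(cohort,
                         variables = c("fmi", "ffmi"),
                         methods = c("SF", "MFBIA", "DXA"),
                         sexes = c("female", "male"),
                         control = lms_control(),
                         table_ages = seq(5, 18, by = 0.5),
                         table_levels = .default_levels,
                         age_range = c(4, 20.9),
                         bp_reference = NULL,
                         min_n = 50, timestamp = FALSE, verbose = FALSE) {
  input_path <- NULL
  if (is.character(cohort)) {
    input_path <- cohort
    cohort <- read_cohort(cohort)
  }
  stopifnot(is.data.frame(cohort))
  say <- function(...) if (verbose) message(sprintf(...))
  n_input <- nrow(cohort)
  say("input: %d subjects", n_input)

  elig <- suppressMessages(
    classify_eligibility(cohort, bp_reference = bp_reference))
  if (verbose)
    for (nm in names(.elig_thresholds))
      say("threshold: %s", .elig_thresholds[[nm]])
  n_incomplete <- sum(elig$incomplete_data)
  n_excluded <- sum(!elig$eligible & !elig$incomplete_data)
  say("eligibility: %d excluded (metabolic), %d incomplete",
      n_excluded, n_incomplete)

  out_flags <- if (any(elig$eligible))
    anthropometric_outlier_filter(cohort[elig$eligible, , drop = FALSE])
  else logical(0)
  keep <- cohort[elig$eligible, , drop = FALSE][!out_flags, , drop = FALSE]
  n_outliers <- sum(out_flags)
  n_eligible <- nrow(keep)
  say("outlier screen: %d flagged; %d subjects enter fitting",
      n_outliers, n_eligible)

  if (nrow(keep) == 0)
    stop("fit stage: insufficient eligible subjects (none survive screening)",
         call. = FALSE)
  bc <- derive_body_composition(keep, methods = methods)
  curves <- list()
  tables <- list()
  strata_n <- list()
  for (sx in sexes) for (vr in variables) for (mt in methods) {
    sub <- bc[bc$sex == sx & bc$method == mt, , drop = FALSE]
    key <- paste(sx, vr, mt, sep = "_")
    strata_n[[key]] <- nrow(sub)
    if (nrow(sub) < min_n)
      stop(sprintf(
        "fit stage: insufficient eligible subjects for stratum %s (%d < %d)",
        key, nrow(sub), min_n), call. = FALSE)
    say("fitting %s (n = %d)", key, nrow(sub))
    curves[[key]] <- fit_lms(sub$age, sub[[vr]], age_range = age_range,
                             control = control, sex = sx,
                             variable = toupper(vr), method = mt)
    tables[[key]] <- make_centile_table(curves[[key]], ages = table_ages,
                                        levels = table_levels)
  }

  crit <- setdiff(names(elig),
                  c("id", "eligible", "violations"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("bcref")),
    input = list(
      n = n_input,
      md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path))
            else .df_md5(cohort)),
    config = list(variables = variables, methods = methods, sexes = sexes,
                  control = unclass(control)[c("n_knots", "degree",
                    "penalty_order", "tol", "max_iter")],
                  lambda = control$lambda,
                  table_ages = range(table_ages),
                  table_step = if (length(table_ages) > 1)
                    diff(table_ages)[1] else NA_real_,
                  table_levels = table_levels,
                  age_range = age_range, min_n = min_n),
    counts = list(n_input = n_input, n_eligible = n_eligible,
                  n_excluded = n_excluded, n_outliers = n_outliers,
                  n_incomplete = n_incomplete,
                  exclusions_by_criterion = vapply(elig[crit], sum,
                                                   integer(1)),
                  strata = unlist(strata_n)),
    timestamp = if (timestamp) format(Sys.time(), tz = "UTC") else NULL)

  structure(list(curves = curves, tables = tables, eligibility = elig,
                 outlier_flags = out_flags, manifest = manifest),
            class = "bcref_pipeline")
}

# order-stable md5 of a data.frame via its CSV text
.df_md5 <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE, na = "")
  unname(tools::md5sum(tmp))
}

#' @export
print.bcref_pipeline <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Body-composition reference pipeline run\n")
  cat(sprintf("  input %d; eligible %d; excluded %d; outliers %d; incomplete %d\n",
              cnt$n_input, cnt$n_eligible, cnt$n_excluded, cnt$n_outliers,
              cnt$n_incomplete))
  cat(sprintf("  fitted strata: %s\n", paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

#' Write a pipeline run's outputs to a directory
#'
#' Tables as CSV, curves and manifest as JSON text.
#'
#' @param run a `bcref_pipeline` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(run, dir) {
  stopifnot(inherits(run, "bcref_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(run$tables))
    write_lms_table(run$tables[[key]],
                    file.path(dir, paste0("table_", key, ".csv")))
  for (key in names(run$curves))
    write_lms_curve(run$curves[[key]],
                    file.path(dir, paste0("curve_", key, ".json")))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare two centile tables on their shared age grid
#'
#' Aligns two tables on overlapping ages and reports per-age differences
#' and ratios of medians, plus differences for every shared centile column.
#'
#' @param table_a,table_b data.frames with `age`, `M` and optionally
#'   `p<level>` columns.
#' @return data.frame: `age, M_a, M_b, M_diff, M_ratio` and
#'   `d_p<level>` columns for shared levels.
#' @export
compare_curves <- function(table_a, table_b) {
  ages <- intersect(table_a$age, table_b$age)
  if (!length(ages))
    stop("age ranges are disjoint; nothing to compare", call. = FALSE)
  a <- table_a[match(ages, table_a$age), , drop = FALSE]
  b <- table_b[match(ages, table_b$age), , drop = FALSE]
  out <- data.frame(age = ages, M_a = a$M, M_b = b$M,
                    M_diff = a$M - b$M, M_ratio = a$M / b$M)
  shared <- intersect(grep("^p[0-9]+$", names(a), value = TRUE),
                      grep("^p[0-9]+$", names(b), value = TRUE))
  for (pc in shared) out[[paste0("d_", pc)]] <- a[[pc]] - b[[pc]]
  out
}
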