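#' Control parameters for LMS curve fitting
#'
#' @param n_knots number of equally spaced interior knots of the cubic
#'   B-spline basis over the age range (basis dimension `n_knots + 4`).
#' @param degree B-spline degree (3 = cubic).
#' @param penalty_order order of the difference penalty on adjacent basis
#'   coefficients (2 penalizes departure from a straight line).
#' @param lambda `NULL` to select per-curve smoothing by GCV, or a named
#'   numeric vector `c(M=, S=, L=)` of fixed smoothing parameters.
#' @param lambda_grid candidate smoothing values for GCV selection
#'   (21 log-spaced values spanning wiggly to essentially linear fits).
#' @param tol convergence tolerance: relative change in penalized deviance.
#' @param max_iter maximum outer backfitting cycles.
#' @param gcv_refit_iter outer cycles used for each short refit while
#'   profiling the GCV grid.
#' @param max_step_halvings step-halvings allowed per parameter update
#'   before the previous coefficients are kept.
#' @param verbose print per-iteration penalized deviance.
#' @return a list of class `lms_control`.
#' @export
lms_control <- function(n_knots = 20, degree = 3, penalty_order = 2,
                        lambda = NULL,
                        lambda_grid = 10^seq(-2, 6, length.out = 21),
                        tol = 1e-4, max_iter = 50, gcv_refit_iter = 10,
                        max_step_halvings = 15, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, n_knots >= 1, penalty_order >= 1,
            length(lambda_grid) >= 1)
  structure(list(n_knots = n_knots, degree = degree,
                 penalty_order = penalty_order, lambda = lambda,
                 lambda_grid = sort(lambda_grid), tol = tol,
                 max_iter = max_iter, gcv_refit_iter = gcv_refit_iter,
                 max_step_halvings = max_step_halvings, verbose = verbose),
            class = "lms_control")
}

# cubic B-spline design matrix with equally spaced interior knots
.pspline_basis <- function(x, age_range, n_knots, degree) {
  a <- age_range[1]; b <- age_range[2]
  dx <- (b - a) / (n_knots + 1)
  interior <- a + dx * seq_len(n_knots)
  list(B = splines::bs(x, knots = interior, degree = degree,
                       intercept = TRUE, Boundary.knots = age_range),
       interior = interior)
}

.diff_penalty <- function(k, order) {
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

# BCCG log-likelihood contributions for vectors L, M, S
.bccg_loglik <- function(y, L, M, S) {
  if (any(!is.finite(M)) || any(M <= 0) || any(!is.finite(S)) || any(S <= 0) ||
      any(!is.finite(L)))
    return(-Inf)
  r <- log(y) - log(M)
  z <- ifelse(abs(L) < 1e-12, r / S, expm1(L * r) / (L * S))
  ll <- L * r - log(y) - log(S) - z^2 / 2 - 0.5 * log(2 * pi)
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}

# score dl/d(eta) and expected Fisher weight per parameter curve, at the
# current (L, M, S).  Links: log for M and S, identity for L.
.bccg_score_weight <- function(param, y, L, M, S) {
  s <- log(y) - log(M)
  z <- ifelse(abs(L) < 1e-12, s / S, expm1(L * s) / (L * S))
  if (param == "M") {
    list(score = z / S + L * (z^2 - 1),
         weight = (1 + 2 * L^2 * S^2) / S^2)
  } else if (param == "S") {
    list(score = z^2 - 1, weight = rep(2, length(y)))
  } else {
    # d z / d L = (s * exp(Ls) - z * L * S) / (L * S); series for small L
    dzdL <- ifelse(abs(L) < 1e-5,
                   (s^2 / 2 + L * s^3 / 3) / S,
                   (s * exp(L * s) / (L * S)) - z / L)
    list(score = s - z * dzdL, weight = 7 * S^2 / 4)
  }
}

.pen_dev <- function(y, B, beta, lambda, P) {
  L <- as.numeric(B %*% beta$L)
  M <- exp(as.numeric(B %*% beta$M))
  S <- exp(as.numeric(B %*% beta$S))
  ll <- .bccg_loglik(y, L, M, S)
  dev <- -2 * ll
  pen <- sum(vapply(c("M", "S", "L"), function(p)
    lambda[[p]] * as.numeric(crossprod(beta[[p]], P %*% beta[[p]])),
    numeric(1)))
  list(dev = dev, pen_dev = dev + pen)
}

# one RS-type backfitting run at fixed smoothing parameters
.fit_engine <- function(y, B, P, lambda, beta, control) {
  n <- length(y)
  link <- c(M = "log", S = "log", L = "identity")
  state <- .pen_dev(y, B, beta, lambda, P)
  halving_events <- 0L
  iter <- 0L
  converged <- FALSE
  while (iter < control$max_iter) {
    iter <- iter + 1L
    pd_before <- state$pen_dev
    for (param in c("M", "S", "L")) {
      Lc <- as.numeric(B %*% beta$L)
      Mc <- exp(as.numeric(B %*% beta$M))
      Sc <- exp(as.numeric(B %*% beta$S))
      sw <- .bccg_score_weight(param, y, Lc, Mc, Sc)
      w <- pmax(sw$weight, 1e-10)
      eta <- as.numeric(B %*% beta[[param]])
      u <- eta + sw$score / w
      A <- crossprod(B, w * B) + lambda[[param]] * P
      beta_new <- tryCatch(solve(A, crossprod(B, w * u)),
                           error = function(e) NULL)
      if (is.null(beta_new)) next
      cand <- beta
      cand[[param]] <- beta_new
      st_new <- .pen_dev(y, B, cand, lambda, P)
      halve <- 0L
      while (!is.finite(st_new$pen_dev) ||
             st_new$pen_dev > state$pen_dev + 1e-10) {
        halve <- halve + 1L
        if (halve > control$max_step_halvings) break
        cand[[param]] <- (cand[[param]] + beta[[param]]) / 2
        st_new <- .pen_dev(y, B, cand, lambda, P)
      }
      if (halve > 0L) halving_events <- halving_events + 1L
      if (is.finite(st_new$pen_dev) &&
          st_new$pen_dev <= state$pen_dev + 1e-10) {
        beta <- cand
        state <- st_new
      }
    }
    if (control$verbose)
      message(sprintf("iter %d: penalized deviance %.4f", iter, state$pen_dev))
    if (abs(pd_before - state$pen_dev) <
        control$tol * (abs(pd_before) + 0.1)) {
      converged <- TRUE
      break
    }
  }
  # effective degrees of freedom per curve at the final weights
  Lc <- as.numeric(B %*% beta$L)
  Mc <- exp(as.numeric(B %*% beta$M))
  Sc <- exp(as.numeric(B %*% beta$S))
  edf <- vapply(c("M", "S", "L"), function(param) {
    w <- pmax(.bccg_score_weight(param, y, Lc, Mc, Sc)$weight, 1e-10)
    BtWB <- crossprod(B, w * B)
    sum(diag(solve(BtWB + lambda[[param]] * P, BtWB)))
  }, numeric(1))
  list(beta = beta, deviance = state$dev, pen_deviance = state$pen_dev,
       edf = edf, iterations = iter, converged = converged,
       halving_events = halving_events, n = n)
}

.init_beta <- function(y, B, P) {
  k <- ncol(B)
  ly <- log(y)
  beta_M <- solve(crossprod(B) + 100 * P, crossprod(B, ly))
  S0 <- min(max(stats::sd(ly), 0.01), 1)
  list(M = beta_M,
       S = matrix(log(S0), k, 1),
       L = matrix(0, k, 1))
}

#' Fit age-varying BCCG (LMS) parameter curves by penalized likelihood
#'
#' Fits smooth curves L(age), M(age), S(age) of a Box-Cox-Cole-Green
#' distribution to cross-sectional `(age, y)` data by maximizing the BCCG
#' log-likelihood minus second-order difference penalties on cubic B-spline
#' coefficient vectors (a P-spline GAMLSS).  The optimizer is
#' Rigby-Stasinopoulos-type backfitting: each parameter curve in turn is
#' updated by a penalized weighted least-squares step built from the score
#' and expected Fisher information of its predictor, with step-halving
#' whenever the penalized deviance would increase, iterated to convergence.
#' Links: log for M and S (positivity), identity for L.  When
#' `control$lambda` is `NULL` the per-curve smoothing parameters are chosen
#' by generalized cross-validation (see [select_smoothing_gcv()]).
#'
#' @param age ages in years.
#' @param y positive measurements (e.g. FMI in kg/m^2).
#' @param age_range ages over which the basis is placed; defaults to
#'   `range(age)`.  Evaluation outside this range is refused.
#' @param control an [lms_control()] list.
#' @param sex,variable,method optional labels stored on the result.
#' @return an object of class `lms_curve`: basis description, fitted
#'   coefficient vectors, per-curve smoothing and effective degrees of
#'   freedom, deviance, convergence state.  Evaluate with [predict()] or
#'   [evaluate_curve()].
#' @examples
#' set.seed(1)
#' age <- runif(300, 4, 20)
#' y <- rbccg(300, L = 1, M = 10, S = 0.1)
#' fit <- fit_lms(age, y, control = lms_control(lambda = c(M = 1e4, S = 1e4, L = 1e4)))
#' predict(fit, c(6, 12, 18))
#' @export
fit_lms <- function(age, y, age_range = NULL, control = lms_control(),
                    sex = NA_character_, variable = NA_character_,
                    method = NA_character_) {
  stopifnot(length(age) == length(y))
  if (any(!is.finite(y)) || any(y <= 0))
    stop("all y must be finite and > 0", call. = FALSE)
  if (length(y) < 50)
    stop("at least 50 observations are required to fit LMS curves",
         call. = FALSE)
  if (is.null(age_range)) age_range <- range(age)
  if (any(age < age_range[1] | age > age_range[2]))
    stop("ages outside the declared age_range", call. = FALSE)

  bas <- .pspline_basis(age, age_range, control$n_knots, control$degree)
  B <- bas$B
  P <- .diff_penalty(ncol(B), control$penalty_order)
  beta <- .init_beta(y, B, P)

  gcv <- NULL
  if (is.null(control$lambda)) {
    gcv <- select_smoothing_gcv(age, y, age_range = age_range,
                                control = control, .basis = bas, .P = P,
                                .beta = beta)
    lambda <- gcv$lambda
    beta <- gcv$beta
  } else {
    lambda <- control$lambda
    if (is.null(names(lambda))) names(lambda) <- c("M", "S", "L")
    stopifnot(all(c("M", "S", "L") %in% names(lambda)))
    lambda <- as.list(lambda[c("M", "S", "L")])
  }

  fit <- .fit_engine(y, B, P, lambda, beta, control)
  if (!fit$converged)
    warning(sprintf(
      "LMS fit did not converge in %d iterations (last penalized deviance %.4f)",
      control$max_iter, fit$pen_deviance), call. = FALSE)

  structure(list(
    sex = sex, variable = variable, method = method,
    age_range = age_range, degree = control$degree,
    interior_knots = bas$interior, penalty_order = control$penalty_order,
    coef = lapply(fit$beta, as.numeric),
    links = c(L = "identity", M = "log", S = "log"),
    lambda = unlist(lambda)[c("M", "S", "L")],
    edf = fit$edf, deviance = fit$deviance,
    penalized_deviance = fit$pen_deviance,
    iterations = fit$iterations, converged = fit$converged,
    halving_events = fit$halving_events, n = fit$n,
    gcv = gcv$profiles), class = "lms_curve")
}

#' Select per-curve smoothing parameters by generalized cross-validation
#'
#' Profiles each parameter curve's smoothing parameter over
#' `control$lambda_grid` in a single outer pass (M, then S, then L), holding
#' the other curves at their current smoothing, and picks the grid point
#' minimizing \eqn{GCV = n D / (n - edf)^2} where `D` is the global deviance
#' of the refitted model and `edf` the total effective degrees of freedom.
#' A minimum on the grid boundary triggers a warning (widen the grid).
#'
#' @inheritParams fit_lms
#' @param .basis,.P,.beta internal fast-path arguments used by [fit_lms()].
#' @return list with `lambda` (named list M/S/L), `profiles` (one
#'   data.frame per curve: lambda, deviance, edf_total, gcv) and the
#'   coefficient state `beta` at the selected smoothing.
#' @export
select_smoothing_gcv <- function(age, y, age_range = NULL,
                                 control = lms_control(),
                                 .basis = NULL, .P = NULL, .beta = NULL) {
  if (is.null(age_range)) age_range <- range(age)
  if (is.null(.basis))
    .basis <- .pspline_basis(age, age_range, control$n_knots, control$degree)
  B <- .basis$B
  if (is.null(.P)) .P <- .diff_penalty(ncol(B), control$penalty_order)
  if (is.null(.beta)) .beta <- .init_beta(y, B, .P)
  grid <- control$lambda_grid
  n <- length(y)
  mid <- grid[ceiling(length(grid) / 2)]
  lambda <- list(M = mid, S = mid, L = mid)

  short <- control
  short$max_iter <- control$gcv_refit_iter
  # settle at the central smoothing before profiling
  cur <- .fit_engine(y, B, .P, lambda, .beta, control)
  profiles <- list()
  for (param in c("M", "S", "L")) {
    prof <- data.frame(lambda = grid, deviance = NA_real_,
                       edf_total = NA_real_, gcv = NA_real_)
    best <- NULL
    for (i in seq_along(grid)) {
      lam <- lambda
      lam[[param]] <- grid[i]
      f <- .fit_engine(y, B, .P, lam, cur$beta, short)
      edf_tot <- sum(f$edf)
      prof$deviance[i] <- f$deviance
      prof$edf_total[i] <- edf_tot
      prof$gcv[i] <- n * f$deviance / (n - edf_tot)^2
      if (is.null(best) || prof$gcv[i] < best$gcv) {
        best <- list(gcv = prof$gcv[i], i = i, fit = f)
      }
    }
    if (best$i %in% c(1L, length(grid)))
      warning(sprintf(
        "GCV minimum for the %s curve lies on the grid boundary (lambda = %g); widen lambda_grid",
        param, grid[best$i]), call. = FALSE)
    lambda[[param]] <- grid[best$i]
    cur <- best$fit
    profiles[[param]] <- prof
  }
  list(lambda = lambda, profiles = profiles, beta = cur$beta)
}

#' Evaluate fitted LMS curves at given ages
#'
#' @param curve an `lms_curve` from [fit_lms()].
#' @param age ages in years, all within the curve's `age_range`
#'   (no extrapolation).
#' @return data.frame with columns `age`, `L`, `M`, `S`.
#' @export
evaluate_curve <- function(curve, age) {
  stopifnot(inherits(curve, "lms_curve"))
  if (any(age < curve$age_range[1] | age > curve$age_range[2]))
    stop(sprintf("age outside the fitted range [%g, %g]; extrapolation is refused",
                 curve$age_range[1], curve$age_range[2]), call. = FALSE)
  B <- splines::bs(age, knots = curve$interior_knots, degree = curve$degree,
                   intercept = TRUE, Boundary.knots = curve$age_range)
  data.frame(age = age,
             L = as.numeric(B %*% curve$coef$L),
             M = exp(as.numeric(B %*% curve$coef$M)),
             S = exp(as.numeric(B %*% curve$coef$S)))
}

#' @param object an `lms_curve`.
#' @param ... unused.
#' @rdname evaluate_curve
#' @export
predict.lms_curve <- function(object, age, ...) evaluate_curve(object, age)

#' @export
print.lms_curve <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$sex, x$variable, x$method)), collapse = " ")
  cat("Penalized BCCG (LMS) curve fit", if (nzchar(lab)) paste0("[", lab, "]"),
      "\n")
  cat(sprintf("  n = %d, ages %.1f-%.1f, basis dim %d, penalty order %d\n",
              x$n, x$age_range[1], x$age_range[2],
              length(x$coef$M), x$penalty_order))
  cat(sprintf("  lambda (M, S, L): %s\n",
              paste(signif(x$lambda, 3), collapse = ", ")))
  cat(sprintf("  edf (M, S, L): %s\n",
              paste(round(x$edf, 2), collapse = ", ")))
  cat(sprintf("  deviance %.2f (penalized %.2f), %d iterations, %s\n",
              x$deviance, x$penalized_deviance, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Serialize fitted LMS curves to/from JSON text
#'
#' The on-disk schema records the labels, age range, basis (degree and
#' interior knots), links, penalty order, smoothing, coefficient vectors,
#' edf and deviance, so that a curve can be re-evaluated without refitting.
#'
#' @param curve an `lms_curve`.
#' @param path file path.
#' @return `read_lms_curve()` an `lms_curve`; `write_lms_curve()` the path,
#'   invisibly.
#' @export
write_lms_curve <- function(curve, path) {
  stopifnot(inherits(curve, "lms_curve"))
  out <- unclass(curve)
  out$gcv <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_lms_curve
#' @export
read_lms_curve <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coef <- lapply(x$coef, as.numeric)
  x$age_range <- as.numeric(x$age_range)
  x$lambda <- stats::setNames(as.numeric(unlist(x$lambda)), c("M", "S", "L"))
  x$edf <- stats::setNames(as.numeric(unlist(x$edf)), c("M", "S", "L"))
  structure(x, class = "lms_curve")
}
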