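sim_constant <- function(n, L, M, S, seed = 1) {
  set.seed(seed)
  list(age = runif(n, 4, 20.9), y = rbccg(n, L, M, S))
}

test_that("penalty-dominated fits collapse to constants under an order-1 penalty", {
  d <- sim_constant(800, 1, 10, 0.1)
  fit <- fit_lms(d$age, d$y, age_range = c(4, 20.9),
                 control = lms_control(penalty_order = 1,
                                       lambda = c(M = 1e8, S = 1e8, L = 1e8)))
  est <- evaluate_curve(fit, seq(4, 20.9, by = 0.5))
  expect_lt(diff(range(est$M)) / mean(est$M), 1e-3)
  expect_lt(diff(range(est$S)) / mean(est$S), 1e-3)
  expect_lt(diff(range(est$L)), 1e-3)
  expect_true(fit$converged)
})

test_that("constant fits agree with the log-normal closed form when data are log-normal", {
  set.seed(3)
  n <- 3000
  age <- runif(n, 4, 20.9)
  y <- exp(rnorm(n, log(8), 0.25))   # truth: L = 0, M = 8, S = 0.25
  fit <- fit_lms(age, y, age_range = c(4, 20.9),
                 control = lms_control(penalty_order = 1,
                                       lambda = c(M = 1e8, S = 1e8, L = 1e8)))
  est <- evaluate_curve(fit, 12)
  # log-normal ML closed form
  expect_equal(est$M, exp(mean(log(y))), tolerance = 0.005)
  expect_equal(est$S, sd(log(y)), tolerance = 0.05)
  expect_equal(est$L, 0, tolerance = 0.15)
})

test_that("the constant-model fit matches direct maximum likelihood", {
  set.seed(7)
  y <- rbccg(3000, -0.35, 5.78, 0.355)
  nll <- function(p) tryCatch(
    -sum(dbccg(y, p[1], exp(p[2]), exp(p[3]), log = TRUE)),
    error = function(e) 1e10)
  o <- optim(c(0, log(median(y)), log(sd(log(y)))), nll,
             control = list(maxit = 5000, reltol = 1e-12))
  age <- runif(3000, 4, 20.9)
  fit <- fit_lms(age, y, age_range = c(4, 20.9),
                 control = lms_control(penalty_order = 1,
                                       lambda = c(M = 1e8, S = 1e8, L = 1e8),
                                       max_iter = 200))
  expect_equal(fit$deviance, 2 * o$value, tolerance = 1e-4)
})

test_that("penalized deviance does not increase with more iterations", {
  d <- sim_constant(500, -0.5, 6, 0.3, seed = 11)
  ctrl <- lms_control(lambda = c(M = 100, S = 100, L = 100), tol = 1e-12)
  pd <- sapply(c(1, 3, 10, 40), function(k) {
    ctrl$max_iter <- k
    suppressWarnings(fit_lms(d$age, d$y, age_range = c(4, 20.9),
                             control = ctrl))$penalized_deviance
  })
  expect_true(all(diff(pd) <= 1e-8))
})

test_that("fitted M stays inside the observed data envelope", {
  d <- sim_constant(600, -0.3, 5, 0.3, seed = 13)
  fit <- fit_lms(d$age, d$y, age_range = c(4, 20.9),
                 control = lms_control(lambda = c(M = 1e3, S = 1e3, L = 1e3)))
  est <- evaluate_curve(fit, d$age)
  expect_true(all(est$M > min(d$y) & est$M < max(d$y)))
})

test_that("input contracts are enforced", {
  d <- sim_constant(100, 1, 10, 0.1)
  expect_error(fit_lms(d$age, -d$y), "> 0")
  expect_error(fit_lms(d$age[1:30], d$y[1:30]), "at least 50")
  expect_error(fit_lms(d$age, d$y, age_range = c(5, 18)), "age_range")
})

test_that("curve evaluation is deterministic, continuous and range-guarded", {
  d <- sim_constant(400, 0.5, 9, 0.15, seed = 2)
  fit <- fit_lms(d$age, d$y, age_range = c(4, 20.9),
                 control = lms_control(lambda = c(M = 10, S = 10, L = 10)))
  knot <- fit$interior_knots[7]
  eps <- 1e-9
  left <- evaluate_curve(fit, knot - eps)
  right <- evaluate_curve(fit, knot + eps)
  expect_equal(left$M, right$M, tolerance = 1e-6)
  expect_equal(left$L, right$L, tolerance = 1e-6)
  expect_identical(evaluate_curve(fit, 10), predict(fit, 10))
  expect_error(evaluate_curve(fit, 21.5), "extrapolation")
  expect_error(evaluate_curve(fit, 3.9), "extrapolation")
})

test_that("GCV selects heavy smoothing for constant truth, lighter for curved M", {
  d <- sim_constant(1200, 0.5, 10, 0.12, seed = 4)
  ctrl <- lms_control()
  sel_const <- suppressWarnings(
    select_smoothing_gcv(d$age, d$y, age_range = c(4, 20.9), control = ctrl))
  # near-maximal penalty: essentially linear fits
  fit_const <- fit_lms(d$age, d$y, age_range = c(4, 20.9),
                       control = lms_control(lambda = unlist(sel_const$lambda)))
  expect_lt(fit_const$edf["M"], 4)

  set.seed(4)
  age <- runif(1200, 4, 20.9)
  M_true <- 10 + 3 * sin((age - 4) / 16.9 * 2 * pi)
  y <- rbccg(1200, 0.5, M_true, 0.12)
  sel_curv <- suppressWarnings(
    select_smoothing_gcv(age, y, age_range = c(4, 20.9), control = ctrl))
  fit_curv <- fit_lms(age, y, age_range = c(4, 20.9),
                      control = lms_control(lambda = unlist(sel_curv$lambda)))
  expect_gt(fit_curv$edf["M"], fit_const$edf["M"])
  expect_lte(sel_curv$lambda$M, sel_const$lambda$M)
})

test_that("edf is non-increasing in the smoothing parameter", {
  d <- sim_constant(700, -0.2, 6, 0.25, seed = 8)
  edfs <- sapply(c(1, 100, 1e4, 1e6), function(lam) {
    fit_lms(d$age, d$y, age_range = c(4, 20.9),
            control = lms_control(lambda = c(M = lam, S = lam, L = lam)))$edf
  })
  for (k in 1:3) expect_true(all(diff(edfs[k, ]) <= 1e-6))
})

test_that("fitted curves serialize to JSON and back without loss", {
  d <- sim_constant(300, 0.3, 7, 0.2, seed = 6)
  fit <- fit_lms(d$age, d$y, age_range = c(4, 20.9), sex = "female",
                 variable = "FMI", method = "DXA",
                 control = lms_control(lambda = c(M = 50, S = 50, L = 50)))
  path <- withr::local_tempfile(fileext = ".json")
  write_lms_curve(fit, path)
  back <- read_lms_curve(path)
  ages <- seq(5, 18, by = 0.5)
  expect_equal(evaluate_curve(back, ages), evaluate_curve(fit, ages))
  expect_equal(back$edf, fit$edf)
  expect_equal(back$sex, "female")
})
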