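test_that("HOMA-IR follows the Matthews formulation", {
  expect_equal(homa_ir(90, 18), 4)      # hand evaluation: 90*18/405
  expect_equal(homa_ir(405, 1), 1)      # normalizing case
  expect_error(homa_ir(81, 0), "> 0")
  expect_error(homa_ir(0, 10), "> 0")
})

test_that("eligibility thresholds use the stated boundary semantics", {
  ok <- suppressMessages(classify_eligibility(healthy_subject()))
  expect_true(ok$eligible)
  expect_equal(ok$violations, "")

  # glucose >= 100 is exclusionary at the boundary
  r <- suppressMessages(classify_eligibility(healthy_subject(glucose = 100)))
  expect_false(r$eligible)
  expect_equal(r$violations, "glucose")
  expect_true(suppressMessages(
    classify_eligibility(healthy_subject(glucose = 99.9)))$eligible)

  # triglycerides: >= 100 under 10 y, >= 130 at 10-19 y
  r <- suppressMessages(
    classify_eligibility(healthy_subject(age = 9, triglycerides = 100)))
  expect_false(r$eligible)
  expect_equal(r$violations, "triglycerides")
  expect_true(suppressMessages(
    classify_eligibility(healthy_subject(age = 12, triglycerides = 129)))$eligible)
  expect_false(suppressMessages(
    classify_eligibility(healthy_subject(age = 12, triglycerides = 130)))$eligible)

  # HDL < 40, or < 45 for post-pubertal girls (Tanner >= 4)
  expect_true(suppressMessages(
    classify_eligibility(healthy_subject(hdl = 42)))$eligible)
  expect_false(suppressMessages(classify_eligibility(
    healthy_subject(sex = "female", tanner = 4, hdl = 42)))$eligible)
  expect_true(suppressMessages(classify_eligibility(
    healthy_subject(sex = "female", tanner = 3, hdl = 42)))$eligible)

  # HOMA-IR strictly > 3.5; cholesterol >= 200; |BMI z| >= 3
  expect_true(suppressMessages(classify_eligibility(
    healthy_subject(glucose = 90, insulin = 3.5 * 405 / 90)))$eligible)
  expect_false(suppressMessages(classify_eligibility(
    healthy_subject(insulin = 20)))$eligible)
  expect_false(suppressMessages(classify_eligibility(
    healthy_subject(total_chol = 200)))$eligible)
  expect_false(suppressMessages(classify_eligibility(
    healthy_subject(bmi_z = -3)))$eligible)
  expect_false(suppressMessages(classify_eligibility(
    healthy_subject(bmi_z = 3)))$eligible)
  expect_true(suppressMessages(classify_eligibility(
    healthy_subject(bmi_z = 2.99)))$eligible)
})

test_that("missing data is a violation, not an exception", {
  r <- suppressMessages(classify_eligibility(healthy_subject(insulin = NA)))
  expect_false(r$eligible)
  expect_equal(r$violations, "incomplete_data")
})

test_that("raising glucose of an eligible subject never removes a violation", {
  set.seed(5)
  for (g in c(80, 95, 100, 120)) {
    lo <- suppressMessages(classify_eligibility(healthy_subject(glucose = g)))
    hi <- suppressMessages(classify_eligibility(healthy_subject(glucose = g + 10)))
    crit <- c("glucose", "total_chol", "hdl", "triglycerides", "homa_ir", "bmi_z")
    expect_true(all(unlist(hi[crit]) >= unlist(lo[crit])))
  }
})

test_that("blood-pressure rule fires only with an injected percentile reference", {
  rec <- healthy_subject(sbp = 130, dbp = 85)
  expect_message(r0 <- classify_eligibility(rec), "skipped")
  expect_true(r0$eligible)
  bp90 <- function(age, sex, height) data.frame(sbp = 115, dbp = 75)
  r1 <- classify_eligibility(rec, bp_reference = bp90)
  expect_false(r1$eligible)
  expect_equal(r1$violations, "blood_pressure")
  r2 <- classify_eligibility(healthy_subject(), bp_reference = bp90)
  expect_true(r2$eligible)
})

test_that("BMI-z rule is tallied under both boundary readings", {
  rec <- rbind(healthy_subject(id = "a", bmi_z = 3),
               healthy_subject(id = "b", bmi_z = 3.2),
               healthy_subject(id = "c", bmi_z = -0.5))
  r <- suppressMessages(classify_eligibility(rec))
  cnt <- attr(r, "bmi_z_counts")
  expect_equal(unname(cnt["at_or_beyond_3"]), 2L)
  expect_equal(unname(cnt["beyond_3"]), 1L)
})

test_that("outlier screen flags gross outliers, spares homogeneous bands", {
  rec <- healthy_cohort(20)
  rec$weight <- 40 + seq(-1, 1, length.out = 20)
  expect_equal(sum(anthropometric_outlier_filter(rec)), 0)
  rec$weight[7] <- rec$weight[7] * 10
  expect_equal(which(anthropometric_outlier_filter(rec)), 7L)
  # exactly identical subjects: zero MAD, no flags
  rec2 <- healthy_cohort(10)
  expect_equal(sum(anthropometric_outlier_filter(rec2)), 0)
})

test_that("outlier screen is order-independent and skips small bands", {
  set.seed(9)
  rec <- healthy_cohort(30)
  rec$weight <- 40 * exp(rnorm(30, 0, 0.08))
  rec$weight[4] <- 150
  f1 <- anthropometric_outlier_filter(rec)
  perm <- sample(30)
  f2 <- anthropometric_outlier_filter(rec[perm, ])
  expect_equal(f2, f1[perm])
  expect_warning(anthropometric_outlier_filter(healthy_cohort(5)), "< 8")
})

test_that("planted log-scale outliers are recovered exactly", {
  set.seed(31)
  n <- 60
  rec <- healthy_cohort(n)
  w <- 40 * exp(rnorm(n, 0, 0.1))
  rec$weight <- w
  planted <- c(11, 48)
  med <- median(w)
  madl <- mad(log(w))
  rec$weight[planted] <- exp(log(med) + 5 * madl)  # 5 robust SDs out
  flags <- anthropometric_outlier_filter(rec)
  expect_setequal(which(flags), planted)
})
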