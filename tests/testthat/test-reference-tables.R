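test_that("packaged reference tables load with the documented shape", {
  tab <- bc_reference("fmi", "dxa", "female")
  expect_equal(nrow(tab), 27)
  expect_equal(range(tab$age), c(5, 18))
  expect_equal(tab$age, seq(5, 18, by = 0.5))
  expect_true(all(c("age", "L", "M", "S", "p1", "p50", "p99") %in% names(tab)))
  expect_equal(tab$M, tab$p50)
  # the published FFMI blocks omit the age-16.5 row
  expect_equal(nrow(bc_reference("ffmi", "sf", "male")), 26)
  # age-5 female DXA FMI row carries the printed parameters
  r5 <- tab[tab$age == 5, ]
  expect_equal(c(r5$L, r5$M, r5$S), c(-1.106, 4.07, 0.202))
  expect_equal(r5$p97, 6.66)
})

test_that("LMS table reader validates format and normalizes unicode minus", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,L,M,S", "5,−0.5,4.1,0.2", "6,−0.4,4.5,0.21"), path)
  tab <- read_lms_table(path)
  expect_equal(tab$L, c(-0.5, -0.4))

  writeLines(c("age,L,M", "5,1,4"), path)
  expect_error(read_lms_table(path), "S")
  writeLines(c("age,L,M,S", "6,1,4,0.2", "5,1,4,0.2"), path)
  expect_error(read_lms_table(path), "strictly increasing")
})

test_that("write/read of a table is lossless at printed precision", {
  tab <- bc_reference("ffmi", "mfbia", "male")
  path <- withr::local_tempfile(fileext = ".csv")
  write_lms_table(tab, path)
  back <- read_lms_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab)[names(back)])
})

test_that("centile tables follow the LMS quantile formula", {
  const <- data.frame(age = c(4, 21), L = 1, M = 10, S = 0.1)
  ct <- make_centile_table(const, ages = seq(5, 18, 0.5))
  expect_equal(unique(round(ct$p97, 2)), 11.88)  # 10*(1 + 0.1*qnorm(.97))
  expect_equal(ct$p50, ct$M)
  # strictly increasing across levels in every row
  pcols <- grep("^p", names(ct), value = TRUE)
  for (i in seq_len(nrow(ct)))
    expect_true(all(diff(unlist(ct[i, pcols])) > 0))
  # 0.25-y step option
  ct25 <- make_centile_table(const, ages = seq(5, 18, 0.25))
  expect_equal(nrow(ct25), 53)

  # a curve interpolating the printed age-5 female DXA FMI row
  tab <- bc_reference("fmi", "dxa", "female")
  ct5 <- make_centile_table(tab, ages = 5)
  expect_equal(ct5$p97, 6.66, tolerance = 0.01)
  expect_error(make_centile_table(tab, ages = c(4.5, 5)), "table range")
})

test_that("scoring interpolates L/M/S linearly and refuses extrapolation", {
  tab <- bc_reference("fmi", "dxa", "female")
  r5 <- tab[tab$age == 5, ]
  # value = tabulated M at a tabulated age
  expect_equal(zscore_against_table(r5$M, 5, tab)$z, 0)
  # interpolated parameters at tabulated ages equal the tabulated values
  ip <- bcref:::interpolate_lms(tab, tab$age)
  expect_equal(ip$L, tab$L)
  expect_equal(ip$M, tab$M)
  expect_equal(ip$S, tab$S)
  # value = interpolated M at a mid-step age
  m525 <- approx(tab$age, tab$M, 5.25)$y
  expect_equal(zscore_against_table(m525, 5.25, tab)$z, 0, tolerance = 1e-12)
  # tabulated 97th centile scores back at z ~ 1.88, centile ~ 97
  sc <- zscore_against_table(6.66, 5, tab)
  expect_equal(sc$z, 1.88, tolerance = 0.01)
  expect_equal(sc$centile, 97, tolerance = 0.1)
  expect_false(sc$extreme)
  # round-trip at a tabulated row to 1e-9
  y <- bccg_value(1.3, r5$L, r5$M, r5$S)
  expect_equal(zscore_against_table(y, 5, tab)$z, 1.3, tolerance = 1e-9)
  expect_error(zscore_against_table(5, 4.5, tab), "nearest tabulated age")
  expect_error(zscore_against_table(5, 18.5, tab), "refuses extrapolation")
})

test_that("consistency checker quantifies printed-vs-recomputed deviations", {
  tab <- bc_reference("fmi", "dxa", "female")
  chk <- check_table_consistency(tab)
  # the age-5 row is fully consistent to +-0.02
  expect_lt(max(abs(chk$deviation[chk$age == 5])), 0.02)
  expect_true(5 %in% attr(chk, "consistent_ages"))
  # a deliberately corrupted cell is flagged with its own deviation
  bad <- tab
  bad$p75[3] <- bad$p75[3] + 0.5
  chk2 <- check_table_consistency(bad)
  d <- chk2$deviation[chk2$age == bad$age[3] & chk2$level == 75]
  expect_equal(d, chk$deviation[chk$age == bad$age[3] & chk$level == 75] - 0.5)
  expect_gt(attr(chk2, "table_max"), 0.4)
  # female SF FMI rows at ages 5 and 10 recompute within +-0.02
  sf <- check_table_consistency(bc_reference("fmi", "sf", "female"))
  rm <- attr(sf, "row_max")
  expect_lt(rm[["5"]], 0.02)
  expect_lt(rm[["10"]], 0.02)
  expect_error(check_table_consistency(tab[, c("age", "L", "M", "S")]),
               "centile columns")
})
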