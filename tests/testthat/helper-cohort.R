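# a minimal healthy subject row; override fields per test
healthy_subject <- function(...) {
  base <- list(
    id = "S1", sex = "male", age = 12, weight = 40, height = 150,
    triceps_sf = 10, calf_sf = 10, thigh_sf = 12,
    bia1_fm = 8, bia1_ffm = 32, bia2_fm = 8.2, bia2_ffm = 31.8,
    bia3_fm = NA_real_, bia3_ffm = NA_real_,
    dxa_fm = 8.1, dxa_lm = 30.2, dxa_bmc = 1.6,
    glucose = 85, total_chol = 150, hdl = 55, ldl = 90,
    triglycerides = 70, insulin = 8, sbp = 100, dbp = 60,
    tanner = 3, bmi_z = 0.2)
  mods <- list(...)
  base[names(mods)] <- mods
  as.data.frame(base, stringsAsFactors = FALSE)
}

healthy_cohort <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) healthy_subject(id = paste0("S", i), ...)))
}
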