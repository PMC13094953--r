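test_that("identical seeds give bit-identical cohorts", {
  cfg <- synth_config(n_patients = 2, duration_hours = c(12, 24), seed = 1)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$device, b$device)
  expect_identical(a$nurse, b$nurse)
  expect_identical(a$truth$artifacts, b$truth$artifacts)
  expect_identical(a$truth$missing_mask, b$truth$missing_mask)
})

test_that("zero slot loss yields a record for every expected slot", {
  cfg <- synth_config(n_patients = 3, duration_hours = c(12, 24),
                      slot_loss_fraction = 0, seed = 3)
  co <- generate_cohort(cfg)
  comp <- completeness(co$device, co$episodes)
  expect_equal(comp$obtained_slots, comp$expected_slots)
  expect_equal(comp$missing_slots, 0L)
})

test_that("zero artifact rates yield an empty ground-truth artifact set", {
  cfg <- synth_config(n_patients = 3, duration_hours = c(12, 24),
                      artifact_rates = c(PR = 0, MBP = 0, RR = 0, SPO2 = 0, TEMP = 0),
                      seed = 4)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth$artifacts), 0L)
})

test_that("inject_artifact constructs rule violations as specified", {
  # deviation spike: value beyond 150% of prior, follow-up left near prior
  res <- inject_artifact(c(80, 80, 80), "deviation_spike", 2, "PR")
  expect_gt(res$value, 120)
  expect_equal(res$values[3], 80)
  # range artifact on PR exceeds the 250 bpm upper limit
  expect_equal(inject_artifact(c(80, 82, 81), "range", 2, "PR")$value, 300)
  # SpO2 step: drop of at least 8 points from the prior reading
  res <- inject_artifact(c(96, 96, 96), "spo2_step", 2, "SPO2")
  expect_lte(res$value, 88)
  expect_gte(res$value, 0)
  # boundary positions have no prior or no follow-up
  expect_error(inject_artifact(c(96, 96), "spo2_step", 1, "SPO2"), "prior")
  expect_error(inject_artifact(c(96, 96), "spo2_step", 2, "SPO2"), "prior")
})

test_that("an episode longer than the shortest monitoring window is rejected", {
  spec <- default_episode_spec()
  spec$duration_minutes[1] <- 13 * 60
  expect_error(synth_config(duration_hours = c(12, 118), episode_spec = spec),
               "infeasible")
})

test_that("realized loss and SpO2 dropout converge to the configured fractions", {
  co <- default_cohort() # 40 patients, 48-72 h, defaults
  cfg <- co$config
  mm <- co$truth$missing_mask
  per_patient <- tapply(!mm$obtained, mm$patient_id, mean)
  se <- sd(per_patient) / sqrt(length(per_patient))
  expect_lt(abs(mean(per_patient) - cfg$slot_loss_fraction), 3 * se)

  drop <- is.na(co$device$SPO2)
  p <- cfg$dropout_fractions[["SPO2"]]
  se_d <- sqrt(p * (1 - p) / length(drop))
  expect_lt(abs(mean(drop) - p), 3 * se_d)
})

test_that("artifact-free sample medians sit at the configured baselines", {
  co <- default_cohort()
  flagged <- co$truth$artifacts
  dev <- co$device
  for (p in core_parameters()) {
    keep <- !paste(dev$patient_id, format(dev$timestamp)) %in%
      paste(flagged$patient_id[flagged$parameter == p],
            format(flagged$timestamp[flagged$parameter == p]))
    med <- median(dev[[p]][keep], na.rm = TRUE)
    base <- co$config$baselines[[p]]
    tol <- max(0.02 * abs(base), 2 * co$config$between_sd[[p]] / sqrt(40))
    expect_lt(abs(med - base), tol + 0.5)
  }
})

test_that("every injected artifact violates its rule on QC replay", {
  cfg <- synth_config(
    n_patients = 10, duration_hours = c(24, 48), seed = 77,
    artifact_rates = c(PR = 5e-3, MBP = 5e-3, RR = 5e-3, SPO2 = 5e-3, TEMP = 5e-3)
  )
  co <- generate_cohort(cfg)
  qc <- apply_qc(co$device)
  truth <- co$truth$artifacts
  expect_gt(nrow(truth), 20)
  flag_key <- paste(qc$flags$patient_id, format(qc$flags$timestamp), qc$flags$parameter)
  truth_key <- paste(truth$patient_id, format(truth$timestamp), truth$parameter)
  expect_true(all(truth_key %in% flag_key))
})

test_that("nurse schedule: at most 3 visits/day, inside the episode, adjusted", {
  co <- default_cohort()
  nurse <- co$nurse
  expect_true(all(nurse$temp_adjusted))
  per_day <- dplyr::count(nurse, patient_id,
                          day = as.Date(timestamp, tz = "UTC"))
  expect_lte(max(per_day$n), 3L)
  joined <- dplyr::left_join(nurse, co$episodes, by = "patient_id")
  expect_true(all(joined$timestamp >= joined$ward_admission &
                    joined$timestamp <= joined$sensor_removal))
})

test_that("nurse biases point the documented directions (RR up, TEMP down)", {
  co <- default_cohort()
  qc <- apply_qc(co$device)
  pr <- match_pairs(co$nurse, qc$clean)
  ag <- agreement_summaries(pr)
  expect_lt(ag$bias[ag$parameter == "RR"], -1)   # device reads below nurse
  expect_gt(ag$bias[ag$parameter == "TEMP"], 0.1) # device reads above nurse
})

test_that("a written cohort directory round-trips through the readers", {
  cfg <- synth_config(n_patients = 2, duration_hours = c(12, 18), seed = 5)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  dev <- read_device_table(file.path(dir, "device.csv"))
  expect_equal(nrow(dev), nrow(co$device))
  expect_equal(dev$MBP, co$device$MBP)
  nur <- read_nurse_table(file.path(dir, "nurse.csv"))
  expect_true(all(nur$temp_adjusted))
  eps <- read_episode_table(file.path(dir, "episodes.csv"))
  expect_equal(eps$patient_id, co$episodes$patient_id)
})
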