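t0 <- as.POSIXct("2021-03-01 10:00:00", tz = "UTC")

test_that("nearest device record within the window is selected", {
  dev <- make_device("P1", t0 + c(0, 300), MBP = c(90, 92))
  nurse <- make_nurse("P1", t0 + 180, MBP = 88) # 10:03
  res <- match_pairs(nurse, dev)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$device_time, t0 + 300) # 10:05, 2 min < 3 min
  expect_equal(res$pairs$delta_seconds, 120)
  expect_equal(res$pairs$diff, 4)
})

test_that("comparisons farther than the window are not formed", {
  dev <- make_device("P1", t0 + 540, MBP = 90) # 10:09
  nurse <- make_nurse("P1", t0 + 180, MBP = 88) # 10:03, nearest 6 min away
  res <- match_pairs(nurse, dev)
  expect_equal(nrow(res$pairs), 0L)
  expect_equal(res$exclusions$reason, "no_device_in_window")
})

test_that("parameters pair independently; absences are logged per parameter", {
  dev <- make_device("P1", t0, MBP = 90, SPO2 = NA_real_)
  nurse <- make_nurse("P1", t0 + 60, MBP = 88, SPO2 = 97)
  res <- match_pairs(nurse, dev)
  expect_equal(res$pairs$parameter, "MBP")
  expect_equal(res$exclusions$parameter, "SPO2")
  expect_equal(res$exclusions$reason, "parameter_absent")
})

test_that("a flagged-and-removed device value is reported as such", {
  dev <- make_device("P1", t0 + c(0, 300, 600), PR = c(80, 300, 82))
  nurse <- make_nurse("P1", t0 + 300, PR = 85)
  qc <- apply_qc(dev)
  res <- match_pairs(nurse, qc$clean, flags = qc$flags)
  # nearest record was flagged; the neighbors are still in the window
  expect_equal(nrow(res$pairs), 1L)
  res2 <- match_pairs(make_nurse("P1", t0 + 300, PR = 85),
                      qc$clean[2, ], flags = qc$flags)
  expect_equal(res2$exclusions$reason, "value_flagged")
})

test_that("distance ties break toward the earlier device record", {
  dev <- make_device("P1", t0 + c(0, 300), MBP = c(90, 92))
  nurse <- make_nurse("P1", t0 + 150, MBP = 88) # equidistant
  res <- match_pairs(nurse, dev)
  expect_equal(res$pairs$device_time, t0)
})

test_that("unadjusted nurse temperatures are refused", {
  dev <- make_device("P1", t0, TEMP = 37.5)
  nurse <- make_nurse("P1", t0, TEMP = 36.8, temp_adjusted = FALSE)
  expect_error(match_pairs(nurse, dev), "adjust")
})

test_that("pair tallies count per parameter, zeros included", {
  expect_equal(unname(pair_counts(tibble::tibble(parameter = character()))),
               rep(0L, 5))
  pairs <- tibble::tibble(parameter = c("MBP", "MBP", "MBP", "RR"))
  pc <- pair_counts(pairs)
  expect_equal(pc[["MBP"]], 3L)
  expect_equal(pc[["RR"]], 1L)
  expect_equal(pc[["SPO2"]], 0L)
})

test_that("with zero loss every nurse observation pairs on every parameter", {
  cfg <- synth_config(
    n_patients = 4, duration_hours = c(24, 36), seed = 12,
    slot_loss_fraction = 0,
    dropout_fractions = c(PR = 0, MBP = 0, RR = 0, SPO2 = 0, TEMP = 0),
    artifact_rates = c(PR = 0, MBP = 0, RR = 0, SPO2 = 0, TEMP = 0)
  )
  co <- generate_cohort(cfg)
  res <- match_pairs(co$nurse, co$device)
  expect_equal(nrow(res$exclusions), 0L)
  expect_equal(unname(pair_counts(res))[1:5], rep(nrow(co$nurse), 5))
  # on a 5-minute grid the nearest record is at most half a slot away
  expect_lte(max(res$pairs$delta_seconds), 150)
})

test_that("pair deltas never exceed the window on lossy cohorts", {
  co <- default_cohort()
  qc <- apply_qc(co$device)
  res <- match_pairs(co$nurse, qc$clean, pairing_config(window_minutes = 5))
  expect_lte(max(res$pairs$delta_seconds), 300)
})

test_that("device records are not reused across well-separated observations", {
  co <- default_cohort()
  qc <- apply_qc(co$device)
  res <- match_pairs(co$nurse, qc$clean)
  p <- res$pairs
  expect_gt(nrow(p), 0)
  for (param in unique(p$parameter)) {
    sub <- p[p$parameter == param, ]
    sub <- dplyr::arrange(sub, patient_id, nurse_time)
    dup <- dplyr::group_by(sub, patient_id, device_time)
    dup <- dplyr::filter(dup, dplyr::n() > 1)
    if (nrow(dup)) {
      gaps <- tapply(as.numeric(dup$nurse_time), paste(dup$patient_id, dup$device_time),
                     function(x) max(x) - min(x))
      expect_lte(max(gaps), 2 * 300)
    }
  }
})
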