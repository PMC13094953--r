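t0 <- as.POSIXct("2021-03-01 10:00:00", tz = "UTC")

test_that("range rule flags strictly outside the limits; boundaries pass", {
  expect_equal(flag_range(c(80, 300, 82), "PR"), c(FALSE, TRUE, FALSE))
  expect_equal(flag_range(c(20, 300), "SBP"), c(FALSE, FALSE)) # boundary values
  expect_equal(flag_range(c(19.9, 300.1), "SBP"), c(TRUE, TRUE))
  expect_false(any(flag_range(c(60, 90, 120), "MBP")))
})

test_that("deviation rule: confirmation semantics on the worked sequences", {
  # 62.5% jump confirmed by the next value -> genuine
  expect_equal(flag_deviation(c(80, 130, 128)), c(FALSE, FALSE, FALSE))
  # same jump, next value back near baseline -> spike flagged
  expect_equal(flag_deviation(c(80, 130, 82)), c(FALSE, TRUE, FALSE))
  # candidate at end of series cannot be confirmed -> flagged
  expect_equal(flag_deviation(c(80, 130)), c(FALSE, TRUE))
  # flagged values do not serve as the prior: no cascade after the spike
  expect_equal(flag_deviation(c(80, 130, 82, 81)), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("deviation rule: recovery semantics flags sustained changes instead", {
  rules <- qc_rules(deviation_semantics = "recovery")
  # next value returns to baseline -> genuine under the literal reading
  expect_equal(flag_deviation(c(80, 130, 82), rules), c(FALSE, FALSE, FALSE))
  # sustained jump -> flagged, and the new level keeps being flagged against
  # the unchanged prior: the literal rule discards genuine deteriorations,
  # which is why confirmation semantics is the default
  expect_equal(flag_deviation(c(80, 130, 128), rules), c(FALSE, TRUE, TRUE))
})

test_that("deviation rule is scale-invariant", {
  withr::local_seed(101)
  for (rep in 1:50) {
    v <- round(random_series("MBP", sample(5:20, 1)), 1)
    v <- pmax(v, 1)
    k <- runif(1, 0.01, 50)
    expect_identical(flag_deviation(v), flag_deviation(k * v))
  }
})

test_that("SpO2 step rule on the worked sequences", {
  expect_equal(flag_spo2_step(c(96, 87, 96)), c(FALSE, TRUE, FALSE))
  expect_equal(flag_spo2_step(c(96, 88, 89)), c(FALSE, FALSE, FALSE))
  expect_equal(flag_spo2_step(c(96, 95, 94)), c(FALSE, FALSE, FALSE))
  # unconfirmed at the end of the series
  expect_equal(flag_spo2_step(c(96, 87)), c(FALSE, TRUE))
})

test_that("production QC agrees with the naive nested-loop reference", {
  withr::local_seed(202)
  params <- c("PR", "MBP", "RR", "SPO2", "TEMP")
  for (rep in 1:200) {
    p <- sample(params, 1)
    v <- random_series(p, sample(4:20, 1))
    expect_identical(production_flags(v, p), naive_flags(v, p),
                     label = paste("series", rep, p, paste(v, collapse = ",")))
  }
})

test_that("apply_qc removes a double-flagged value once, tallies it twice", {
  tb <- make_device("P1", t0 + (0:3) * 300, SPO2 = c(50, 20, 50, 51))
  qc <- apply_qc(tb)
  # the 20 is both a >50% deviation and an unconfirmed >=8-point step
  expect_equal(sort(qc$flags$rule), c("deviation", "spo2_step"))
  s <- qc$summary[qc$summary$parameter == "SPO2", ]
  expect_equal(s$n_deviation, 1L)
  expect_equal(s$n_spo2_step, 1L)
  expect_equal(s$n_flagged_values, 1L)
  expect_equal(qc$clean$SPO2, c(50, NA, 50, 51))
})

test_that("apply_qc neither invents nor duplicates records", {
  co <- generate_cohort(synth_config(n_patients = 4, duration_hours = c(12, 24), seed = 8))
  qc <- apply_qc(co$device)
  expect_equal(dim(qc$clean), dim(co$device))
  expect_identical(qc$clean$timestamp, dplyr::arrange(co$device, patient_id, timestamp)$timestamp)
  # flags point at obtained records
  key_dev <- paste(co$device$patient_id, format(co$device$timestamp))
  expect_true(all(paste(qc$flags$patient_id, format(qc$flags$timestamp)) %in% key_dev))
})

test_that("range-flagged values never serve as the prior reading", {
  # 300 is removed by the range rule; 82 is then compared against 80, not 300
  tb <- make_device("P1", t0 + (0:2) * 300, PR = c(80, 300, 82))
  qc <- apply_qc(tb)
  expect_equal(qc$flags$rule, "range")
  expect_equal(qc$clean$PR, c(80, NA, 82))
})

test_that("completeness arithmetic on a constructed two-patient cohort", {
  eps <- dplyr::bind_rows(make_episode("P1", hours = 1), make_episode("P2", hours = 1))
  slots <- t0 + (0:12) * 300
  dev <- dplyr::bind_rows(
    make_device("P1", slots, PR = 80, MBP = 90, RR = 15, SPO2 = 97, TEMP = 37),
    make_device("P2", slots[1:7], PR = 81, MBP = 91, RR = 16, SPO2 = 96, TEMP = 37)
  )
  comp <- completeness(dev, eps)
  expect_equal(comp$expected_slots, 26L)
  expect_equal(comp$missing_slots, 6L)
  expect_equal(round(100 * comp$missing_fraction, 1), 23.1)
  # all records complete -> complete == obtained
  expect_equal(comp$complete_records, comp$obtained_slots)
  expect_equal(comp$per_parameter$n_absent, rep(0L, 5))
})

test_that("records outside the episode are excluded and counted", {
  eps <- make_episode("P1", hours = 1)
  dev <- make_device("P1", t0 + c(0, 300, 2 * 3600), PR = c(80, 81, 82),
                     MBP = 90, RR = 15, SPO2 = 97, TEMP = 37)
  comp <- completeness(dev, eps)
  expect_equal(comp$n_excluded_records, 1L)
  expect_equal(comp$obtained_slots, 2L)
})

test_that("per-parameter absence is counted among obtained records", {
  eps <- make_episode("P1", hours = 1)
  dev <- make_device("P1", t0 + (0:12) * 300,
                     PR = 80, MBP = 90, RR = 15,
                     SPO2 = c(rep(NA, 3), rep(96, 10)), TEMP = 37)
  comp <- completeness(dev, eps)
  pp <- comp$per_parameter
  expect_equal(pp$n_absent[pp$parameter == "SPO2"], 3L)
  expect_equal(round(100 * pp$absent_fraction[pp$parameter == "SPO2"], 1), 23.1)
  expect_equal(comp$complete_records, 10L)
})
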