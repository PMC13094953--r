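th <- abnormality_thresholds()
row_th <- function(label) th[th$label == label, ]

test_that("abnormality detection honors the printed strictness", {
  expect_true(detect_abnormal(c(72, 58, 75), row_th("MBP <60")))
  expect_false(detect_abnormal(c(60, 60), row_th("MBP <60"))) # strict boundary
  expect_true(detect_abnormal(100, row_th("PR ≥100")))        # inclusive
  expect_true(detect_abnormal(40, row_th("PR ≤40")))          # inclusive
  expect_true(detect_abnormal(c(21, NA, 19), row_th("RR >20"))) # NAs skipped
  expect_false(detect_abnormal(numeric(0), row_th("MBP <60")))
  expect_false(detect_abnormal(c(NA_real_, NA_real_), row_th("MBP <60")))
})

test_that("a persistence requirement needs consecutive exceedances", {
  th2 <- abnormality_thresholds(min_consecutive = 2)
  r <- th2[th2$label == "MBP <60", ]
  expect_false(detect_abnormal(c(58, 70, 58), r))
  expect_true(detect_abnormal(c(70, 58, 58), r))
})

test_that("2x2 tables tally and exclude as defined", {
  tab <- build_table(c(P1 = TRUE, P2 = FALSE), c(P1 = TRUE, P2 = FALSE))
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(1L, 0L, 0L, 1L))
  tab <- build_table(c(P1 = TRUE), c(P1 = FALSE))
  expect_equal(tab$b, 1L)
  # a patient with missing data in one source is excluded and counted
  tab <- build_table(c(P1 = TRUE, P2 = NA), c(P1 = TRUE, P2 = TRUE))
  expect_equal(tab$n, 1L)
  expect_equal(tab$n_excluded, 1L)
  expect_error(build_table(c(P1 = TRUE), c(P2 = TRUE)), "patient sets differ")
})

test_that("kappa matches the hand-checked 2x2 values", {
  k <- cohen_kappa(two_by_two(2, 1, 7, 80))
  expect_equal(round(k$kappa, 2), 0.30)
  expect_equal(round(k$ci_lower, 2), -0.04)
  expect_equal(round(k$ci_upper, 2), 0.64)
  expect_equal(cohen_kappa(two_by_two(5, 0, 0, 5))$kappa, 1)
  expect_equal(cohen_kappa(two_by_two(1, 1, 1, 1))$kappa, 0)
  # degenerate single-category case
  expect_equal(cohen_kappa(two_by_two(0, 0, 0, 6))$kappa, 1)
})

test_that("kappa is invariant under simultaneous label swap", {
  withr::local_seed(55)
  for (rep in 1:50) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x) == 0) next
    k1 <- cohen_kappa(two_by_two(x[1], x[2], x[3], x[4]))
    k2 <- cohen_kappa(two_by_two(x[4], x[3], x[2], x[1]))
    expect_equal(k1$kappa, k2$kappa)
    expect_equal(k1$se, k2$se)
  }
})

test_that("McNemar switches between exact and corrected at 10 discordants", {
  m <- mcnemar_test(two_by_two(82, 1, 7, 0))
  expect_equal(m$method, "exact")
  expect_equal(round(m$p_value, 3), 0.070)
  m <- mcnemar_test(two_by_two(75, 2, 13, 0))
  expect_equal(m$method, "continuity_corrected")
  expect_equal(round(m$p_value, 3), 0.010)
  expect_equal(mcnemar_test(two_by_two(5, 0, 0, 5))$p_value, 1)
  # equal discordants above the cutoff use the corrected statistic as stated
  m <- mcnemar_test(two_by_two(68, 11, 11, 0))
  expect_equal(m$method, "continuity_corrected")
  expect_equal(round(m$p_value, 3), 0.831)
})

test_that("exact McNemar equals brute-force enumeration; b and c commute", {
  for (b in 0:12) {
    for (c in 0:(12 - b)) {
      m <- mcnemar_test(two_by_two(1, b, c, 1))
      if (b + c < 10) {
        expect_equal(m$p_value, enum_mcnemar_p(b, c), tolerance = 1e-12)
      }
      expect_equal(m$p_value, mcnemar_test(two_by_two(1, c, b, 1))$p_value)
    }
  }
})

test_that("corrected McNemar agrees with the base-R implementation", {
  for (bc in list(c(2, 13), c(21, 18), c(30, 1))) {
    m <- mcnemar_test(two_by_two(10, bc[1], bc[2], 10))
    ref <- stats::mcnemar.test(matrix(c(10, bc[1], bc[2], 10), 2), correct = TRUE)
    expect_equal(m$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("the concordance suite reproduces a brute-force tally on planted truth", {
  co <- generate_cohort(synth_config(n_patients = 12, duration_hours = c(24, 48), seed = 31))
  qc <- apply_qc(co$device)
  suite <- concordance_suite(qc$clean, co$nurse)
  expect_equal(nrow(suite), 17L)
  expect_true(all(suite$n + suite$n_excluded == 12L))
  # brute-force recount for one threshold
  r <- row_th("MBP >100")
  pats <- sort(unique(co$device$patient_id))
  dev_pos <- nur_pos <- logical(length(pats))
  for (i in seq_along(pats)) {
    dv <- qc$clean$MBP[qc$clean$patient_id == pats[i]]
    nv <- co$nurse$MBP[co$nurse$patient_id == pats[i]]
    dev_pos[i] <- any(dv > 100, na.rm = TRUE)
    nur_pos[i] <- any(nv > 100, na.rm = TRUE)
  }
  row <- suite[suite$label == "MBP >100", ]
  expect_equal(row$a, sum(nur_pos & dev_pos))
  expect_equal(row$b, sum(nur_pos & !dev_pos))
  expect_equal(row$c, sum(!nur_pos & dev_pos))
  expect_equal(row$d, sum(!nur_pos & !dev_pos))
})

test_that("continuous monitoring catches short episodes nurses miss", {
  # device-only detectable hypotension: c should exceed b at the MBP <65 cut
  cfg <- synth_config(n_patients = 25, duration_hours = c(36, 60), seed = 99)
  co <- generate_cohort(cfg)
  qc <- apply_qc(co$device)
  suite <- concordance_suite(qc$clean, co$nurse)
  sub <- suite[suite$parameter %in% c("MBP", "SPO2", "PR"), ]
  expect_gt(sum(sub$c), sum(sub$b))
})

test_that("an empty cohort is an error", {
  empty <- tibble::tibble(patient_id = character(), MBP = double())
  expect_error(concordance_suite(empty, empty), "empty cohort")
})

test_that("report formatting follows the stated rounding rules", {
  expect_equal(format_pvalue(0.0703), "0.070")
  expect_equal(format_pvalue(0.0004), "<0.001")
  expect_equal(format_pvalue(0.00051), "0.001")
  expect_equal(format_kappa(0.2982, -0.0449, 0.6414), "0.30 [-0.04; 0.64]")
  expect_equal(format_kappa(NA, NA, NA), "-")
})
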