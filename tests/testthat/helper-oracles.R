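# Independent reference implementations used as oracles. These are written
# as plain nested loops / closed forms, deliberately sharing no code with
# the package internals.

# naive artifact screening: range first, then deviation and (SpO2) step on
# the survivors, re-scanning for the prior reading at every position
naive_flags <- function(values, parameter, rules = qc_rules()) {
  lim <- rules$range_limits[[parameter]]
  n <- length(values)
  range_f <- values < lim[1] | values > lim[2]
  keep <- which(!range_f)
  v <- values[keep]
  m <- length(v)

  dev_f <- rep(FALSE, m)
  for (i in seq_len(m)) {
    prior <- NA_real_
    if (i > 1) for (j in 1:(i - 1)) if (!dev_f[j]) prior <- v[j]
    if (!is.na(prior) && prior > 0 &&
        abs(v[i] - prior) / prior > rules$deviation_fraction) {
      confirmed <- FALSE
      if (i < m && v[i] > 0 &&
          abs(v[i + 1] - v[i]) / v[i] <= rules$confirmation_fraction) {
        confirmed <- TRUE
      }
      if (!confirmed) dev_f[i] <- TRUE
    }
  }

  step_f <- rep(FALSE, m)
  if (parameter == "SPO2") {
    for (i in seq_len(m)) {
      prior <- NA_real_
      if (i > 1) for (j in 1:(i - 1)) if (!step_f[j]) prior <- v[j]
      if (!is.na(prior) && abs(v[i] - prior) >= rules$spo2_step_points) {
        confirmed <- i < m && abs(v[i + 1] - v[i]) < rules$spo2_step_points
        if (!confirmed) step_f[i] <- TRUE
      }
    }
  }

  out_dev <- rep(FALSE, n); out_dev[keep] <- dev_f
  out_step <- rep(FALSE, n); out_step[keep] <- step_f
  list(range = range_f, deviation = out_dev, spo2_step = out_step)
}

# exact McNemar p by explicit binomial-tail enumeration
enum_mcnemar_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  tail <- 0
  for (i in 0:min(b, c)) tail <- tail + choose(n, i) / 2^n
  min(1, 2 * tail)
}

# run the production QC on a bare series and return per-rule logical flags
production_flags <- function(values, parameter, rules = qc_rules()) {
  t0 <- as.POSIXct("2021-03-01 10:00:00", tz = "UTC")
  tb <- tibble::tibble(patient_id = "P1",
                       timestamp = t0 + (seq_along(values) - 1) * 300)
  tb[[parameter]] <- values
  qc <- apply_qc(tb, rules)
  out <- list(range = rep(FALSE, length(values)),
              deviation = rep(FALSE, length(values)),
              spo2_step = rep(FALSE, length(values)))
  for (k in seq_len(nrow(qc$flags))) {
    i <- match(qc$flags$timestamp[k], tb$timestamp)
    out[[qc$flags$rule[k]]][i] <- TRUE
  }
  out
}

# random plausible series per parameter, with occasional wild values so the
# range rule and large jumps are exercised
random_series <- function(parameter, n) {
  base <- switch(parameter,
    PR = runif(1, 50, 120), MBP = runif(1, 60, 120), RR = runif(1, 10, 25),
    SPO2 = runif(1, 88, 99), TEMP = runif(1, 36, 39))
  v <- numeric(n)
  v[1] <- base
  for (i in 2:n) {
    u <- runif(1)
    v[i] <- if (u < 0.70) v[i - 1] * runif(1, 0.93, 1.07)
      else if (u < 0.85) v[i - 1] * runif(1, 0.4, 2.2)
      else switch(parameter,
        PR = runif(1, 0, 320), MBP = runif(1, 0, 320), RR = runif(1, 0, 100),
        SPO2 = runif(1, 40, 100), TEMP = runif(1, 28, 47))
  }
  if (parameter == "SPO2") v <- pmin(pmax(v, 0), 100)
  round(v, 1)
}

make_episode <- function(pid = "P1", start = "2021-03-01 10:00:00", hours = 1) {
  adm <- as.POSIXct(start, tz = "UTC")
  tibble::tibble(patient_id = pid, ward_admission = adm,
                 sensor_removal = adm + hours * 3600)
}

make_device <- function(pid, times, ...) {
  tibble::tibble(patient_id = pid, timestamp = times, ...)
}

make_nurse <- function(pid, times, ..., temp_adjusted = TRUE) {
  tibble::tibble(patient_id = pid, timestamp = times, ...,
                 temp_adjusted = temp_adjusted)
}

# a single mid-size cohort at default study conditions, shared within a file
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(
        synth_config(n_patients = 40, duration_hours = c(48, 72), seed = 20210301)
      )
    }
    cache
  }
})
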