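#' Synthetic ward-monitoring configuration
#'
#' Describes a cohort of postoperative patients wearing a continuous
#' multiparameter sensor alongside routine nurse spot-checks. Defaults
#' emulate the statistical structure the analysis pipeline assumes:
#' episodes of 12-118 h on a 5-minute slot grid, bursty whole-record data
#' loss near 43.8% of expected slots, SpO2 additionally absent in 16.1% of
#' obtained records, rare isolated spike artifacts, superimposed abnormality
#' episodes, and 2-3 nurse checks per day with measurement noise plus a
#' positive nurse RR bias and a positive device TEMP bias.
#'
#' @param n_patients Number of patients.
#' @param duration_hours Range (hours) of the uniform episode-duration
#'   distribution.
#' @param baselines Named per-parameter cohort centers.
#' @param between_sd Named per-parameter SD of patient baselines.
#' @param within_sd Named per-parameter stationary SD of the within-patient
#'   AR(1) fluctuation.
#' @param ar1 Named per-parameter AR(1) coefficient at the 5-minute lag.
#' @param slot_minutes Device reporting interval.
#' @param slot_loss_fraction Long-run fraction of expected slots lost
#'   (all parameters jointly).
#' @param loss_burst_mean_slots Mean length (slots) of a lost burst;
#'   obtained bursts get the complementary mean so the long-run loss
#'   fraction equals `slot_loss_fraction`. Burst lengths are geometric.
#' @param dropout_fractions Named per-parameter probability that an obtained
#'   record lacks that parameter (SpO2-dominated).
#' @param artifact_rates Named per-parameter per-record probability of an
#'   injected spike artifact.
#' @param episode_spec Tibble (`parameter`, `target`, `prob`,
#'   `duration_minutes`) of true abnormality episodes: with probability
#'   `prob` a patient gets one episode during which the latent value ramps
#'   smoothly (raised cosine) to `target` and back.
#' @param nurse_visits_per_day 2 (morning, evening) or 3 (plus midday).
#' @param nurse_noise Named per-parameter SD of nurse measurement error.
#' @param nurse_rr_bias Breaths/min added to nurse RR relative to the latent
#'   value (nurse counts read higher than the device).
#' @param nurse_temp_bias Degrees C by which the device reads above the
#'   (adjusted) nurse temperature.
#' @param start_time Cohort start; admissions fall within 6 h after it.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A list of class `wardmon_synth_config`.
#' @export
synth_config <- function(n_patients = 90,
                         duration_hours = c(12, 118),
                         baselines = c(MBP = 89, PR = 77, RR = 16, SPO2 = 96, TEMP = 37.8),
                         between_sd = c(MBP = 8, PR = 10, RR = 2, SPO2 = 1.5, TEMP = 0.3),
                         within_sd = c(MBP = 7, PR = 7, RR = 2, SPO2 = 1.5, TEMP = 0.25),
                         ar1 = c(MBP = 0.9, PR = 0.9, RR = 0.9, SPO2 = 0.9, TEMP = 0.9),
                         slot_minutes = 5,
                         slot_loss_fraction = 0.438,
                         loss_burst_mean_slots = 6,
                         dropout_fractions = c(PR = 2e-4, MBP = 0.020, RR = 0.016,
                                               SPO2 = 0.161, TEMP = 1e-4),
                         artifact_rates = c(PR = 4e-4, MBP = 4e-4, RR = 1.4e-3,
                                            SPO2 = 3.1e-3, TEMP = 1.7e-3),
                         episode_spec = default_episode_spec(),
                         nurse_visits_per_day = 3,
                         nurse_noise = c(MBP = 6, PR = 4, RR = 2.5, SPO2 = 1.5, TEMP = 0.25),
                         nurse_rr_bias = 3,
                         nurse_temp_bias = 0.4,
                         start_time = as.POSIXct("2021-03-01 10:00:00", tz = "UTC"),
                         seed = 1L) {
  params <- core_parameters()
  for (nm in c("baselines", "between_sd", "within_sd", "ar1",
               "dropout_fractions", "artifact_rates", "nurse_noise")) {
    v <- get(nm)
    if (!all(params %in% names(v))) {
      rlang::abort(paste0("`", nm, "` must be named over ", paste(params, collapse = ", ")))
    }
  }
  stopifnot(
    n_patients >= 1,
    length(duration_hours) == 2L, duration_hours[1] < duration_hours[2],
    duration_hours[1] >= 1, duration_hours[2] <= 200,
    slot_minutes > 0,
    slot_loss_fraction >= 0, slot_loss_fraction < 1,
    loss_burst_mean_slots >= 1,
    all(dropout_fractions >= 0), all(dropout_fractions <= 1),
    all(artifact_rates >= 0), all(artifact_rates <= 1),
    all(between_sd >= 0), all(within_sd >= 0),
    all(ar1 >= 0), all(ar1 < 1),
    nurse_visits_per_day %in% c(2, 3),
    all(nurse_noise >= 0)
  )
  if (nrow(episode_spec)) {
    stopifnot(all(c("parameter", "target", "prob", "duration_minutes") %in% names(episode_spec)))
    stopifnot(all(episode_spec$prob >= 0), all(episode_spec$prob <= 1))
    if (any(episode_spec$duration_minutes / 60 >= duration_hours[1])) {
      rlang::abort("infeasible episode_spec: an abnormality episode is longer than the shortest monitoring window")
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      duration_hours = duration_hours,
      baselines = baselines[params], between_sd = between_sd[params],
      within_sd = within_sd[params], ar1 = ar1[params],
      slot_minutes = slot_minutes,
      slot_loss_fraction = slot_loss_fraction,
      loss_burst_mean_slots = loss_burst_mean_slots,
      dropout_fractions = dropout_fractions[params],
      artifact_rates = artifact_rates[params],
      episode_spec = episode_spec,
      nurse_visits_per_day = as.integer(nurse_visits_per_day),
      nurse_noise = nurse_noise[params],
      nurse_rr_bias = nurse_rr_bias,
      nurse_temp_bias = nurse_temp_bias,
      start_time = start_time,
      seed = as.integer(seed)
    ),
    class = "wardmon_synth_config"
  )
}

#' Default abnormality-episode specification
#'
#' One optional episode per patient and row: transient hypotension and
#' hypertension, tachycardia, tachypnea, desaturation, and fever. Targets
#' sit beyond the corresponding detection thresholds; prevalences are
#' package defaults for a plausible postoperative ward.
#' @return Tibble (`parameter`, `target`, `prob`, `duration_minutes`).
#' @export
default_episode_spec <- function() {
  tibble::tribble(
    ~parameter, ~target, ~prob, ~duration_minutes,
    "MBP",   54,  0.12,  45,
    "MBP",  125,  0.25,  60,
    "PR",   112,  0.35,  90,
    "RR",    24,  0.40,  60,
    "SPO2",  89,  0.35,  40,
    "TEMP", 38.6, 0.40, 180
  )
}

#' Inject one artifact into an obtained series
#'
#' Modifies a single value of one parameter's obtained (non-missing)
#' sequence so that it violates one artifact rule by construction:
#' `"deviation_spike"` sets the value beyond the deviation fraction of the
#' prior reading while the following reading stays near the prior, so the
#' spike is unconfirmed; `"range"` sets the value outside the configured
#' physiological limits; `"spo2_step"` introduces a one-sample drop of at
#' least the step threshold that the next reading reverses.
#'
#' @param values Numeric vector of obtained values (no NAs), time-ordered.
#' @param kind One of `"deviation_spike"`, `"range"`, `"spo2_step"`.
#' @param position Index to corrupt; must have a prior and a following value.
#' @param parameter Parameter name (for limits and rounding).
#' @param rules [qc_rules()] the artifact is constructed to violate.
#' @return List with `values` (modified vector) and `value` (the injected
#'   reading).
#' @export
#' @examples
#' inject_artifact(c(80, 82, 81), "range", 2, "PR")$value  # 300
inject_artifact <- function(values, kind = c("deviation_spike", "range", "spo2_step"),
                            position, parameter, rules = qc_rules()) {
  kind <- match.arg(kind)
  assert_parameter(parameter)
  n <- length(values)
  if (position <= 1L || position >= n) {
    rlang::abort("`position` must have a prior and a following obtained value")
  }
  if (anyNA(values)) rlang::abort("`values` must be the obtained (non-NA) sequence")
  prior <- values[position - 1L]
  lim <- rules$range_limits[[parameter]]
  digits <- parameter_digits(parameter)
  v <- switch(
    kind,
    deviation_spike = {
      if (prior <= 0) rlang::abort("deviation spike needs a positive prior value")
      up <- prior * (1 + 2.2 * rules$deviation_fraction) # 1.7x at defaults
      dn <- prior * (1 - 1.1 * rules$deviation_fraction) # 0.45x at defaults
      if (is.null(lim) || up < lim[2]) up
      else if (dn > lim[1]) dn
      else rlang::abort("cannot construct an in-range deviation spike here")
    },
    range = {
      if (is.null(lim)) rlang::abort(paste0("no range limits configured for ", parameter))
      if (parameter == "TEMP") lim[2] + 1.5 else lim[2] * 1.2
    },
    spo2_step = {
      if (parameter != "SPO2") rlang::abort("spo2_step artifacts apply to SPO2 only")
      max(0, prior - (rules$spo2_step_points + 4))
    }
  )
  v <- round(v, digits)
  values[position] <- v
  list(values = values, value = v)
}

#' Generate a synthetic monitoring cohort with ground truth
#'
#' Simulates, per patient: a latent smooth AR(1) trajectory per parameter
#' around a patient-specific baseline; optional abnormality episodes ramped
#' in with a raised-cosine profile; nurse observations drawn from the latent
#' truth at scheduled visit times with noise and the configured biases;
#' bursty whole-record slot loss; per-parameter dropout; and isolated
#' injected artifacts that violate the artifact rules by construction.
#' One random stream per patient is derived from `(seed, patient index)`,
#' so cohorts are bit-identical under a fixed seed.
#'
#' @param config A [synth_config()].
#' @param thresholds Abnormality thresholds used to compute ground-truth
#'   per-patient labels from the latent (pre-loss, pre-artifact) series.
#' @param rules [qc_rules()] that injected artifacts are constructed to
#'   violate.
#' @return A list of class `wardmon_cohort`:
#' \describe{
#'   \item{device}{obtained device records (wide tibble).}
#'   \item{nurse}{nurse observations (`temp_adjusted = TRUE`).}
#'   \item{episodes}{monitoring episodes per patient.}
#'   \item{truth}{ground truth: `missing_mask`, `artifacts`,
#'     `episode_windows`, `labels` (per patient x threshold).}
#'   \item{config}{the resolved configuration.}
#' }
#' @export
generate_cohort <- function(config = synth_config(),
                            thresholds = abnormality_thresholds(),
                            rules = qc_rules()) {
  stopifnot(inherits(config, "wardmon_synth_config"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)

  params <- core_parameters()
  step_s <- config$slot_minutes * 60
  out <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%03d", i)
    out[[i]] <- simulate_patient(pid, config, thresholds, rules, params, step_s)
  }
  cohort <- list(
    device = dplyr::bind_rows(purrr::map(out, "device")),
    nurse = dplyr::bind_rows(purrr::map(out, "nurse")),
    episodes = dplyr::bind_rows(purrr::map(out, "episode")),
    truth = list(
      missing_mask = dplyr::bind_rows(purrr::map(out, "mask")),
      artifacts = dplyr::bind_rows(purrr::map(out, "artifacts")),
      episode_windows = dplyr::bind_rows(purrr::map(out, "windows")),
      labels = dplyr::bind_rows(purrr::map(out, "labels"))
    ),
    config = config
  )
  class(cohort) <- "wardmon_cohort"
  cohort
}

patient_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 30269) %% 2147483629)
}

simulate_patient <- function(pid, config, thresholds, rules, params, step_s) {
  dur_s <- round(stats::runif(1, config$duration_hours[1], config$duration_hours[2]) * 3600)
  adm <- config$start_time + round(stats::runif(1, 0, 6 * 3600))
  n <- floor(dur_s / step_s) + 1L
  slots <- adm + (seq_len(n) - 1L) * step_s
  rem <- adm + dur_s

  # latent AR(1) trajectories around patient baselines
  latent <- matrix(NA_real_, n, length(params), dimnames = list(NULL, params))
  for (p in params) {
    mu <- config$baselines[[p]] + stats::rnorm(1, 0, config$between_sd[[p]])
    phi <- config$ar1[[p]]
    innov <- stats::rnorm(n, 0, config$within_sd[[p]] * sqrt(1 - phi^2))
    z0 <- stats::rnorm(1, 0, config$within_sd[[p]])
    latent[, p] <- mu + as.numeric(stats::filter(innov, phi, method = "recursive", init = z0))
  }

  # superimpose abnormality episodes as raised-cosine excursions
  windows <- list()
  spec <- config$episode_spec
  for (k in seq_len(nrow(spec))) {
    hit <- stats::runif(1) < spec$prob[k]
    dur_slots <- max(3L, as.integer(round(spec$duration_minutes[k] / config$slot_minutes)))
    if (!hit || dur_slots >= n) next
    s <- sample.int(n - dur_slots, 1L)
    idx <- s:(s + dur_slots - 1L)
    alpha <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (dur_slots + 1)))
    p <- spec$parameter[k]
    latent[idx, p] <- (1 - alpha) * latent[idx, p] + alpha * spec$target[k]
    windows[[length(windows) + 1L]] <- tibble::tibble(
      patient_id = pid, parameter = p, target = spec$target[k],
      start = slots[s], end = slots[s + dur_slots - 1L]
    )
  }
  latent[, "SPO2"] <- pmin(pmax(latent[, "SPO2"], 0), 100)

  # device-scale (rounded) full-grid series defines the ground truth labels
  device_scale <- latent
  for (p in params) device_scale[, p] <- round(latent[, p], parameter_digits(p))
  labels <- purrr::map_dfr(seq_len(nrow(thresholds)), function(j) {
    th <- thresholds[j, ]
    tibble::tibble(
      patient_id = pid, label = th$label,
      truth = detect_abnormal(device_scale[, th$parameter], th)
    )
  })

  # nurse observations from the latent truth, with noise and biases
  nurse <- simulate_nurse(pid, config, latent, adm, rem, slots)

  # bursty whole-record slot loss
  lost <- simulate_loss_mask(n, config)
  mask <- tibble::tibble(patient_id = pid, slot_time = slots, obtained = !lost)

  obt <- which(!lost)
  device <- tibble::as_tibble(as.data.frame(device_scale[obt, , drop = FALSE]))
  device <- dplyr::bind_cols(
    tibble::tibble(patient_id = pid, timestamp = slots[obt]), device
  )

  # per-parameter dropout among obtained records
  for (p in params) {
    fr <- config$dropout_fractions[[p]]
    if (fr > 0 && nrow(device)) {
      device[[p]][stats::runif(nrow(device)) < fr] <- NA_real_
    }
  }

  # isolated injected artifacts
  art <- inject_patient_artifacts(pid, device, config, rules, params)
  list(
    device = art$device, nurse = nurse,
    episode = tibble::tibble(patient_id = pid, ward_admission = adm, sensor_removal = rem),
    mask = mask, artifacts = art$truth,
    windows = if (length(windows)) dplyr::bind_rows(windows) else NULL,
    labels = labels
  )
}

simulate_loss_mask <- function(n, config) {
  f <- config$slot_loss_fraction
  if (f <= 0) return(rep(FALSE, n))
  mean_lost <- config$loss_burst_mean_slots
  mean_obt <- mean_lost * (1 - f) / f
  p_lost <- 1 / mean_lost
  p_obt <- 1 / mean_obt
  state <- stats::runif(1) < f # TRUE = lost
  out <- logical(0)
  while (length(out) < n) {
    len <- 1L + stats::rgeom(1, if (state) p_lost else p_obt)
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n)]
}

simulate_nurse <- function(pid, config, latent, adm, rem, slots) {
  starts <- if (config$nurse_visits_per_day == 3L) c(7, 12, 18) else c(7, 18)
  days <- seq(as.Date(adm, tz = "UTC"), as.Date(rem, tz = "UTC"), by = "day")
  rows <- list()
  for (d in as.list(days)) {
    day0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    for (h in starts) {
      t <- day0 + h * 3600 + round(stats::runif(1, 0, 2 * 3600) / 60) * 60
      if (t < adm || t > rem) next
      j <- min(max(1L, round(as.numeric(t - adm, units = "secs") / (config$slot_minutes * 60)) + 1L),
               nrow(latent))
      noise <- config$nurse_noise
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, timestamp = t,
        PR = round(latent[j, "PR"] + stats::rnorm(1, 0, noise[["PR"]])),
        MBP = round(latent[j, "MBP"] + stats::rnorm(1, 0, noise[["MBP"]])),
        RR = round(latent[j, "RR"] + config$nurse_rr_bias + stats::rnorm(1, 0, noise[["RR"]])),
        SPO2 = min(100, round(latent[j, "SPO2"] + stats::rnorm(1, 0, noise[["SPO2"]]))),
        TEMP = round(latent[j, "TEMP"] - config$nurse_temp_bias + stats::rnorm(1, 0, noise[["TEMP"]]), 1),
        temp_adjusted = TRUE
      )
    }
  }
  if (!length(rows)) return(NULL)
  dplyr::bind_rows(rows)
}

inject_patient_artifacts <- function(pid, device, config, rules, params) {
  truth <- list()
  for (p in params) {
    rate <- config$artifact_rates[[p]]
    vals <- device[[p]]
    obt_idx <- which(!is.na(vals))
    m <- length(obt_idx)
    if (rate <= 0 || m < 3L) next
    n_art <- stats::rbinom(1, m, rate)
    if (n_art == 0L) next
    # positions spaced >= 3 apart so priors and follow-ups stay natural
    chosen <- integer(0)
    for (j in sample(2:(m - 1L))) {
      if (length(chosen) >= n_art) break
      if (all(abs(j - chosen) >= 3L)) chosen <- c(chosen, j)
    }
    for (j in sort(chosen)) {
      kind <- if (p == "SPO2") "spo2_step"
        else if (p == "TEMP") "range"
        else if (stats::runif(1) < 0.7) "deviation_spike" else "range"
      seq_vals <- device[[p]][obt_idx]
      res <- inject_artifact(seq_vals, kind, j, p, rules)
      device[[p]][obt_idx] <- res$values
      truth[[length(truth) + 1L]] <- tibble::tibble(
        patient_id = pid, timestamp = device$timestamp[obt_idx[j]],
        parameter = p,
        rule = switch(kind, deviation_spike = "deviation", range = "range",
                      spo2_step = "spo2_step"),
        value = res$value
      )
    }
  }
  list(
    device = device,
    truth = if (length(truth)) dplyr::bind_rows(truth) else
      tibble::tibble(patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                     parameter = character(), rule = character(), value = double())
  )
}

#' Write a synthetic cohort to a directory
#'
#' Writes `device.csv`, `nurse.csv`, `episodes.csv` and `ground_truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wardmon_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vitals_table(cohort$device, file.path(dir, "device.csv"))
  write_vitals_table(cohort$nurse, file.path(dir, "nurse.csv"))
  write_vitals_table(cohort$episodes, file.path(dir, "episodes.csv"))
  truth <- cohort$truth
  truth <- purrr::map(truth, function(tb) {
    for (nm in names(tb)) {
      if (inherits(tb[[nm]], "POSIXct")) tb[[nm]] <- format(tb[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    }
    tb
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
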