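#' Flag values outside physiological range limits
#'
#' Values strictly below the lower or strictly above the upper configured
#' limit are artifacts; boundary values pass. Parameters without configured
#' limits are skipped with a message.
#'
#' @param values Numeric vector of obtained values (time-ordered, no NAs).
#' @param parameter Parameter name.
#' @param rules A [qc_rules()].
#' @return Logical vector: `TRUE` where flagged.
#' @export
#' @examples
#' flag_range(c(80, 300, 82), "PR")  # FALSE TRUE FALSE
flag_range <- function(values, parameter, rules = qc_rules()) {
  assert_parameter(parameter)
  lim <- rules$range_limits[[parameter]]
  if (is.null(lim)) {
    message("no range limits configured for ", parameter, "; range rule skipped")
    return(rep(FALSE, length(values)))
  }
  values < lim[1] | values > lim[2]
}

#' Flag unconfirmed large deviations from the prior reading
#'
#' A value whose relative change from the prior reading exceeds the
#' deviation fraction is an artifact candidate. Under the default
#' `"confirmation"` semantics the candidate is genuine only when the next
#' obtained value stays within the confirmation fraction of the candidate
#' (a sustained change); under `"recovery"` it is genuine only when the
#' next value returns to within the confirmation fraction of the prior
#' reading. Unconfirmed candidates — including a candidate with no
#' following value — are flagged. Flagged values never serve as the prior
#' for later comparisons, so one spike cannot cascade. Comparisons against
#' a nonpositive prior are skipped.
#'
#' The rule is scale-invariant: it flags the same positions for `values`
#' and `k * values`, any `k > 0`.
#'
#' @inheritParams flag_range
#' @return Logical vector: `TRUE` where flagged.
#' @export
#' @examples
#' flag_deviation(c(80, 130, 128))  # no flag: jump confirmed
#' flag_deviation(c(80, 130, 82))   # flags the 130
flag_deviation <- function(values, rules = qc_rules()) {
  n <- length(values)
  flags <- logical(n)
  prior <- NA_real_
  for (i in seq_len(n)) {
    v <- values[i]
    if (!is.na(prior)) {
      if (prior <= 0) {
        # nonpositive prior: comparison undefined, skip
      } else if (abs(v - prior) / prior > rules$deviation_fraction) {
        flags[i] <- !deviation_confirmed(values, i, prior, rules)
      }
    }
    if (!flags[i]) prior <- v
  }
  flags
}

deviation_confirmed <- function(values, i, prior, rules) {
  if (i >= length(values)) return(FALSE) # no follow-up: unconfirmed
  nxt <- values[i + 1L]
  v <- values[i]
  if (rules$deviation_semantics == "confirmation") {
    v > 0 && abs(nxt - v) / v <= rules$confirmation_fraction
  } else {
    abs(nxt - prior) / prior <= rules$confirmation_fraction
  }
}

#' Flag unconfirmed SpO2 steps between consecutive readings
#'
#' The later reading of a consecutive obtained pair changing by at least
#' `spo2_step_points` percentage points is a candidate. The candidate is
#' genuine when the next obtained value stays within the step threshold of
#' it (the new level holds); it is flagged when the next value leaps again
#' by the step threshold or more, or when the series ends. Flagged values
#' are excluded from serving as the comparison point for later readings.
#'
#' @param values SpO2 values in \[0, 100\] (obtained, time-ordered, no NAs).
#' @param rules A [qc_rules()].
#' @return Logical vector: `TRUE` where flagged.
#' @export
#' @examples
#' flag_spo2_step(c(96, 87, 96))  # flags the 87 (drop then rebound)
#' flag_spo2_step(c(96, 88, 89))  # no flag (drop is sustained)
flag_spo2_step <- function(values, rules = qc_rules()) {
  step <- rules$spo2_step_points
  n <- length(values)
  flags <- logical(n)
  prior <- NA_real_
  for (i in seq_len(n)) {
    v <- values[i]
    if (!is.na(prior) && abs(v - prior) >= step) {
      confirmed <- i < n && abs(values[i + 1L] - v) < step
      flags[i] <- !confirmed
    }
    if (!flags[i]) prior <- v
  }
  flags
}

#' Apply all artifact rules to a cohort of device records
#'
#' Per patient and parameter, the range rule is applied first; surviving
#' values are screened by the deviation rule and (for SpO2) the step rule.
#' Flagged values are set to missing in the clean copy. A value flagged by
#' two rules is removed once but counted in each rule's tally.
#'
#' @param device Wide tibble of device records, sorted per patient.
#' @param rules A [qc_rules()].
#' @return A list of class `wardmon_qc`:
#' \describe{
#'   \item{clean}{`device` with flagged values set to `NA`.}
#'   \item{flags}{tibble (`patient_id`, `timestamp`, `parameter`, `rule`,
#'     `value`) — one row per rule firing.}
#'   \item{summary}{per-parameter obtained counts, per-rule flag counts,
#'     flagged value counts and rates.}
#' }
#' @export
apply_qc <- function(device, rules = qc_rules()) {
  params <- intersect(core_parameters(), names(device))
  clean <- dplyr::arrange(device, .data$patient_id, .data$timestamp)
  flag_rows <- list()
  for (pid in unique(clean$patient_id)) {
    rows <- which(clean$patient_id == pid)
    for (p in params) {
      vals <- clean[[p]][rows]
      obt <- which(!is.na(vals))
      if (!length(obt)) next
      v <- vals[obt]
      f_range <- flag_range(v, p, rules)
      keep <- which(!f_range)
      f_dev <- logical(length(v))
      f_step <- logical(length(v))
      if (length(keep)) {
        f_dev[keep] <- flag_deviation(v[keep], rules)
        if (p == "SPO2") f_step[keep] <- flag_spo2_step(v[keep], rules)
      }
      for (rule in c("range", "deviation", "spo2_step")) {
        f <- switch(rule, range = f_range, deviation = f_dev, spo2_step = f_step)
        if (any(f)) {
          flag_rows[[length(flag_rows) + 1L]] <- tibble::tibble(
            patient_id = pid,
            timestamp = clean$timestamp[rows][obt][f],
            parameter = p, rule = rule, value = v[f]
          )
        }
      }
      any_f <- f_range | f_dev | f_step
      if (any(any_f)) {
        clean[[p]][rows[obt[any_f]]] <- NA_real_
      }
    }
  }
  flags <- if (length(flag_rows)) dplyr::bind_rows(flag_rows) else
    tibble::tibble(patient_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC"),
                   parameter = character(), rule = character(), value = double())
  summary <- qc_summary(device, flags, params)
  structure(list(clean = clean, flags = flags, summary = summary),
            class = "wardmon_qc")
}

qc_summary <- function(device, flags, params) {
  purrr::map_dfr(params, function(p) {
    n_obt <- sum(!is.na(device[[p]]))
    fl <- flags[flags$parameter == p, ]
    n_flagged <- nrow(dplyr::distinct(fl, .data$patient_id, .data$timestamp))
    tibble::tibble(
      parameter = p,
      n_obtained = n_obt,
      n_range = sum(fl$rule == "range"),
      n_deviation = sum(fl$rule == "deviation"),
      n_spo2_step = sum(fl$rule == "spo2_step"),
      n_flagged_values = n_flagged,
      flag_rate = if (n_obt > 0) n_flagged / n_obt else NA_real_
    )
  })
}

#' Data-completeness accounting against the expected slot grid
#'
#' Expected slots come from each patient's monitoring episode; obtained
#' slots are the expected slots covered by a device record (records are
#' assigned to the nearest slot). Records outside their patient's episode
#' are excluded and reported. Per-parameter absence is counted among
#' obtained records.
#'
#' @param device Wide tibble of device records.
#' @param episodes Episode tibble covering all patients in `device`.
#' @param slot_minutes Slot spacing, default 5.
#' @return A list of class `wardmon_completeness`: `expected_slots`,
#'   `obtained_slots`, `missing_slots`, `missing_fraction`,
#'   `complete_records`, `n_excluded_records`, and `per_parameter`
#'   (tibble of absent counts/fractions among obtained records).
#' @export
completeness <- function(device, episodes, slot_minutes = 5) {
  params <- intersect(core_parameters(), names(device))
  missing_pat <- setdiff(unique(device$patient_id), episodes$patient_id)
  if (length(missing_pat)) {
    rlang::abort(paste0("no episode for patient(s): ", paste(missing_pat, collapse = ", ")))
  }
  step_s <- slot_minutes * 60
  expected <- 0L
  obtained <- 0L
  complete <- 0L
  excluded <- 0L
  absent <- stats::setNames(rep(0L, length(params)), params)
  for (k in seq_len(nrow(episodes))) {
    ep <- episodes[k, ]
    slots <- slot_grid(ep, slot_minutes)
    expected <- expected + length(slots)
    rec <- device[device$patient_id == ep$patient_id, , drop = FALSE]
    if (!nrow(rec)) next
    inside <- rec$timestamp >= ep$ward_admission & rec$timestamp <= ep$sensor_removal
    excluded <- excluded + sum(!inside)
    rec <- rec[inside, , drop = FALSE]
    if (!nrow(rec)) next
    slot_idx <- pmin(pmax(round(as.numeric(rec$timestamp - ep$ward_admission, units = "secs") / step_s) + 1L,
                          1L), length(slots))
    obtained <- obtained + length(unique(slot_idx))
    pres <- !is.na(as.matrix(rec[, params, drop = FALSE]))
    complete <- complete + sum(rowSums(pres) == length(params))
    absent <- absent + colSums(!pres)
  }
  n_rec_inside <- obtained # one record per slot in grid-aligned data
  per_parameter <- tibble::tibble(
    parameter = params,
    n_absent = as.integer(absent),
    absent_fraction = if (obtained > 0) as.numeric(absent) / obtained else NA_real_
  )
  structure(
    list(
      expected_slots = expected,
      obtained_slots = obtained,
      missing_slots = expected - obtained,
      missing_fraction = if (expected > 0) (expected - obtained) / expected else NA_real_,
      complete_records = complete,
      n_excluded_records = excluded,
      per_parameter = per_parameter
    ),
    class = "wardmon_completeness"
  )
}
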