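#' Pair nurse observations with device records
#'
#' For every nurse observation and every analyzed parameter present in it,
#' selects among the patient's device records carrying that parameter the
#' one closest in time, provided the interval does not exceed the pairing
#' window; comparisons further apart are not formed. Ties in distance are
#' broken toward the earlier device record. Each (observation, parameter)
#' yields at most one pair; a device record may serve two back-to-back
#' observations when both fall within the window.
#'
#' @param nurse Nurse observation tibble (TEMP must already carry the
#'   auricular correction: `temp_adjusted = TRUE`).
#' @param device QC-cleaned device tibble (flagged values set `NA`).
#' @param config A [pairing_config()].
#' @param flags Optional flag tibble from [apply_qc()]; used only to label
#'   exclusions caused by a flagged-and-removed device value.
#' @return A list of class `wardmon_pairs`:
#' \describe{
#'   \item{pairs}{tibble (`patient_id`, `parameter`, `nurse_time`,
#'     `device_time`, `delta_seconds`, `nurse_value`, `device_value`,
#'     `diff` = device - nurse).}
#'   \item{exclusions}{tibble of unmatched (observation, parameter) with a
#'     `reason`: `no_device_in_window`, `parameter_absent`, `value_flagged`.}
#' }
#' @export
match_pairs <- function(nurse, device, config = pairing_config(), flags = NULL) {
  params <- intersect(core_parameters(), names(nurse))
  if ("TEMP" %in% params && "temp_adjusted" %in% names(nurse)) {
    if (any(!nurse$temp_adjusted & !is.na(nurse$TEMP))) {
      rlang::abort("nurse TEMP must be auricular-adjusted before pairing; see adjust_auricular_temperature()")
    }
  }
  window_s <- config$window_minutes * 60
  pair_rows <- list()
  excl_rows <- list()
  dev_split <- split(device, device$patient_id)
  for (i in seq_len(nrow(nurse))) {
    obs <- nurse[i, ]
    dev <- dev_split[[obs$patient_id]]
    for (p in params) {
      nv <- obs[[p]]
      if (is.na(nv)) next
      reason <- NULL
      if (is.null(dev) || !nrow(dev)) {
        reason <- "no_device_in_window"
      } else {
        dt <- as.numeric(dev$timestamp - obs$timestamp, units = "secs")
        in_win <- abs(dt) <= window_s
        if (!any(in_win)) {
          reason <- "no_device_in_window"
        } else {
          cand <- which(in_win & !is.na(dev[[p]]))
          if (!length(cand)) {
            reason <- if (was_flagged(flags, obs$patient_id, p, dev$timestamp[in_win]))
              "value_flagged" else "parameter_absent"
          } else {
            j <- switch(config$selection,
              nearest = cand[order(abs(dt[cand]), dt[cand])][1],
              first = cand[order(dt[cand])][1]
            )
            pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
              patient_id = obs$patient_id, parameter = p,
              nurse_time = obs$timestamp, device_time = dev$timestamp[j],
              delta_seconds = abs(dt[j]),
              nurse_value = nv, device_value = dev[[p]][j],
              diff = dev[[p]][j] - nv
            )
          }
        }
      }
      if (!is.null(reason)) {
        excl_rows[[length(excl_rows) + 1L]] <- tibble::tibble(
          patient_id = obs$patient_id, parameter = p,
          nurse_time = obs$timestamp, reason = reason
        )
      }
    }
  }
  empty_pairs <- tibble::tibble(
    patient_id = character(), parameter = character(),
    nurse_time = as.POSIXct(character(), tz = "UTC"),
    device_time = as.POSIXct(character(), tz = "UTC"),
    delta_seconds = double(), nurse_value = double(),
    device_value = double(), diff = double()
  )
  structure(
    list(
      pairs = if (length(pair_rows)) dplyr::bind_rows(pair_rows) else empty_pairs,
      exclusions = if (length(excl_rows)) dplyr::bind_rows(excl_rows) else
        tibble::tibble(patient_id = character(), parameter = character(),
                       nurse_time = as.POSIXct(character(), tz = "UTC"),
                       reason = character())
    ),
    class = "wardmon_pairs"
  )
}

was_flagged <- function(flags, pid, parameter, times) {
  if (is.null(flags) || !nrow(flags)) return(FALSE)
  any(flags$patient_id == pid & flags$parameter == parameter &
        flags$timestamp %in% times)
}

#' Per-parameter pair tallies
#'
#' @param pairs A `wardmon_pairs` object or its `pairs` tibble.
#' @return Named integer vector over the five analyzed parameters.
#' @export
pair_counts <- function(pairs) {
  if (inherits(pairs, "wardmon_pairs")) pairs <- pairs$pairs
  counts <- stats::setNames(integer(length(core_parameters())), core_parameters())
  if (nrow(pairs)) {
    tab <- table(pairs$parameter)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
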