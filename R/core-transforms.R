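#' Apply the auricular-to-core temperature correction
#'
#' Nurse temperatures taken at the ear underestimate core temperature; the
#' study protocol adds +0.5 °C systematically. This transform applies that
#' correction to every `TEMP` value in a nurse observation table and marks
#' the rows adjusted. Re-adjusting an already-adjusted table is an error, so
#' the correction can never be applied twice.
#'
#' @param obs Nurse observation tibble with columns `TEMP` and
#'   `temp_adjusted`.
#' @return The table with `TEMP` increased by 0.5 where present and
#'   `temp_adjusted = TRUE`.
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   patient_id = "P1",
#'   timestamp = as.POSIXct("2021-03-01 08:00:00", tz = "UTC"),
#'   TEMP = 36.5, temp_adjusted = FALSE
#' )
#' adjust_auricular_temperature(obs)$TEMP  # 37.0
adjust_auricular_temperature <- function(obs) {
  if (!"temp_adjusted" %in% names(obs)) {
    rlang::abort("`obs` must carry a `temp_adjusted` column")
  }
  already <- which(obs$temp_adjusted & !is.na(obs$TEMP))
  if (length(already)) {
    rlang::abort(paste0(
      "auricular correction already applied (row ", already[1],
      "); refusing to adjust twice"
    ))
  }
  if ("TEMP" %in% names(obs)) {
    obs$TEMP <- obs$TEMP + 0.5
  }
  obs$temp_adjusted <- TRUE
  obs
}

#' Expected measurement slots of a monitoring episode
#'
#' The device is expected to report once per `step_minutes` from ward
#' admission to sensor removal; the slot grid enumerates those expected
#' times. An episode of duration `D` yields `floor(D / step) + 1` slots
#' (admission itself is a slot).
#'
#' @param episode One-row tibble (or list) with `ward_admission` and
#'   `sensor_removal` POSIXct fields.
#' @param step_minutes Slot spacing, default 5.
#' @return POSIXct vector of slot times.
#' @export
#' @examples
#' ep <- tibble::tibble(
#'   patient_id = "P1",
#'   ward_admission = as.POSIXct("2021-03-01 10:00:00", tz = "UTC"),
#'   sensor_removal = as.POSIXct("2021-03-01 11:00:00", tz = "UTC")
#' )
#' length(slot_grid(ep))  # 13
slot_grid <- function(episode, step_minutes = 5) {
  stopifnot(step_minutes > 0)
  adm <- episode$ward_admission
  rem <- episode$sensor_removal
  if (length(adm) != 1L || length(rem) != 1L) {
    rlang::abort("`episode` must describe exactly one patient")
  }
  if (!(rem > adm)) rlang::abort("sensor_removal must be after ward_admission")
  seq(from = adm, to = rem, by = step_minutes * 60)
}
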