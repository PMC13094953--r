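#' Vital-sign parameter registry
#'
#' The five parameters analyzed throughout the package (pulse rate, mean
#' blood pressure, respiratory rate, peripheral oxygen saturation, skin /
#' core temperature), plus systolic and diastolic pressure which may appear
#' in device exports but are not analyzed. Units are fixed per parameter.
#'
#' @return A tibble with columns `parameter`, `units`, `analyzed`.
#' @export
#' @examples
#' vital_parameters()
vital_parameters <- function() {
  tibble::tibble(
    parameter = c("PR", "MBP", "RR", "SPO2", "TEMP", "SBP", "DBP"),
    units = c("bpm", "mmHg", "breaths/min", "%", "°C", "mmHg", "mmHg"),
    analyzed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

#' Names of the five analyzed vital-sign parameters
#' @return Character vector `c("PR", "MBP", "RR", "SPO2", "TEMP")`.
#' @export
core_parameters <- function() c("PR", "MBP", "RR", "SPO2", "TEMP")

# all parameter columns a device table may carry
all_parameters <- function() vital_parameters()$parameter

#' @noRd
assert_parameter <- function(parameter) {
  if (!is.character(parameter) || length(parameter) != 1L ||
      !parameter %in% all_parameters()) {
    rlang::abort(paste0(
      "`parameter` must be one of: ", paste(all_parameters(), collapse = ", ")
    ))
  }
  invisible(parameter)
}

# decimal places used when a parameter is reported on the device scale
parameter_digits <- function(parameter) {
  if (parameter == "TEMP") 1L else 0L
}
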