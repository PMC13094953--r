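#' Read a device stream table
#'
#' Reads a wide CSV of device measurements: one row per time point, columns
#' `patient_id`, `timestamp` (ISO-8601, second resolution, timezone-naive,
#' interpreted as UTC), and one column per parameter. Blank cells become
#' missing values, never zeros.
#'
#' @param path CSV file.
#' @return A tibble sorted by (`patient_id`, `timestamp`) with one numeric
#'   column per parameter present in the file.
#' @export
read_device_table <- function(path) {
  read_vitals_table(path, source = "device")
}

#' Read a nurse observation table
#'
#' Same dialect as [read_device_table()], plus a logical `temp_adjusted`
#' column stating whether the +0.5 °C auricular-to-core correction has
#' already been applied to `TEMP`. If the column is absent it defaults to
#' `FALSE` (raw auricular values).
#'
#' @param path CSV file.
#' @return A tibble sorted by (`patient_id`, `timestamp`).
#' @export
read_nurse_table <- function(path) {
  tb <- read_vitals_table(path, source = "nurse")
  if (!"temp_adjusted" %in% names(tb)) tb$temp_adjusted <- FALSE
  tb$temp_adjusted <- as.logical(tb$temp_adjusted)
  tb
}

#' Read a monitoring-episode table
#'
#' Columns `patient_id`, `ward_admission`, `sensor_removal` (ISO-8601).
#' Episode durations must lie between 1 and 200 hours.
#'
#' @param path CSV file.
#' @return A tibble of episodes.
#' @export
read_episode_table <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    ward_admission = readr::col_character(),
    sensor_removal = readr::col_character()
  ))
  tb$ward_admission <- parse_timestamps(tb$ward_admission, path)
  tb$sensor_removal <- parse_timestamps(tb$sensor_removal, path)
  validate_episodes(tb)
  dplyr::arrange(tb, .data$patient_id)
}

#' Write a device, nurse, or episode table to CSV
#'
#' Timestamps are written as ISO-8601 at second resolution; missing cells
#' are written blank. A read of the written file reproduces values exactly
#' (all values are stored at the package's reporting resolution).
#'
#' @param x Tibble as returned by the readers or by [generate_cohort()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_vitals_table <- function(x, path) {
  out <- x
  for (nm in names(out)) {
    if (inherits(out[[nm]], "POSIXct")) {
      out[[nm]] <- format(out[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    }
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# shared reader for the wide vitals dialect
read_vitals_table <- function(path, source) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  tb <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("patient_id", "timestamp")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols)) {
    rlang::abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  tb$timestamp <- parse_timestamps(tb$timestamp, path)
  param_cols <- intersect(all_parameters(), names(tb))
  for (nm in param_cols) {
    v <- suppressWarnings(as.numeric(tb[[nm]]))
    bad <- which(!is.na(tb[[nm]]) & tb[[nm]] != "" & is.na(v))
    if (length(bad)) {
      rlang::abort(paste0("non-numeric ", nm, " value in row ", bad[1], " of ", path))
    }
    tb[[nm]] <- v
  }
  dup <- duplicated(tb[c("patient_id", "timestamp")])
  if (any(dup)) {
    i <- which(dup)[1]
    rlang::abort(paste0(
      "duplicate (patient_id, timestamp): ", tb$patient_id[i], " at ",
      format(tb$timestamp[i], "%Y-%m-%dT%H:%M:%S"), " in ", path
    ))
  }
  dplyr::arrange(tb, .data$patient_id, .data$timestamp)
}

parse_timestamps <- function(x, path) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  # also accept a space separator
  retry <- is.na(out) & !is.na(x)
  out[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    rlang::abort(paste0("malformed timestamp in row ", bad[1], " of ", path,
                        ": \"", x[bad[1]], "\""))
  }
  out
}

validate_episodes <- function(episodes) {
  dur_h <- as.numeric(episodes$sensor_removal - episodes$ward_admission, units = "hours")
  bad <- which(!(dur_h > 0))
  if (length(bad)) {
    rlang::abort(paste0("episode for ", episodes$patient_id[bad[1]],
                        " has sensor_removal <= ward_admission"))
  }
  oor <- which(dur_h < 1 | dur_h > 200)
  if (length(oor)) {
    rlang::abort(paste0("episode for ", episodes$patient_id[oor[1]],
                        " has duration ", round(dur_h[oor[1]], 2),
                        " h outside [1, 200] h"))
  }
  invisible(episodes)
}
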