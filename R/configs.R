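#' Artifact-rule configuration
#'
#' Numerical artifact criteria for device streams: a deviation rule (a value
#' changing by more than `deviation_fraction` from the prior reading is an
#' artifact unless the next reading confirms the new level to within
#' `confirmation_fraction`), a physiological range rule with per-parameter
#' closed limits, and an SpO2 step rule (a jump of `spo2_step_points`
#' percentage points or more between consecutive readings).
#'
#' Two semantics are available for the deviation rule's follow-up clause.
#' Under `"confirmation"` (default) a large jump is genuine when the next
#' value stays within `confirmation_fraction` of the jumped value, so
#' sustained deteriorations are kept and spike-and-return patterns are
#' flagged. Under `"recovery"` the jump is genuine only when the next value
#' returns to within `confirmation_fraction` of the prior reading.
#'
#' @param deviation_fraction Relative change from the prior reading that
#'   makes a value an artifact candidate. Default 0.50.
#' @param confirmation_fraction Relative tolerance of the follow-up clause.
#'   Default 0.25.
#' @param spo2_step_points SpO2 change, in absolute percentage points,
#'   flagged as a step candidate. Default 8.
#' @param range_limits Named list of `c(lower, upper)` physiological limits.
#'   Values strictly outside the limits are artifacts; boundary values pass.
#' @param deviation_semantics `"confirmation"` or `"recovery"` (see Details).
#' @return A list of class `wardmon_qc_rules`.
#' @export
#' @examples
#' rules <- qc_rules()
#' rules$range_limits$PR
qc_rules <- function(deviation_fraction = 0.5,
                     confirmation_fraction = 0.25,
                     spo2_step_points = 8,
                     range_limits = default_range_limits(),
                     deviation_semantics = c("confirmation", "recovery")) {
  deviation_semantics <- match.arg(deviation_semantics)
  stopifnot(
    is.numeric(deviation_fraction), length(deviation_fraction) == 1L,
    deviation_fraction > 0, deviation_fraction < 1,
    is.numeric(confirmation_fraction), length(confirmation_fraction) == 1L,
    confirmation_fraction > 0, confirmation_fraction < 1,
    is.numeric(spo2_step_points), length(spo2_step_points) == 1L,
    spo2_step_points > 0
  )
  for (nm in names(range_limits)) {
    lim <- range_limits[[nm]]
    if (length(lim) != 2L || !is.numeric(lim) || lim[1] >= lim[2]) {
      rlang::abort(paste0("range limit for ", nm, " must be c(lower, upper) with lower < upper"))
    }
  }
  structure(
    list(
      deviation_fraction = deviation_fraction,
      confirmation_fraction = confirmation_fraction,
      spo2_step_points = spo2_step_points,
      range_limits = range_limits,
      deviation_semantics = deviation_semantics
    ),
    class = "wardmon_qc_rules"
  )
}

#' Default physiological range limits
#'
#' PR and SBP limits follow the published artifact criteria; the remaining
#' limits are broad package defaults, overridable in [qc_rules()] and echoed
#' in report metadata.
#' @return Named list of `c(lower, upper)` vectors.
#' @export
default_range_limits <- function() {
  list(
    PR = c(5, 250),
    SBP = c(20, 300),
    DBP = c(10, 200),
    MBP = c(10, 250),
    RR = c(0, 80),
    SPO2 = c(0, 100),
    TEMP = c(30, 45)
  )
}

#' Pairing configuration
#'
#' @param window_minutes Maximum interval between a nurse observation and a
#'   device record for the two to be compared; pairs further apart are not
#'   formed. Default 5 minutes.
#' @param selection `"nearest"` pairs each nurse reading with the device
#'   record minimizing the absolute time difference (ties broken toward the
#'   earlier record); `"first"` takes the earliest record in the window.
#' @return A list of class `wardmon_pairing_config`.
#' @export
pairing_config <- function(window_minutes = 5,
                           selection = c("nearest", "first")) {
  selection <- match.arg(selection)
  stopifnot(is.numeric(window_minutes), length(window_minutes) == 1L,
            window_minutes > 0)
  structure(
    list(window_minutes = window_minutes, selection = selection),
    class = "wardmon_pairing_config"
  )
}

#' Agreement (Bland-Altman) configuration
#'
#' @param loa_multiplier Multiplier on the total SD for the limits of
#'   agreement; 1.96 by convention.
#' @param bias_method `"all"` computes the bias as the mean of all paired
#'   differences; `"subject_means"` averages per-subject mean differences.
#' @return A list of class `wardmon_agreement_config`.
#' @export
agreement_config <- function(loa_multiplier = 1.96,
                             bias_method = c("all", "subject_means")) {
  bias_method <- match.arg(bias_method)
  stopifnot(is.numeric(loa_multiplier), length(loa_multiplier) == 1L,
            loa_multiplier > 0)
  structure(
    list(loa_multiplier = loa_multiplier, bias_method = bias_method),
    class = "wardmon_agreement_config"
  )
}

#' Default abnormality thresholds
#'
#' The 17 per-parameter abnormality cutoffs used for patient-level
#' concordance between the two monitoring sources. Strictness follows the
#' printed symbol: `<60` and `>20` are strict, `≤40` and `≥100`
#' are inclusive.
#'
#' @param min_consecutive Number of consecutive exceeding samples required
#'   before a patient counts as positive (default 1: any single exceedance).
#' @return A tibble with columns `parameter`, `direction` (`"below"` /
#'   `"above"`), `cutoff`, `inclusive`, `min_consecutive`, `label`.
#' @export
#' @examples
#' abnormality_thresholds()
abnormality_thresholds <- function(min_consecutive = 1L) {
  stopifnot(is.numeric(min_consecutive), min_consecutive >= 1)
  tb <- tibble::tribble(
    ~parameter, ~direction, ~cutoff, ~inclusive,
    "MBP",  "below",  60,   FALSE,
    "MBP",  "below",  65,   FALSE,
    "MBP",  "below",  70,   FALSE,
    "MBP",  "above", 100,   FALSE,
    "MBP",  "above", 110,   FALSE,
    "MBP",  "above", 120,   FALSE,
    "PR",   "below",  40,   TRUE,
    "PR",   "above", 100,   TRUE,
    "RR",   "below",   8,   FALSE,
    "RR",   "above",  20,   FALSE,
    "SPO2", "below",  95,   FALSE,
    "SPO2", "below",  92,   FALSE,
    "SPO2", "below",  90,   FALSE,
    "SPO2", "below",  85,   FALSE,
    "TEMP", "below",  36.8, FALSE,
    "TEMP", "above",  38,   FALSE,
    "TEMP", "above",  39,   FALSE
  )
  tb$min_consecutive <- as.integer(min_consecutive)
  tb$label <- paste0(
    tb$parameter, " ",
    ifelse(tb$direction == "below",
           ifelse(tb$inclusive, "≤", "<"),
           ifelse(tb$inclusive, "≥", ">")),
    tb$cutoff
  )
  tb
}

#' Write a configuration object to YAML
#'
#' Serializes [qc_rules()], [pairing_config()], [agreement_config()],
#' [synth_config()] or a threshold tibble so a run's exact settings can be
#' stored alongside its outputs.
#'
#' @param config The configuration object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(config, path) {
  x <- config
  if (inherits(x, "data.frame")) {
    x <- list(kind = "thresholds", rows = purrr::transpose(as.list(x)))
  } else {
    kind <- config_kind(config)
    x <- unclass(x)
    x <- purrr::map(x, function(v) {
      if (inherits(v, "POSIXct")) return(format(v, "%Y-%m-%dT%H:%M:%S"))
      # named atomic vectors must become maps, or yaml drops the names
      if (is.atomic(v) && !is.null(names(v))) return(as.list(v))
      v
    })
    if (!is.null(x$episode_spec) && inherits(config$episode_spec, "data.frame")) {
      x$episode_spec <- purrr::transpose(as.list(config$episode_spec))
    }
    x <- c(list(kind = kind), x)
  }
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a configuration object from YAML
#'
#' Reads a file written by [config_to_yaml()] and rebuilds the configuration
#' through its constructor, so invariants are re-validated.
#'
#' @param path YAML file written by [config_to_yaml()].
#' @return The configuration object.
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  kind <- x$kind
  x$kind <- NULL
  if (is.null(kind)) rlang::abort("YAML file does not carry a wardmon `kind` field")
  switch(
    kind,
    thresholds = dplyr::bind_rows(purrr::map(x$rows, tibble::as_tibble)),
    qc_rules = do.call(qc_rules, x),
    pairing = do.call(pairing_config, x),
    agreement = do.call(agreement_config, x),
    synth = {
      x$start_time <- as.POSIXct(x$start_time, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
      for (nm in c("baselines", "between_sd", "within_sd", "ar1", "dropout_fractions",
                   "artifact_rates", "nurse_noise")) {
        x[[nm]] <- unlist(x[[nm]])
      }
      x$episode_spec <- dplyr::bind_rows(purrr::map(x$episode_spec, tibble::as_tibble))
      do.call(synth_config, x)
    },
    rlang::abort(paste0("unknown configuration kind: ", kind))
  )
}

config_kind <- function(config) {
  if (inherits(config, "wardmon_qc_rules")) return("qc_rules")
  if (inherits(config, "wardmon_pairing_config")) return("pairing")
  if (inherits(config, "wardmon_agreement_config")) return("agreement")
  if (inherits(config, "wardmon_synth_config")) return("synth")
  rlang::abort("unsupported configuration object")
}
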