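#' Assemble a pipeline configuration
#'
#' Bundles every stage's settings into one serializable object; a run's
#' report embeds the resolved configuration and package version, so results
#' are reproducible from the report alone.
#'
#' @param synth A [synth_config()] (used when no input tables are given).
#' @param device,nurse,episodes Optional pre-loaded input tibbles; when all
#'   three are supplied the synthetic generator is skipped.
#' @param qc A [qc_rules()].
#' @param pairing A [pairing_config()].
#' @param agreement An [agreement_config()].
#' @param zones Named list of [clarke_zone_config()] objects.
#' @param thresholds Threshold tibble.
#' @return A list of class `wardmon_pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            device = NULL, nurse = NULL, episodes = NULL,
                            qc = qc_rules(),
                            pairing = pairing_config(),
                            agreement = agreement_config(),
                            zones = default_zone_configs(),
                            thresholds = abnormality_thresholds()) {
  structure(
    list(synth = synth, device = device, nurse = nurse, episodes = episodes,
         qc = qc, pairing = pairing, agreement = agreement,
         zones = zones, thresholds = thresholds),
    class = "wardmon_pipeline_config"
  )
}

#' Run the full monitoring-agreement pipeline
#'
#' Executes, in order: cohort input (synthetic generation or supplied
#' tables), artifact QC, completeness accounting, nurse-device pairing,
#' repeated-measures Bland-Altman and error-grid classification per
#' parameter, and per-threshold abnormality concordance. Deterministic
#' given the synthetic seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, intermediate tables
#'   (clean device CSV, flags CSV, pairs CSV, exclusions CSV) and the
#'   consolidated `report.json` are written there.
#' @return A list of class `wardmon_report` with elements `completeness`,
#'   `qc_summary`, `pair_counts`, `agreement`, `zones`, `concordance`,
#'   `config_echo`, plus the underlying objects under `objects`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "wardmon_pipeline_config"))
  have_inputs <- !is.null(config$device) && !is.null(config$nurse) &&
    !is.null(config$episodes)
  if (have_inputs) {
    device <- config$device
    nurse <- config$nurse
    episodes <- config$episodes
    truth <- NULL
  } else {
    cohort <- generate_cohort(config$synth, thresholds = config$thresholds,
                              rules = config$qc)
    device <- cohort$device
    nurse <- cohort$nurse
    episodes <- cohort$episodes
    truth <- cohort$truth
  }
  qc <- apply_qc(device, config$qc)
  comp <- completeness(device, episodes, config$synth$slot_minutes %||% 5)
  pairs <- match_pairs(nurse, qc$clean, config$pairing, flags = qc$flags)
  agree <- agreement_summaries(pairs, config$agreement)
  zone_summaries <- purrr::map(config$zones, function(z) classify_clarke(pairs, z))
  conc <- concordance_suite(qc$clean, nurse, config$thresholds)
  report <- structure(
    list(
      completeness = comp,
      qc_summary = qc$summary,
      pair_counts = pair_counts(pairs),
      agreement = agree,
      zones = purrr::map(zone_summaries, "summary"),
      concordance = conc,
      config_echo = config_echo(config),
      objects = list(device = device, nurse = nurse, episodes = episodes,
                     qc = qc, pairs = pairs, zone_details = zone_summaries,
                     truth = truth)
    ),
    class = "wardmon_report"
  )
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

config_echo <- function(config) {
  list(
    package_version = as.character(utils::packageVersion("wardmon")),
    qc = unclass(config$qc),
    pairing = unclass(config$pairing),
    agreement = unclass(config$agreement),
    thresholds = config$thresholds$label,
    zone_geometries = purrr::map(config$zones, function(z) z$geometry),
    synth_seed = config$synth$seed %||% NA_integer_
  )
}

write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- report$objects
  write_vitals_table(obj$qc$clean, file.path(out_dir, "device_clean.csv"))
  write_vitals_table(obj$qc$flags, file.path(out_dir, "flags.csv"))
  write_vitals_table(obj$pairs$pairs, file.path(out_dir, "pairs.csv"))
  write_vitals_table(obj$pairs$exclusions, file.path(out_dir, "exclusions.csv"))
  jsonlite::write_json(report_json(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(render_report(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

report_json <- function(report) {
  comp <- report$completeness
  list(
    completeness = list(
      expected_slots = comp$expected_slots,
      obtained_slots = comp$obtained_slots,
      missing_slots = comp$missing_slots,
      missing_percent = round(100 * comp$missing_fraction, 1),
      complete_records = comp$complete_records,
      per_parameter = comp$per_parameter
    ),
    artifacts = report$qc_summary,
    pair_counts = as.list(report$pair_counts),
    agreement = report$agreement,
    zones = report$zones,
    concordance = report$concordance,
    config = report$config_echo
  )
}

#' Render a report as markdown
#'
#' Tables mirror the study-report shapes: completeness accounting,
#' per-parameter artifact tallies, pair counts, Bland-Altman summaries,
#' error-grid zone proportions, and the per-threshold concordance table
#' with kappa \[95% CI\] at 2 decimals and p-values at 3 decimals
#' (`<0.001` below 0.0005).
#'
#' @param report A `wardmon_report`.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "wardmon_report"))
  comp <- report$completeness
  out <- c(
    "# Ward monitoring agreement report",
    "",
    "## Data completeness",
    sprintf("- expected slots: %d", comp$expected_slots),
    sprintf("- obtained slots: %d", comp$obtained_slots),
    sprintf("- missing slots: %d (%s%%)", comp$missing_slots,
            fmt_num(100 * comp$missing_fraction, 1)),
    sprintf("- complete records (all five parameters): %d", comp$complete_records),
    "",
    "| parameter | absent among obtained | % |",
    "|---|---|---|",
    sprintf("| %s | %d | %s |", comp$per_parameter$parameter,
            comp$per_parameter$n_absent,
            fmt_num(100 * comp$per_parameter$absent_fraction, 1)),
    "",
    "## Artifacts (numerical criteria)",
    "| parameter | obtained | range | deviation | SpO2 step | flagged | % |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %d | %d | %d | %s |",
            report$qc_summary$parameter, report$qc_summary$n_obtained,
            report$qc_summary$n_range, report$qc_summary$n_deviation,
            report$qc_summary$n_spo2_step, report$qc_summary$n_flagged_values,
            fmt_num(100 * report$qc_summary$flag_rate, 2)),
    "",
    "## Nurse-device pairs",
    paste0("- ", paste(sprintf("%s: %d", names(report$pair_counts),
                               report$pair_counts), collapse = ", ")),
    ""
  )
  if (nrow(report$agreement %||% tibble::tibble())) {
    ag <- report$agreement
    out <- c(out,
      "## Bland-Altman (device - nurse)",
      "| parameter | pairs | subjects | bias | total SD | LoA lower | LoA upper |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %d | %d | %s | %s | %s | %s |",
              ag$parameter, ag$n_pairs, ag$n_subjects,
              fmt_num(ag$bias, 2), fmt_num(ag$total_sd, 2),
              fmt_num(ag$loa_lower, 2), fmt_num(ag$loa_upper, 2)),
      "")
  }
  out <- c(out, "## Error-grid zones")
  for (p in names(report$zones)) {
    zs <- report$zones[[p]]
    out <- c(out, sprintf("- %s: %s", p,
                          paste(sprintf("%s %s%%", zs$zone,
                                        fmt_num(100 * zs$proportion, 1)),
                                collapse = ", ")))
  }
  conc <- report$concordance
  out <- c(out, "",
    "## Abnormality concordance",
    "| threshold | agreement | nurse-only | device-only | kappa [95% CI] | McNemar p |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %d (%s%%) | %d (%s%%) | %d (%s%%) | %s | %s |",
            conc$label,
            conc$a + conc$d, fmt_num(100 * conc$agreement_fraction, 1),
            conc$b, fmt_num(100 * conc$b / conc$n, 1),
            conc$c, fmt_num(100 * conc$c / conc$n, 1),
            format_kappa(conc$kappa, conc$kappa_ci_lower, conc$kappa_ci_upper),
            format_pvalue(conc$mcnemar_p))
  )
  out
}

#' Format a p-value for reports
#'
#' Three decimals; values below 0.0005 render `"<0.001"`.
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
#' @examples
#' format_pvalue(0.0703)  # "0.070"
format_pvalue <- function(p) {
  ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p))
}

#' Format kappa with its interval at two decimals
#' @param kappa,lower,upper Numeric vectors.
#' @return Character vector like `"0.30 [-0.04; 0.64]"`.
#' @export
format_kappa <- function(kappa, lower, upper) {
  ifelse(is.na(kappa), "-",
         sprintf("%.2f [%.2f; %.2f]", kappa, lower, upper))
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "-", sprintf(paste0("%.", digits, "f"), x))
}
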