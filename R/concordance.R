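#' Does a patient's series cross an abnormality threshold?
#'
#' `TRUE` when at least `min_consecutive` consecutive obtained values
#' satisfy the directional comparison. Strictness follows the threshold's
#' `inclusive` field: `<60` is strict, `≤40` and `≥100` are inclusive, as
#' printed in the clinical cutoff list. An empty series (or all-missing)
#' returns `FALSE`.
#'
#' @param values Numeric vector (missing values are skipped over; runs are
#'   counted on the obtained subsequence).
#' @param threshold One row of [abnormality_thresholds()] (or a list with
#'   fields `direction`, `cutoff`, `inclusive`, `min_consecutive`).
#' @return Logical scalar.
#' @export
#' @examples
#' th <- abnormality_thresholds()
#' detect_abnormal(c(72, 58, 75), th[th$label == "MBP <60", ])  # TRUE
#' detect_abnormal(c(60, 60), th[th$label == "MBP <60", ])      # FALSE
detect_abnormal <- function(values, threshold) {
  v <- values[!is.na(values)]
  if (!length(v)) return(FALSE)
  hit <- switch(
    threshold$direction,
    below = if (threshold$inclusive) v <= threshold$cutoff else v < threshold$cutoff,
    above = if (threshold$inclusive) v >= threshold$cutoff else v > threshold$cutoff,
    rlang::abort("threshold direction must be 'below' or 'above'")
  )
  need <- max(1L, as.integer(threshold$min_consecutive %||% 1L))
  if (need == 1L) return(any(hit))
  r <- rle(hit)
  any(r$values & r$lengths >= need)
}

#' Build a per-threshold 2x2 concordance table
#'
#' Cross-classifies patients by nurse-detected and device-detected
#' abnormality. Patients with a missing flag in either source (no analyzed
#' value for the parameter) are excluded and counted.
#'
#' @param nurse_flags,device_flags Named logical vectors over the same
#'   patient set (`NA` = parameter unavailable for that patient).
#' @param label Optional threshold label carried into the table.
#' @return A list of class `wardmon_2x2`: `a` (both positive), `b`
#'   (nurse-only), `c` (device-only), `d` (both negative), `n`,
#'   `n_excluded`, `label`.
#' @export
build_table <- function(nurse_flags, device_flags, label = NULL) {
  if (!setequal(names(nurse_flags), names(device_flags))) {
    extra_n <- setdiff(names(nurse_flags), names(device_flags))
    extra_d <- setdiff(names(device_flags), names(nurse_flags))
    rlang::abort(paste0(
      "patient sets differ; only in nurse: {", paste(extra_n, collapse = ", "),
      "}, only in device: {", paste(extra_d, collapse = ", "), "}"
    ))
  }
  device_flags <- device_flags[names(nurse_flags)]
  ok <- !is.na(nurse_flags) & !is.na(device_flags)
  nf <- nurse_flags[ok]
  df <- device_flags[ok]
  two_by_two(
    a = sum(nf & df), b = sum(nf & !df),
    c = sum(!nf & df), d = sum(!nf & !df),
    n_excluded = sum(!ok), label = label
  )
}

#' Construct a 2x2 table from counts
#'
#' @param a Both-positive count; `b` nurse-positive/device-negative;
#'   `c` nurse-negative/device-positive; `d` both-negative.
#' @param b,c,d See `a`.
#' @param n_excluded Patients excluded for missing data.
#' @param label Optional threshold label.
#' @return A list of class `wardmon_2x2`.
#' @export
#' @examples
#' two_by_two(2, 1, 7, 80)
two_by_two <- function(a, b, c, d, n_excluded = 0L, label = NULL) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(
    list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
         d = as.integer(d), n = as.integer(a + b + c + d),
         n_excluded = as.integer(n_excluded), label = label),
    class = "wardmon_2x2"
  )
}

#' Cohen's kappa with an asymptotic 95% confidence interval
#'
#' Chance-corrected agreement for a 2x2 patient classification:
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with \eqn{p_o = (a+d)/n} and
#' \eqn{p_e} from the marginals. The interval is \eqn{\kappa \pm 1.96\,SE}
#' with the Fleiss-Cohen-Everitt asymptotic standard error. In the
#' degenerate single-category case (\eqn{p_e = 1}) kappa is defined as 1
#' when \eqn{p_o = 1}.
#'
#' @param table A `wardmon_2x2` (see [two_by_two()]).
#' @return A list: `kappa`, `se`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' cohen_kappa(two_by_two(2, 1, 7, 80))$kappa  # 0.298
cohen_kappa <- function(table) {
  stopifnot(inherits(table, "wardmon_2x2"))
  n <- table$n
  if (n == 0) rlang::abort("empty table")
  p <- matrix(c(table$a, table$b, table$c, table$d), 2, byrow = TRUE) / n
  po <- sum(diag(p))
  pr <- rowSums(p)
  pc <- colSums(p)
  pe <- sum(pr * pc)
  if (pe >= 1) {
    k <- if (po >= 1) 1 else NA_real_
    return(list(kappa = k, se = 0, ci_lower = k, ci_upper = k))
  }
  k <- (po - pe) / (1 - pe)
  t1 <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  t2 <- (1 - k)^2 * (p[1, 2] * (pc[1] + pr[2])^2 + p[2, 1] * (pc[2] + pr[1])^2)
  t3 <- (k - pe * (1 - k))^2
  se <- sqrt(max(0, t1 + t2 - t3) / (n * (1 - pe)^2))
  list(kappa = k, se = se,
       ci_lower = k - 1.96 * se, ci_upper = k + 1.96 * se)
}

#' McNemar's test with the exact / continuity-corrected rule
#'
#' Tests whether discordant classifications favor one monitoring source.
#' With fewer than 10 discordant pairs the exact binomial version is used:
#' \eqn{p = \min\{1, 2 P(X \le \min(b, c))\}} for
#' \eqn{X \sim Bin(b + c, 1/2)} (and \eqn{p = 1} when \eqn{b + c = 0});
#' otherwise the continuity-corrected chi-square
#' \eqn{(|b - c| - 1)^2 / (b + c)} on 1 degree of freedom.
#'
#' @param table A `wardmon_2x2` (see [two_by_two()]).
#' @return A list: `p_value`, `method` (`"exact"` or
#'   `"continuity_corrected"`), `statistic` (chi-square, or `NA` for the
#'   exact test), `n_discordant`.
#' @export
#' @examples
#' mcnemar_test(two_by_two(82, 1, 7, 0))$p_value  # 0.0703125
mcnemar_test <- function(table) {
  stopifnot(inherits(table, "wardmon_2x2"))
  b <- table$b
  c <- table$c
  nd <- b + c
  if (nd < 10) {
    p <- if (nd == 0) 1 else min(1, 2 * stats::pbinom(min(b, c), nd, 0.5))
    list(p_value = p, method = "exact", statistic = NA_real_, n_discordant = nd)
  } else {
    stat <- (abs(b - c) - 1)^2 / nd
    list(p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = "continuity_corrected", statistic = stat, n_discordant = nd)
  }
}

#' Per-patient detection flags for one source
#'
#' @param data Device (clean) or nurse tibble.
#' @param threshold One row of [abnormality_thresholds()].
#' @param patients Patient universe; patients absent from `data`, or with
#'   no obtained value of the parameter, get `NA`.
#' @return Named logical vector over `patients`.
#' @export
patient_flags <- function(data, threshold, patients = sort(unique(data$patient_id))) {
  p <- threshold$parameter
  out <- stats::setNames(rep(NA, length(patients)), patients)
  if (!p %in% names(data)) return(out)
  for (pid in patients) {
    v <- data[[p]][data$patient_id == pid]
    v <- v[!is.na(v)]
    if (length(v)) out[[pid]] <- detect_abnormal(v, threshold)
  }
  out
}

#' Full per-threshold concordance analysis
#'
#' Runs abnormality detection for both sources at every threshold, builds
#' the 2x2 tables and computes Cohen's kappa and the McNemar p-value under
#' the exact / continuity-corrected rule.
#'
#' @param device Clean device tibble (artifact-filtered).
#' @param nurse Nurse observation tibble.
#' @param thresholds Threshold tibble, default [abnormality_thresholds()].
#' @return A tibble with one row per threshold: counts `a`, `b`, `c`, `d`,
#'   `n`, `n_excluded`, `agreement_fraction`, `kappa`, `kappa_ci_lower`,
#'   `kappa_ci_upper`, `mcnemar_p`, `mcnemar_method`.
#' @export
concordance_suite <- function(device, nurse, thresholds = abnormality_thresholds()) {
  patients <- sort(union(unique(device$patient_id), unique(nurse$patient_id)))
  if (!length(patients)) rlang::abort("empty cohort")
  purrr::map_dfr(seq_len(nrow(thresholds)), function(j) {
    th <- thresholds[j, ]
    nf <- patient_flags(nurse, th, patients)
    df <- patient_flags(device, th, patients)
    tab <- build_table(nf, df, label = th$label)
    kp <- cohen_kappa(tab)
    mc <- mcnemar_test(tab)
    tibble::tibble(
      label = th$label, parameter = th$parameter,
      a = tab$a, b = tab$b, c = tab$c, d = tab$d, n = tab$n,
      n_excluded = tab$n_excluded,
      agreement_fraction = (tab$a + tab$d) / tab$n,
      kappa = kp$kappa, kappa_ci_lower = kp$ci_lower,
      kappa_ci_upper = kp$ci_upper,
      mcnemar_p = mc$p_value, mcnemar_method = mc$method
    )
  })
}
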