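#' Repeated-measures Bland-Altman limits of agreement
#'
#' Agreement between two measurement methods when subjects contribute
#' multiple paired readings. The bias is the mean paired difference
#' (device - nurse). The SD entering the limits of agreement combines
#' within- and between-subject variance components from a one-way analysis
#' of variance of the differences by subject, with the unbalanced-design
#' correction:
#' \deqn{s^2_w = MSW, \quad s^2_b = \max\{0, (MSB - MSW)/n_0\},}
#' \deqn{n_0 = \frac{N - \sum_i m_i^2/N}{k - 1},}
#' where \eqn{m_i} is subject \eqn{i}'s number of pairs, \eqn{N = \sum m_i}
#' and \eqn{k} the number of subjects. The limits are
#' \eqn{bias \pm multiplier \sqrt{s^2_w + s^2_b}}.
#'
#' When every subject contributes exactly one pair the within mean square
#' is undefined and the method degenerates, by design, to the classic
#' single-measurement Bland-Altman (total SD = sample SD of differences).
#'
#' @param device,nurse Numeric vectors of paired measurements.
#' @param subject Subject (patient) identifier per pair.
#' @param config An [agreement_config()].
#' @return A one-row tibble: `n_pairs`, `n_subjects`, `bias`,
#'   `within_subject_variance`, `between_subject_variance`, `total_sd`,
#'   `loa_lower`, `loa_upper`, `method` (`"repeated"` or `"classic"`).
#' @export
#' @examples
#' bland_altman_repeated(c(1, -1, 0, 2, -2), rep(0, 5), subject = 1:5)
bland_altman_repeated <- function(device, nurse, subject,
                                  config = agreement_config()) {
  stopifnot(length(device) == length(nurse), length(device) == length(subject))
  ok <- !is.na(device) & !is.na(nurse) & !is.na(subject)
  d <- device[ok] - nurse[ok]
  g <- factor(subject[ok])
  N <- length(d)
  k <- nlevels(g)
  if (k < 2L) rlang::abort("repeated-measures Bland-Altman needs at least 2 subjects")
  m <- as.numeric(table(g))
  bias <- if (config$bias_method == "all") mean(d) else
    mean(tapply(d, g, mean))
  if (all(m == 1)) {
    total_sd <- stats::sd(d)
    within <- NA_real_
    between <- NA_real_
    method <- "classic"
  } else {
    gm <- tapply(d, g, mean)
    ssb <- sum(m * (gm - mean(d))^2)
    ssw <- sum((d - gm[g])^2)
    msb <- ssb / (k - 1)
    msw <- ssw / (N - k)
    n0 <- (N - sum(m^2) / N) / (k - 1)
    within <- msw
    between <- max(0, (msb - msw) / n0)
    total_sd <- sqrt(within + between)
    method <- "repeated"
  }
  tibble::tibble(
    n_pairs = N, n_subjects = k, bias = bias,
    within_subject_variance = within,
    between_subject_variance = between,
    total_sd = total_sd,
    loa_lower = bias - config$loa_multiplier * total_sd,
    loa_upper = bias + config$loa_multiplier * total_sd,
    method = method
  )
}

#' Bland-Altman summaries for every parameter in a pair set
#'
#' @param pairs A `wardmon_pairs` object or its `pairs` tibble.
#' @param config An [agreement_config()].
#' @return A tibble with one row per parameter having at least two subjects.
#' @export
agreement_summaries <- function(pairs, config = agreement_config()) {
  if (inherits(pairs, "wardmon_pairs")) pairs <- pairs$pairs
  purrr::map_dfr(unique(pairs$parameter), function(p) {
    sub <- pairs[pairs$parameter == p, ]
    if (length(unique(sub$patient_id)) < 2L) return(NULL)
    out <- bland_altman_repeated(sub$device_value, sub$nurse_value,
                                 sub$patient_id, config)
    dplyr::bind_cols(tibble::tibble(parameter = p), out)
  })
}
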