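#' Bland-Altman scatter for one parameter
#'
#' Differences (device - nurse) against pair means, with the bias and
#' limits of agreement from [bland_altman_repeated()].
#'
#' @param pairs A `wardmon_pairs` object or its `pairs` tibble.
#' @param parameter Parameter to plot.
#' @param config An [agreement_config()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, parameter, config = agreement_config()) {
  if (inherits(pairs, "wardmon_pairs")) pairs <- pairs$pairs
  sub <- pairs[pairs$parameter == parameter, ]
  if (!nrow(sub)) rlang::abort(paste0("no pairs for ", parameter))
  ba <- bland_altman_repeated(sub$device_value, sub$nurse_value,
                              sub$patient_id, config)
  df <- tibble::tibble(
    mean = (sub$device_value + sub$nurse_value) / 2,
    diff = sub$device_value - sub$nurse_value
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = paste0("Mean of device and nurse ", parameter),
      y = "Device - nurse",
      title = sprintf("%s: bias %.2f, LoA [%.2f, %.2f]", parameter,
                      ba$bias, ba$loa_lower, ba$loa_upper)
    ) +
    ggplot2::theme_minimal()
}

#' Error-grid scatter for one parameter
#'
#' Device measurements against nurse references, colored by assigned zone,
#' with the identity line.
#'
#' @param pairs A `wardmon_pairs` object or its `pairs` tibble.
#' @param zones A [clarke_zone_config()].
#' @return A ggplot object.
#' @export
plot_clarke <- function(pairs, zones) {
  cz <- classify_clarke(pairs, zones)
  df <- cz$labels
  if (!nrow(df)) rlang::abort(paste0("no pairs for ", zones$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nurse_value, y = .data$device_value,
                                   color = .data$zone)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = zones$domain, ylim = zones$domain) +
    ggplot2::labs(x = paste0("Nurse ", zones$parameter),
                  y = paste0("Device ", zones$parameter),
                  title = paste0("Error grid: ", zones$parameter)) +
    ggplot2::theme_minimal()
}
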