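#' Build a Clarke-style error-grid zone configuration
#'
#' Adapts the Clarke Error Grid — originally defined for self-monitored
#' blood glucose — to an arbitrary vital sign. The geometry is declarative:
#' an A band around the identity line (within `tol_rel` relative or
#' `tol_abs` absolute error, whichever is larger), a clinically normal band
#' `norm = c(lo, hi)` and critical boundaries `crit = c(lo, hi)` define the
#' risk zones,
#' \describe{
#'   \item{A}{acceptable agreement, `|measured - reference| <= max(tol_rel *
#'     reference, tol_abs)`; the identity line always lies in A.}
#'   \item{E}{opposite critical extremes (reference critically low while
#'     measured critically high, or vice versa).}
#'   \item{D}{dangerous miss: reference critical, measured in the normal
#'     band.}
#'   \item{C}{overcorrection risk: reference normal, measured critical.}
#'   \item{B}{all remaining (clinically benign) disagreement.}
#' }
#' Zone regions are closed; a point on a shared boundary is assigned the
#' more benign zone (A > B > C > D > E). Use `crit = c(lo, Inf)` for a
#' parameter with no critical upper end (such as SpO2); zone E is then
#' empty and the remaining zones still partition the domain.
#'
#' @param parameter Parameter name.
#' @param domain `c(lo, hi)` plausible-value rectangle for both axes.
#' @param tol_rel,tol_abs Relative and absolute half-width of zone A.
#' @param norm `c(lo, hi)` clinically normal band.
#' @param crit `c(lo, hi)` critical boundaries; must satisfy
#'   `crit[1] < norm[1] <= norm[2] < crit[2]`.
#' @param zones Optional custom zone list (each element
#'   `list(label =, contains = function(reference, measured))`), overriding
#'   the parametric geometry; labels must come from A-E.
#' @return A list of class `wardmon_clarke_zones`.
#' @export
clarke_zone_config <- function(parameter, domain, tol_rel = 0.1, tol_abs,
                               norm, crit, zones = NULL) {
  assert_parameter(parameter)
  stopifnot(length(domain) == 2L, domain[1] < domain[2])
  if (is.null(zones)) {
    stopifnot(
      length(norm) == 2L, length(crit) == 2L,
      crit[1] < norm[1], norm[1] <= norm[2], norm[2] < crit[2],
      tol_rel >= 0, tol_abs >= 0, tol_rel + tol_abs > 0
    )
    tol <- function(r) pmax(tol_rel * r, tol_abs)
    in_a <- function(r, m) abs(m - r) <= tol(r)
    in_e <- function(r, m) (r <= crit[1] & m >= crit[2]) | (r >= crit[2] & m <= crit[1])
    in_d <- function(r, m) (r <= crit[1] | r >= crit[2]) & (m >= norm[1] & m <= norm[2])
    in_c <- function(r, m) (r >= norm[1] & r <= norm[2]) & (m <= crit[1] | m >= crit[2])
    strict_a <- function(r, m) abs(m - r) < tol(r)
    strict_e <- function(r, m) (r < crit[1] & m > crit[2]) | (r > crit[2] & m < crit[1])
    strict_d <- function(r, m) (r < crit[1] | r > crit[2]) & (m > norm[1] & m < norm[2])
    strict_c <- function(r, m) (r > norm[1] & r < norm[2]) & (m < crit[1] | m > crit[2])
    in_b <- function(r, m) !(strict_a(r, m) | strict_c(r, m) | strict_d(r, m) | strict_e(r, m))
    zones <- list(
      list(label = "A", contains = in_a),
      list(label = "B", contains = in_b),
      list(label = "C", contains = in_c),
      list(label = "D", contains = in_d),
      list(label = "E", contains = in_e)
    )
  } else {
    labs <- purrr::map_chr(zones, "label")
    if (!all(labs %in% c("A", "B", "C", "D", "E"))) {
      rlang::abort("zone labels must come from A-E")
    }
  }
  # benign-first evaluation order implements the boundary tie-break (A > B > ... > E)
  zones <- zones[order(match(purrr::map_chr(zones, "label"), c("A", "B", "C", "D", "E")))]
  structure(
    list(parameter = parameter, domain = domain, zones = zones,
         geometry = if (missing(norm)) NULL else
           list(tol_rel = tol_rel, tol_abs = tol_abs, norm = norm, crit = crit)),
    class = "wardmon_clarke_zones"
  )
}

#' Default error-grid geometries for the five analyzed parameters
#'
#' Provisional package defaults (the zone boundaries of published
#' vital-sign error grids vary by study and are a clinical judgment); every
#' report embeds the geometry actually used.
#' @return Named list of [clarke_zone_config()] objects.
#' @export
default_zone_configs <- function() {
  list(
    MBP = clarke_zone_config("MBP", domain = c(20, 160), tol_rel = 0.1,
                             tol_abs = 5, norm = c(65, 110), crit = c(55, 130)),
    PR = clarke_zone_config("PR", domain = c(20, 200), tol_rel = 0.1,
                            tol_abs = 5, norm = c(50, 110), crit = c(40, 135)),
    RR = clarke_zone_config("RR", domain = c(2, 50), tol_rel = 0.1,
                            tol_abs = 2, norm = c(8, 20), crit = c(6, 28)),
    SPO2 = clarke_zone_config("SPO2", domain = c(70, 100), tol_rel = 0,
                              tol_abs = 3, norm = c(92, 100), crit = c(88, Inf)),
    TEMP = clarke_zone_config("TEMP", domain = c(34, 41), tol_rel = 0,
                              tol_abs = 0.4, norm = c(36, 38.5), crit = c(35.2, 39.5))
  )
}

classify_point <- function(zones, r, m) {
  for (z in zones$zones) {
    if (isTRUE(z$contains(r, m))) return(z$label)
  }
  NA_character_
}

#' Classify paired readings on the error grid
#'
#' Each (nurse reference, device measurement) pair is assigned the most
#' benign zone whose closed region contains it. Pairs outside the domain
#' rectangle are classified with the same predicates (clamped into the
#' domain if no zone matches) and counted in `n_outside_domain`.
#'
#' @param pairs A `wardmon_pairs` object or its `pairs` tibble (single
#'   parameter, or the zone config's parameter is used to filter).
#' @param zones A [clarke_zone_config()].
#' @return A list of class `wardmon_zone_summary`: `labels` (per-pair zone
#'   tibble), `summary` (counts and proportions per zone A-E),
#'   `n_outside_domain`, `zones`.
#' @export
classify_clarke <- function(pairs, zones) {
  stopifnot(inherits(zones, "wardmon_clarke_zones"))
  if (inherits(pairs, "wardmon_pairs")) pairs <- pairs$pairs
  if ("parameter" %in% names(pairs)) {
    pairs <- pairs[pairs$parameter == zones$parameter, , drop = FALSE]
  }
  dom <- zones$domain
  n <- nrow(pairs)
  lab <- character(n)
  outside <- logical(n)
  for (i in seq_len(n)) {
    r <- pairs$nurse_value[i]
    m <- pairs$device_value[i]
    outside[i] <- r < dom[1] || r > dom[2] || m < dom[1] || m > dom[2]
    z <- classify_point(zones, r, m)
    if (is.na(z)) {
      z <- classify_point(zones, min(max(r, dom[1]), dom[2]),
                          min(max(m, dom[1]), dom[2]))
    }
    lab[i] <- z
  }
  labels <- dplyr::bind_cols(pairs, tibble::tibble(zone = lab))
  counts <- table(factor(lab, levels = c("A", "B", "C", "D", "E")))
  n_total <- length(lab)
  summary <- tibble::tibble(
    zone = names(counts),
    n = as.integer(counts),
    proportion = if (n_total > 0) as.integer(counts) / n_total else NA_real_
  )
  structure(
    list(labels = labels, summary = summary,
         n_outside_domain = sum(outside), zones = zones),
    class = "wardmon_zone_summary"
  )
}

#' Validate an error-grid zone configuration
#'
#' Probes a regular lattice over the domain rectangle and checks that the
#' closed zone regions cover it with no gap, that overlaps occur only on
#' shared boundaries (a point interior to two zones — still inside both
#' after small perturbations — is a genuine overlap and an error, reported
#' with a witness point), and that the identity line lies wholly in zone A.
#'
#' @param zones A [clarke_zone_config()].
#' @param n Lattice points per axis (default 100, i.e. a 10^4-point probe).
#' @return A list: `valid = TRUE`, `area_share` (fraction of probe points
#'   per assigned zone), `n_probe`. Errors describe the defect and a
#'   witness point.
#' @export
validate_zone_config <- function(zones, n = 100) {
  stopifnot(inherits(zones, "wardmon_clarke_zones"))
  dom <- zones$domain
  g <- seq(dom[1], dom[2], length.out = n)
  h <- (dom[2] - dom[1]) / (n - 1) / 4
  labs <- purrr::map_chr(zones$zones, "label")
  assigned <- character(n * n)
  idx <- 0L
  for (r in g) {
    for (m in g) {
      idx <- idx + 1L
      member <- purrr::map_lgl(zones$zones, function(z) isTRUE(z$contains(r, m)))
      if (!any(member)) {
        rlang::abort(sprintf(
          "zone gap: point (reference = %.4g, measured = %.4g) lies in no zone", r, m))
      }
      if (sum(member) > 1L) {
        # tolerate boundary contact; flag interior overlap
        hit <- which(member)
        interior <- purrr::map_lgl(hit, function(j) {
          all(purrr::map_lgl(list(c(h, h), c(h, -h), c(-h, h), c(-h, -h)), function(d) {
            isTRUE(zones$zones[[j]]$contains(r + d[1], m + d[2]))
          }))
        })
        if (sum(interior) > 1L) {
          rlang::abort(sprintf(
            "zone overlap between %s at (reference = %.4g, measured = %.4g)",
            paste(labs[hit[interior]], collapse = " and "), r, m))
        }
      }
      assigned[idx] <- labs[which(member)[1]]
    }
  }
  on_identity <- purrr::map_chr(g, function(x) classify_point(zones, x, x))
  if (any(on_identity != "A")) {
    bad <- g[which(on_identity != "A")[1]]
    rlang::abort(sprintf("identity line leaves zone A at reference = %.4g", bad))
  }
  share <- table(factor(assigned, levels = c("A", "B", "C", "D", "E"))) / (n * n)
  list(valid = TRUE, area_share = as.numeric(share),
       zone = names(share), n_probe = n * n)
}
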