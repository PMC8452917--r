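# FFR extraction at measurement sites, diameter-stenosis grading, and
# ischemia classification at the 0.80 threshold.

#' Compute the simulated FFR at a measurement site
#'
#' FFR is the ratio of the local pressure, interpolated linearly between
#' centerline samples, to the (hyperemic) inlet pressure of the
#' simulation. Values exceeding 1 by more than 1e-6 are clipped with a
#' warning.
#'
#' @param solution A converged `flow_solution`.
#' @param inlet_pressure Inlet static pressure used in the solve (mmHg).
#' @param site A [measurement_site()].
#' @param phase Optional phase tag, `"pre"` or `"post"`.
#' @param threshold Ischemia threshold applied to the result.
#' @return An object of class `ffr_result` with fields `site`, `ffrb`,
#'   `phase` and `ischemic`.
#' @export
compute_ffrb <- function(solution, inlet_pressure, site,
                         phase = NA_character_, threshold = 0.80) {
  if (!inherits(solution, "flow_solution") || !isTRUE(solution$converged))
    stop_coroflow("state_error", "solution is not a converged flow_solution")
  sp <- solution$sample_pressures
  rows <- sp[sp$branch_id == site$branch_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_coroflow("lookup_error", "branch '%s' not in solution", site$branch_id)
  if (site$s < min(rows$s) - 1e-9 || site$s > max(rows$s) + 1e-9)
    stop_coroflow("lookup_error",
                  "site s = %.2f off branch '%s'", site$s, site$branch_id)
  p <- stats::approx(rows$s, rows$pressure, xout = site$s, rule = 2)$y
  ffrb <- p / inlet_pressure
  if (ffrb > 1 + 1e-6) {
    warning(sprintf("FFR %.6f exceeds 1; clipping", ffrb))
    ffrb <- 1
  }
  ffrb <- min(ffrb, 1)
  structure(list(site = site, ffrb = ffrb, phase = phase,
                 ischemic = classify_ischemia(ffrb, threshold)),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("<ffr_result> FFR = %.3f at %s @ %.1f mm (%s)\n",
              x$ffrb, x$site$branch_id, x$site$s,
              if (x$ischemic) "ischemic" else "non-ischemic"))
  invisible(x)
}

#' Classify ischemia from an FFR value
#'
#' An FFR at or below the threshold (default 0.80, inclusive) indicates a
#' hemodynamically significant lesion.
#'
#' @param ffr FFR value(s) in (0, 1.05].
#' @param threshold Ischemia threshold.
#' @return Logical vector, `TRUE` for ischemic.
#' @export
classify_ischemia <- function(ffr, threshold = 0.80) {
  if (any(!is.finite(ffr)) || any(ffr <= 0) || any(ffr > 1.05))
    stop_coroflow("domain_error", "ffr must be in (0, 1.05]")
  ffr <= threshold
}

#' Grade percent diameter stenosis in an arc range
#'
#' Finds the minimal-lumen point in the range, takes the proximal and
#' distal shoulders from the lumen-area curve (as in [auto_size_stent()]),
#' interpolates the reference diameter linearly between the shoulder
#' diameters at the throat, and reports
#' `%DS = (1 - d_min / d_ref) * 100`.
#'
#' @param tree A `coronary_tree`.
#' @param branch_id Branch to grade.
#' @param s_range Length-2 numeric arc range (mm).
#' @return A list with `percent_ds` and a [lesion_record()].
#' @export
diameter_stenosis <- function(tree, branch_id, s_range) {
  b <- tree_branch(tree, branch_id)
  s <- b$samples$s
  area <- pi * b$samples$r^2
  iw <- which(s >= s_range[1] - 1e-9 & s <= s_range[2] + 1e-9)
  mk <- find_lesion_markers(s, area, iw)
  d_min <- 2 * b$samples$r[mk$i_s]
  d_p <- 2 * stats::approx(s, b$samples$r, xout = mk$s_p, rule = 2)$y
  d_d <- 2 * stats::approx(s, b$samples$r, xout = mk$s_d, rule = 2)$y
  d_ref <- stats::approx(c(mk$s_p, mk$s_d), c(d_p, d_d),
                         xout = s[mk$i_s])$y
  pct <- (1 - d_min / d_ref) * 100
  rec <- lesion_record(branch_id, s_range = c(mk$s_p, mk$s_d),
                       min_diameter = d_min, reference_diameter = d_ref,
                       percent_ds = max(pct, 0))
  list(percent_ds = pct, lesion = rec)
}
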