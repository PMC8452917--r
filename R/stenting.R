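# Virtual stent deployment on centerline geometry, automatic stent sizing
# from the lumen-area curve, and lesion classification.

#' Describe a stent
#'
#' @param branch_id Branch carrying the stent.
#' @param s_proximal Proximal landing position P* (mm).
#' @param s_distal Distal landing position D* (mm), beyond `s_proximal`.
#' @param diameter Deployed stent diameter (mm).
#' @param name Optional device name, carried as metadata only.
#' @return An object of class `stent_spec`; `length` is
#'   `s_distal - s_proximal`.
#' @export
stent_spec <- function(branch_id, s_proximal, s_distal, diameter,
                       name = NULL) {
  if (!is.finite(s_proximal) || !is.finite(s_distal) ||
      s_distal <= s_proximal)
    stop_coroflow("geometry_error", "require s_distal > s_proximal")
  if (!is.finite(diameter) || diameter <= 0)
    stop_coroflow("geometry_error", "stent diameter must be positive")
  structure(list(branch_id = as.character(branch_id),
                 s_proximal = as.numeric(s_proximal),
                 s_distal = as.numeric(s_distal),
                 diameter = as.numeric(diameter),
                 length = as.numeric(s_distal - s_proximal),
                 name = name),
            class = "stent_spec")
}

#' Record a lesion
#'
#' @param branch_id Branch carrying the lesion.
#' @param s_range Numeric length-2 vector, lesion extent (mm).
#' @param min_diameter Minimal lumen diameter (mm).
#' @param reference_diameter Reference (healthy) diameter at the throat (mm).
#' @param percent_ds Percent diameter stenosis.
#' @param type Lesion class, one of `"focal"`, `"bifurcation"`, `"ostial"`,
#'   `"tandem-member"`, or `NA` before classification.
#' @return An object of class `lesion_record`.
#' @export
lesion_record <- function(branch_id, s_range, min_diameter,
                          reference_diameter, percent_ds,
                          type = NA_character_) {
  if (percent_ds < 0 || percent_ds >= 100)
    stop_coroflow("domain_error", "percent_ds must be in [0, 100)")
  if (min_diameter > reference_diameter + 1e-9)
    stop_coroflow("domain_error",
                  "min_diameter cannot exceed reference_diameter")
  structure(list(branch_id = as.character(branch_id),
                 s_range = as.numeric(s_range),
                 min_diameter = as.numeric(min_diameter),
                 reference_diameter = as.numeric(reference_diameter),
                 percent_ds = as.numeric(percent_ds),
                 type = type),
            class = "lesion_record")
}

#' Deploy a virtual stent on the centerline geometry
#'
#' Mimics stent deployment: the diseased radius profile between the
#' proximal (P*) and distal (D*) landing points is replaced by a cubic
#' spline through circular cross-sections of the stent diameter spaced
#' every `section_spacing` mm strictly inside the span, blended into the
#' original lumen radii at P* and D*. Geometry outside [P*, D*] is
#' untouched, and the input tree is not modified.
#'
#' @param tree A `coronary_tree`.
#' @param spec A [stent_spec()].
#' @param section_spacing Spacing of the interior circular sections (mm).
#' @return A new `coronary_tree` with the stented profile.
#' @export
deploy_stent <- function(tree, spec, section_spacing = 3) {
  if (section_spacing <= 0)
    stop_coroflow("geometry_error", "section_spacing must be positive")
  b <- tree_branch(tree, spec$branch_id)
  smax <- branch_length(b)
  if (spec$s_proximal < -1e-9 || spec$s_distal > smax + 1e-9)
    stop_coroflow("geometry_error",
                  "stent span [%.2f, %.2f] outside branch '%s' (0..%.2f mm)",
                  spec$s_proximal, spec$s_distal, spec$branch_id, smax)
  L <- spec$s_distal - spec$s_proximal
  # interior stations: integer multiples of the spacing strictly inside the
  # span; a station falling exactly on D* is excluded (with a tolerance for
  # spans that are floating-point multiples of the spacing)
  n_int <- max(0L, as.integer(ceiling(L / section_spacing - 1e-9)) - 1L)
  s_ctrl <- c(spec$s_proximal,
              spec$s_proximal + section_spacing * seq_len(n_int),
              spec$s_distal)
  r_end <- stats::approx(b$samples$s, b$samples$r,
                         xout = c(spec$s_proximal, spec$s_distal),
                         rule = 2)$y
  r_ctrl <- c(r_end[1], rep(spec$diameter / 2, n_int), r_end[2])
  fit <- if (length(s_ctrl) > 2L)
    stats::splinefun(s_ctrl, r_ctrl, method = "natural")
  else stats::approxfun(s_ctrl, r_ctrl, rule = 2)
  s <- b$samples$s
  inside <- s >= spec$s_proximal - 1e-9 & s <= spec$s_distal + 1e-9
  tree$branches[[spec$branch_id]]$samples$r[inside] <- pmax(fit(s[inside]),
                                                            1e-6)
  tree
}

# Lesion markers on a lumen-area curve: index of the throat (minimum area)
# and of the proximal/distal shoulders, operationalized as the point of
# maximal absolute change of slope (discrete second difference) of the
# area curve on each side of the throat. Because the curvature magnitude
# jumps at the shoulder, the marker is taken at the outermost sample still
# at half-prominence and then refined to sub-sample accuracy by
# interpolating the half-prominence crossing towards the next sample out.
find_lesion_markers <- function(s, area, i_window) {
  iw <- i_window
  if (length(iw) < 5L)
    stop_coroflow("no_lesion_error", "window too narrow to locate a lesion")
  i_s <- iw[which.min(area[iw])]
  rng <- diff(range(area[iw]))
  if (rng <= 1e-9 * max(area[iw]) || i_s == iw[1] || i_s == iw[length(iw)])
    stop_coroflow("no_lesion_error",
                  "no interior lumen-area minimum in the window")
  n <- length(s)
  d2 <- rep(NA_real_, n)
  idx <- 2:(n - 1L)
  d2[idx] <- 2 * ((area[idx + 1L] - area[idx]) / (s[idx + 1L] - s[idx]) -
                  (area[idx] - area[idx - 1L]) / (s[idx] - s[idx - 1L])) /
             (s[idx + 1L] - s[idx - 1L])
  atol <- 1e-12 * max(area[iw])
  side <- function(step) {
    # confine the shoulder search to this lesion's own flank: walk outwards
    # from the throat while the area keeps rising (a drop marks the next
    # lesion or segment)
    k <- i_s
    while ((k + step) %in% iw && area[k + step] >= area[k] - atol)
      k <- k + step
    cand <- if (step < 0) seq(k, i_s - 1L) else seq(i_s + 1L, k)
    cand <- cand[!is.na(d2[cand])]
    if (length(cand) == 0L)
      stop_coroflow("no_lesion_error", "no shoulder candidates in window")
    j <- cand[which.max(abs(d2[cand]))]
    thr <- abs(d2[j]) / 2
    # then walk outwards while the curvature magnitude stays above
    # half-prominence
    while ((j + step) %in% cand && abs(d2[j + step]) >= thr) j <- j + step
    # sub-sample refinement: interpolate the half-prominence crossing
    # between this sample and the next one out
    s_ref <- s[j]
    j_out <- j + step
    if (j_out >= 1L && j_out <= n && !is.na(d2[j_out]) &&
        abs(d2[j_out]) < thr) {
      fr <- (abs(d2[j]) - thr) / (abs(d2[j]) - abs(d2[j_out]))
      s_ref <- s[j] + fr * (s[j_out] - s[j])
    }
    list(i = j, s = s_ref)
  }
  p <- side(-1L)
  d <- side(1L)
  list(i_s = i_s, i_p = p$i, i_d = d$i, s_p = p$s, s_d = d$s)
}

#' Automatically size a stent from the lumen-area curve
#'
#' Locates the stenotic throat S as the lumen-area minimum in the search
#' window, then the proximal (P) and distal (D) shoulders as the points of
#' maximal absolute change of slope of the area curve on either side of S.
#' The distance P-D gives the stent length and the mean of the lumen
#' diameters at P and D the stent diameter.
#'
#' @param tree A `coronary_tree`.
#' @param branch_id Branch to size on.
#' @param search_window Length-2 numeric, arc range (mm) to search;
#'   defaults to the whole branch.
#' @return A [stent_spec()] spanning P to D.
#' @export
auto_size_stent <- function(tree, branch_id, search_window = NULL) {
  b <- tree_branch(tree, branch_id)
  s <- b$samples$s
  area <- pi * b$samples$r^2
  search_window <- search_window %||% range(s)
  iw <- which(s >= search_window[1] - 1e-9 & s <= search_window[2] + 1e-9)
  mk <- find_lesion_markers(s, area, iw)
  d_p <- 2 * stats::approx(s, b$samples$r, xout = mk$s_p, rule = 2)$y
  d_d <- 2 * stats::approx(s, b$samples$r, xout = mk$s_d, rule = 2)$y
  stent_spec(branch_id, s_proximal = mk$s_p, s_distal = mk$s_d,
             diameter = (d_p + d_d) / 2)
}

#' Classify lesions as focal, bifurcation, ostial or tandem
#'
#' A lesion is ostial when its extent starts within `ostial_margin` of the
#' branch origin (the aortic ostium for the root vessel, the daughter
#' take-off otherwise); bifurcation when its extent spans a child take-off;
#' tandem-member when two or more lesions of at least 50 % diameter
#' stenosis share a root-to-outlet path; focal otherwise. Precedence:
#' ostial > bifurcation > tandem-member > focal.
#'
#' @param tree A `coronary_tree`.
#' @param lesions A list of [lesion_record()]s located on the tree.
#' @param ostial_margin Margin (mm) from the branch origin that defines an
#'   ostial lesion.
#' @return The lesion list with `type` filled in.
#' @export
classify_lesions <- function(tree, lesions, ostial_margin = 3) {
  ch <- tree_children(tree)
  for (ls in lesions) {
    b <- tree_branch(tree, ls$branch_id)   # lookup error if off-tree
    if (ls$s_range[1] < -1e-9 || ls$s_range[2] > branch_length(b) + 1e-9)
      stop_coroflow("lookup_error",
                    "lesion range [%.2f, %.2f] off branch '%s'",
                    ls$s_range[1], ls$s_range[2], ls$branch_id)
  }
  n <- length(lesions)
  chains <- lapply(lesions, function(ls) ancestor_chain(tree, ls$branch_id))
  shares_path <- function(i, j) {
    lesions[[i]]$branch_id %in% chains[[j]] ||
      lesions[[j]]$branch_id %in% chains[[i]]
  }
  is_tandem <- logical(n)
  for (i in seq_len(n)) {
    if (lesions[[i]]$percent_ds < 50) next
    for (j in seq_len(n)) {
      if (j != i && lesions[[j]]$percent_ds >= 50 && shares_path(i, j)) {
        is_tandem[i] <- TRUE
        break
      }
    }
  }
  for (i in seq_len(n)) {
    ls <- lesions[[i]]
    kids <- ch[[ls$branch_id]]
    spans_child <- nrow(kids) > 0L &&
      any(kids$attach_s >= ls$s_range[1] & kids$attach_s <= ls$s_range[2])
    type <- if (ls$s_range[1] <= ostial_margin) "ostial"
            else if (spans_child) "bifurcation"
            else if (is_tandem[i]) "tandem-member"
            else "focal"
    lesions[[i]]$type <- type
  }
  lesions
}
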