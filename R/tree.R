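#' Construct a coronary branch
#'
#' A branch is an ordered centerline with lumen-radius samples. Arc length
#' `s` is measured in mm from the proximal (upstream) end of the branch;
#' radii are lumen radii in mm. Optional 3-D positions (mm) support
#' geometry export.
#'
#' @param id Branch identifier (character scalar).
#' @param s Numeric vector of arc-length samples (mm), strictly increasing,
#'   starting at or above 0.
#' @param r Numeric vector of lumen radii (mm), positive, same length as `s`.
#' @param parent_id Identifier of the parent branch, or `NULL`/`NA` for the
#'   root branch.
#' @param attach_s Arc position on the parent (mm) where this branch
#'   originates; `NA` for the root.
#' @param label Optional vessel name (e.g. `"LAD"`, `"LCX"`, `"RCA"`, `"D2"`).
#' @param xyz Optional numeric matrix (length(s) x 3) of centerline
#'   coordinates in mm.
#' @return An object of class `coro_branch`.
#' @export
branch <- function(id, s, r, parent_id = NULL, attach_s = NA_real_,
                   label = NULL, xyz = NULL) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop_coroflow("parse_error", "branch id must be a non-empty string")
  s <- as.numeric(s); r <- as.numeric(r)
  if (length(s) != length(r))
    stop_coroflow("parse_error", "branch '%s': s and r differ in length", id)
  samples <- data.frame(s = s, r = r)
  if (!is.null(xyz)) {
    xyz <- as.matrix(xyz)
    if (nrow(xyz) != length(s) || ncol(xyz) != 3L)
      stop_coroflow("parse_error", "branch '%s': xyz must be a %d x 3 matrix",
                    id, length(s))
    samples$x <- as.numeric(xyz[, 1])
    samples$y <- as.numeric(xyz[, 2])
    samples$z <- as.numeric(xyz[, 3])
  } else {
    samples$x <- NA_real_; samples$y <- NA_real_; samples$z <- NA_real_
  }
  structure(
    list(
      id = id,
      parent_id = if (is.null(parent_id) || is.na(parent_id)) NA_character_
                  else as.character(parent_id),
      attach_s = as.numeric(attach_s),
      label = if (is.null(label) || is.na(label)) NA_character_
              else as.character(label),
      samples = samples
    ),
    class = "coro_branch"
  )
}

#' Assemble a coronary tree from branches
#'
#' A coronary tree is a rooted collection of branches. Children attach to
#' their parent at an arc position `attach_s`; the distal tip of a branch
#' with no child attached at that tip is an outflow boundary (outlet).
#'
#' @param branches A list of [branch()] objects.
#' @param root_id Identifier of the root branch; inferred from the single
#'   branch without a parent when omitted.
#' @param metadata Free-form named list carried through I/O.
#' @param radius_floor Radii below this value (mm) trigger a warning during
#'   validation (default 0.75 mm, i.e. 1.5 mm diameter, the usual lower
#'   limit of reliable lumen segmentation).
#' @return An object of class `coronary_tree`.
#' @export
coronary_tree <- function(branches, root_id = NULL, metadata = list(),
                          radius_floor = 0.75) {
  if (length(branches) == 0L)
    stop_coroflow("topology_error", "a coronary tree needs at least one branch")
  ids <- vapply(branches, function(b) b$id, character(1))
  if (anyDuplicated(ids))
    stop_coroflow("topology_error", "duplicate branch id: %s",
                  ids[duplicated(ids)][1])
  names(branches) <- ids
  roots <- ids[vapply(branches, function(b) is.na(b$parent_id), logical(1))]
  if (is.null(root_id)) {
    if (length(roots) != 1L)
      stop_coroflow("topology_error",
                    "expected exactly one root branch, found %d", length(roots))
    root_id <- roots
  }
  tree <- structure(
    list(branches = branches, root_id = root_id, metadata = metadata),
    class = "coronary_tree"
  )
  validate_tree(tree, radius_floor = radius_floor)
}

#' Validate a coronary tree
#'
#' Checks every structural invariant: a single root, resolvable parents, no
#' cycles, at least two strictly increasing arc samples per branch, positive
#' radii, and child attachment positions within the parent's arc range.
#' Radii below `radius_floor` produce a warning (sub-resolution segments are
#' allowed but flagged).
#'
#' @param tree A `coronary_tree`.
#' @param radius_floor Warning threshold for lumen radii (mm).
#' @return The validated tree, invisibly usable in pipelines.
#' @export
validate_tree <- function(tree, radius_floor = 0.75) {
  brs <- tree$branches
  ids <- names(brs)
  if (!tree$root_id %in% ids)
    stop_coroflow("topology_error", "root_id '%s' is not a branch", tree$root_id)
  if (!is.na(brs[[tree$root_id]]$parent_id))
    stop_coroflow("topology_error", "root branch '%s' has a parent", tree$root_id)
  n_roots <- sum(vapply(brs, function(b) is.na(b$parent_id), logical(1)))
  if (n_roots != 1L)
    stop_coroflow("topology_error", "tree has %d root branches, expected 1", n_roots)
  low <- character(0)
  for (b in brs) {
    sm <- b$samples
    if (nrow(sm) < 2L)
      stop_coroflow("topology_error", "branch '%s' has fewer than 2 samples", b$id)
    if (any(!is.finite(sm$s)) || any(!is.finite(sm$r)))
      stop_coroflow("parse_error", "branch '%s' has non-finite samples", b$id)
    if (sm$s[1] < 0 || any(diff(sm$s) <= 0))
      stop_coroflow("topology_error",
                    "branch '%s': arc length must be >= 0 and strictly increasing", b$id)
    if (any(sm$r <= 0))
      stop_coroflow("topology_error", "branch '%s': radii must be positive", b$id)
    if (any(sm$r < radius_floor)) low <- c(low, b$id)
    if (!is.na(b$parent_id)) {
      if (!b$parent_id %in% ids)
        stop_coroflow("topology_error",
                      "branch '%s' references missing parent '%s'", b$id, b$parent_id)
      ps <- brs[[b$parent_id]]$samples$s
      if (!is.finite(b$attach_s) || b$attach_s < min(ps) - 1e-9 ||
          b$attach_s > max(ps) + 1e-9)
        stop_coroflow("topology_error",
                      "branch '%s': attach_s %.3f outside parent '%s' arc range",
                      b$id, b$attach_s, b$parent_id)
    }
    # cycle check: walk to root, bounded by branch count
    seen <- character(0); cur <- b$id
    repeat {
      if (cur %in% seen)
        stop_coroflow("topology_error", "cycle detected at branch '%s'", cur)
      seen <- c(seen, cur)
      pid <- brs[[cur]]$parent_id
      if (is.na(pid)) break
      if (!pid %in% ids)
        stop_coroflow("topology_error",
                      "branch '%s' references missing parent '%s'", cur, pid)
      cur <- pid
      if (length(seen) > length(ids))
        stop_coroflow("topology_error", "cycle detected in tree")
    }
  }
  if (length(low) > 0L)
    warning(sprintf(
      "branch(es) %s contain radii below %.2f mm (%.1f mm diameter)",
      paste(unique(low), collapse = ", "), radius_floor, 2 * radius_floor))
  invisible(tree)
}

#' @export
print.coronary_tree <- function(x, ...) {
  n_out <- length(outlet_ids(x))
  cat(sprintf("<coronary_tree> %d branch(es), root '%s', %d outlet(s)\n",
              length(x$branches), x$root_id, n_out))
  invisible(x)
}

tree_branch <- function(tree, branch_id) {
  b <- tree$branches[[branch_id]]
  if (is.null(b))
    stop_coroflow("lookup_error", "unknown branch '%s'", branch_id)
  b
}

branch_length <- function(b) max(b$samples$s)

# Children of each branch: named list of data.frames (id, attach_s),
# sorted by attach position then id for deterministic traversal.
tree_children <- function(tree) {
  out <- stats::setNames(
    rep(list(data.frame(id = character(0), attach_s = numeric(0))),
        length(tree$branches)),
    names(tree$branches))
  for (b in tree$branches) {
    if (!is.na(b$parent_id)) {
      out[[b$parent_id]] <- rbind(
        out[[b$parent_id]],
        data.frame(id = b$id, attach_s = b$attach_s))
    }
  }
  lapply(out, function(df) df[order(df$attach_s, df$id), , drop = FALSE])
}

#' Outlet branches of a tree
#'
#' An outlet is the distal tip of a branch with no child attached at that
#' tip (within `tol`). A vessel whose side branches all take off upstream of
#' its distal end therefore ends in an outlet, while a parent that splits at
#' its tip does not.
#'
#' @param tree A `coronary_tree`.
#' @param tol Arc-length tolerance (mm) for "attached at the tip".
#' @return Character vector of branch ids, sorted.
#' @export
outlet_ids <- function(tree, tol = 1e-6) {
  ch <- tree_children(tree)
  ids <- names(tree$branches)
  is_out <- vapply(ids, function(id) {
    tip <- branch_length(tree$branches[[id]])
    kids <- ch[[id]]
    nrow(kids) == 0L || all(kids$attach_s < tip - tol)
  }, logical(1))
  sort(ids[is_out])
}

# Ancestor chain from branch to root (inclusive of branch_id).
ancestor_chain <- function(tree, branch_id) {
  chain <- character(0); cur <- branch_id
  while (!is.na(cur)) {
    chain <- c(chain, cur)
    cur <- tree_branch(tree, cur)$parent_id
  }
  chain
}

#' Lumen-area curve of a branch
#'
#' Returns the cross-sectional lumen area A(s) = pi * r(s)^2 along a branch,
#' on the branch's own arc-length grid. This curve drives automatic stent
#' sizing and diameter-stenosis grading.
#'
#' @param tree A `coronary_tree`.
#' @param branch_id Branch identifier.
#' @return A data.frame with columns `s` (mm) and `area` (mm^2).
#' @export
lumen_area_curve <- function(tree, branch_id) {
  b <- tree_branch(tree, branch_id)
  data.frame(s = b$samples$s, area = pi * b$samples$r^2)
}

#' Mark an FFR measurement location
#'
#' @param branch_id Branch identifier.
#' @param s Arc position on the branch (mm).
#' @return An object of class `measurement_site`.
#' @export
measurement_site <- function(branch_id, s) {
  structure(list(branch_id = as.character(branch_id), s = as.numeric(s)),
            class = "measurement_site")
}
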