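# Reading and writing centerline trees.
#
# Canonical JSON schema:
#   {"root_id": str,
#    "branches": [{"id": str, "parent_id": str|null, "attach_s": num,
#                  "label": str|null,
#                  "samples": [{"s": num, "r": num, "xyz": [x,y,z]|null}]}],
#    "metadata": {}}
# Flat CSV: one row per sample, columns
#   branch_id,parent_id,attach_s,label,s,r,x,y,z (empty for missing).
# VTK legacy polyline is export-only, with radius as a point scalar.

#' Read a coronary tree from file
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; guessed from the file extension when
#'   omitted.
#' @param radius_floor Warning threshold for small radii (mm), see
#'   [validate_tree()].
#' @return A validated `coronary_tree`.
#' @export
read_tree <- function(path, format = c("json", "csv"), radius_floor = 0.75) {
  if (!file.exists(path))
    stop_coroflow("parse_error", "file not found: %s", path)
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("json", "csv")) ext else "json"
  }
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") read_tree_json(path, radius_floor)
  else read_tree_csv(path, radius_floor)
}

read_tree_json <- function(path, radius_floor) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_coroflow("parse_error", "malformed JSON in %s: %s",
                                  path, conditionMessage(e)))
  if (is.null(doc$branches) || length(doc$branches) == 0L)
    stop_coroflow("parse_error", "%s: no branches", path)
  brs <- lapply(doc$branches, function(br) {
    if (is.null(br$id))
      stop_coroflow("parse_error", "%s: branch record without id", path)
    smp <- br$samples
    if (is.null(smp) || length(smp) < 2L)
      stop_coroflow("parse_error", "%s: branch '%s' needs >= 2 samples",
                    path, br$id)
    s <- vapply(smp, function(p) as.numeric(p$s), numeric(1))
    r <- vapply(smp, function(p) as.numeric(p$r), numeric(1))
    has_xyz <- vapply(smp, function(p) !is.null(p$xyz), logical(1))
    xyz <- NULL
    if (all(has_xyz)) {
      xyz <- t(vapply(smp, function(p) as.numeric(unlist(p$xyz)), numeric(3)))
    }
    branch(id = br$id,
           s = s, r = r,
           parent_id = br$parent_id,
           attach_s = if (is.null(br$attach_s)) NA_real_ else as.numeric(br$attach_s),
           label = br$label,
           xyz = xyz)
  })
  coronary_tree(brs, root_id = doc$root_id,
                metadata = doc$metadata %||% list(),
                radius_floor = radius_floor)
}

read_tree_csv <- function(path, radius_floor) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(branch_id = "character",
                                   parent_id = "character",
                                   label = "character")),
    error = function(e)
      stop_coroflow("parse_error", "malformed CSV in %s: %s",
                    path, conditionMessage(e)))
  need <- c("branch_id", "parent_id", "attach_s", "label", "s", "r")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_coroflow("parse_error", "%s: missing column(s) %s",
                  path, paste(miss, collapse = ", "))
  brs <- lapply(split(df, factor(df$branch_id, levels = unique(df$branch_id))),
                function(g) {
    g <- g[order(g$s), , drop = FALSE]
    pid <- g$parent_id[1]
    if (is.na(pid) || !nzchar(pid)) pid <- NULL
    lab <- g$label[1]
    if (is.na(lab) || !nzchar(lab)) lab <- NULL
    xyz <- NULL
    if (all(c("x", "y", "z") %in% names(g)) && !anyNA(g[, c("x", "y", "z")]))
      xyz <- as.matrix(g[, c("x", "y", "z")])
    branch(id = g$branch_id[1], s = g$s, r = g$r, parent_id = pid,
           attach_s = g$attach_s[1], label = lab, xyz = xyz)
  })
  coronary_tree(unname(brs), radius_floor = radius_floor)
}

#' Write a coronary tree to file
#'
#' JSON and CSV round-trip exactly with [read_tree()]; the VTK legacy
#' polyline format is export-only (one polyline per branch, lumen radius as
#' a point scalar) for visualisation in standard viewers.
#'
#' @param tree A valid `coronary_tree`.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"vtk"`.
#' @return Invisibly, `path`.
#' @export
write_tree <- function(tree, path, format = c("json", "csv", "vtk")) {
  if (!inherits(tree, "coronary_tree"))
    stop_coroflow("parse_error", "write_tree expects a coronary_tree")
  suppressWarnings(validate_tree(tree))
  if (length(format) > 1L) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("json", "csv", "vtk")) ext else "json"
  }
  format <- match.arg(format, c("json", "csv", "vtk"))
  ok <- switch(format,
    json = write_tree_json(tree, path),
    csv  = write_tree_csv(tree, path),
    vtk  = write_tree_vtk(tree, path))
  invisible(path)
}

write_tree_json <- function(tree, path) {
  brs <- lapply(unname(tree$branches), function(b) {
    smp <- b$samples
    samples <- lapply(seq_len(nrow(smp)), function(i) {
      p <- list(s = smp$s[i], r = smp$r[i])
      p$xyz <- if (is.na(smp$x[i])) NULL else c(smp$x[i], smp$y[i], smp$z[i])
      p
    })
    list(id = b$id,
         parent_id = if (is.na(b$parent_id)) NULL else b$parent_id,
         attach_s = if (is.na(b$attach_s)) NULL else b$attach_s,
         label = if (is.na(b$label)) NULL else b$label,
         samples = samples)
  })
  doc <- list(root_id = tree$root_id, branches = brs, metadata = tree$metadata)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  tryCatch(writeLines(txt, path),
           error = function(e)
             stop_coroflow("io_error", "cannot write %s: %s",
                           path, conditionMessage(e)))
  TRUE
}

write_tree_csv <- function(tree, path) {
  rows <- do.call(rbind, lapply(unname(tree$branches), function(b) {
    smp <- b$samples
    data.frame(branch_id = b$id,
               parent_id = ifelse(is.na(b$parent_id), "", b$parent_id),
               attach_s = b$attach_s,
               label = ifelse(is.na(b$label), "", b$label),
               s = smp$s, r = smp$r, x = smp$x, y = smp$y, z = smp$z)
  }))
  tryCatch(utils::write.csv(rows, path, row.names = FALSE, na = ""),
           error = function(e)
             stop_coroflow("io_error", "cannot write %s: %s",
                           path, conditionMessage(e)))
  TRUE
}

write_tree_vtk <- function(tree, path) {
  brs <- unname(tree$branches)
  pts <- list(); lines <- list(); radii <- list(); offset <- 0L
  for (b in brs) {
    smp <- b$samples
    xyz <- if (anyNA(smp$x)) cbind(smp$s, 0, 0) else cbind(smp$x, smp$y, smp$z)
    n <- nrow(xyz)
    pts[[b$id]] <- xyz
    radii[[b$id]] <- smp$r
    lines[[b$id]] <- c(n, seq.int(offset, offset + n - 1L))
    offset <- offset + n
  }
  all_pts <- do.call(rbind, pts)
  con <- tryCatch(file(path, "w"),
                  error = function(e)
                    stop_coroflow("io_error", "cannot write %s: %s",
                                  path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coroflow centerline export", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(all_pts))), con)
  writeLines(apply(all_pts, 1, function(p) paste(format(p, digits = 9),
                                                 collapse = " ")), con)
  nseg <- length(lines)
  writeLines(sprintf("LINES %d %d", nseg,
                     sum(vapply(lines, length, integer(1)))), con)
  for (ln in lines) writeLines(paste(ln, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", nrow(all_pts)),
               "SCALARS radius float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(unlist(radii), digits = 9), con)
  TRUE
}
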