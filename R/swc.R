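#' Read a traced villous tree from an SWC file
#'
#' SWC is the standard line-oriented interchange format for skeletonized
#' 3D tracings: seven whitespace-separated columns
#' (`id type x y z radius parent`), `#` comments, parent `-1` for the root.
#' Coordinates and radii are taken as isotropic micrometers; the stored
#' point diameter is `2 * radius`.  Point chains are split into branches at
#' every branching node (point with two or more children); degree-2 points
#' remain interior samples of a branch.
#'
#' @param path path to an SWC file.
#' @param tree_id identifier for the tree; defaults to the file name
#'   without extension.
#' @return A [villous_tree()].
#' @seealso [write_swc()], [validate_tree()]
#' @export
read_swc <- function(path, tree_id = NULL) {
  if (is.null(tree_id))
    tree_id <- sub("\\.[^.]*$", "", basename(path))
  tab <- .parse_swc_table(path)
  if (nrow(tab) == 0L) stop("no points in ", path)
  ids <- tab$id
  if (anyDuplicated(ids))
    stop("duplicate point id(s) in ", path, ": line(s) ",
         paste(tab$line[duplicated(ids)], collapse = ", "))
  bad <- !is.finite(tab$radius) | tab$radius <= 0
  if (any(bad))
    stop("non-positive radius in ", path, ": line(s) ",
         paste(tab$line[bad], collapse = ", "))
  parent <- match(tab$parent, ids)          # NA for -1 or missing
  orphan <- tab$parent != -1 & is.na(parent)
  if (any(orphan))
    stop("parent id not found in ", path, ": line(s) ",
         paste(tab$line[orphan], collapse = ", "))
  roots <- tab$parent == -1
  if (sum(roots) > 1L)
    stop("multiple root points in ", path, ": line(s) ",
         paste(tab$line[roots], collapse = ", "))
  if (!any(roots)) stop("no root point (parent -1) in ", path)
  pts <- data.frame(x = tab$x, y = tab$y, z = tab$z,
                    diameter = 2 * tab$radius, parent = parent)
  tryCatch(villous_tree(pts, tree_id),
           error = function(e) stop("invalid tree in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

.parse_swc_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  if (!length(fields))
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric(), parent = integer(),
                      line = integer()))
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("expected 7 columns, line(s) ",
         paste(lineno[nf != 7L], collapse = ", "))
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m))
    stop("non-numeric field, line(s) ",
         paste(unique(lineno[rowSums(is.na(m)) > 0]), collapse = ", "))
  data.frame(id = as.integer(m[, 1L]), x = m[, 3L], y = m[, 4L], z = m[, 5L],
             radius = m[, 6L], parent = as.integer(m[, 7L]), line = lineno)
}

#' Write a villous tree to an SWC file
#'
#' Points are renumbered in depth-first order; the shared start point of a
#' child branch is written once (as part of the parent branch).  Radii are
#' written as `diameter / 2` with enough digits for a metric-preserving
#' round trip.
#'
#' @param tree a [villous_tree()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_swc <- function(tree, path) {
  np <- nrow(tree$points)
  # reconstruct one parent pointer per point from the branch chains
  parent <- rep(NA_integer_, np)
  for (pts in tree$branches$points) {
    for (k in 2:length(pts)) parent[pts[k]] <- pts[k - 1L]
  }
  # depth-first output order: root branch first, matching branch storage
  ord <- unique(unlist(tree$branches$points))
  newid <- match(seq_len(np), ord)
  p <- tree$points
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# SWC export (villomorph)",
               "# id type x y z radius parent"), con)
  swc_parent <- ifelse(is.na(parent[ord]), -1L, newid[parent[ord]])
  writeLines(sprintf("%d 0 %.10g %.10g %.10g %.10g %d",
                     newid[ord], p$x[ord], p$y[ord], p$z[ord],
                     p$diameter[ord] / 2, swc_parent), con)
  invisible(path)
}
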