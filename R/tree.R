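#' Villous tree objects
#'
#' A `villous_tree` represents one traced peripheral villous tree as a rooted
#' collection of branches.  Center points carry 3D coordinates (micrometers)
#' and a local diameter; branches run from a branching node (or the root) to
#' the next node or terminal end.  Points of degree 2 are interior samples of
#' a branch, never branch boundaries; only branching nodes (>= 2 children)
#' and terminal ends delimit branches.
#'
#' @param points data.frame with columns `x`, `y`, `z`, `diameter`
#'   (micrometers) and `parent` (integer row index of the parent point,
#'   `NA` for the root point).
#' @param tree_id character scalar identifying the tree.
#'
#' @return An object of class `villous_tree`: a list with elements
#'   `tree_id`, `points` (data.frame `x`, `y`, `z`, `diameter`) and
#'   `branches` (data.frame with `branch_id`, `parent_id`, `ends_terminal`
#'   and a list column `points` of point row indices, proximal to distal).
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 0, -3, 3), y = 0, z = c(0, 5, 9, 9),
#'                   diameter = 40, parent = c(NA, 1, 2, 2))
#' tr <- villous_tree(pts, "example")
#' tr
villous_tree <- function(points, tree_id = "tree") {
  stopifnot(is.data.frame(points),
            all(c("x", "y", "z", "diameter", "parent") %in% names(points)))
  n <- nrow(points)
  if (n < 2L) stop("a villous tree needs at least 2 points")
  coords <- as.matrix(points[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(!is.finite(points$diameter) | points$diameter <= 0))
    stop("diameters must be positive")
  parent <- as.integer(points$parent)
  root <- which(is.na(parent))
  if (length(root) != 1L)
    stop("expected exactly one root point, found ", length(root))
  if (any(parent[-root] < 1L | parent[-root] > n, na.rm = TRUE))
    stop("parent index out of range")

  # reachability from root doubles as the cycle / connectivity check
  children <- vector("list", n)
  for (i in seq_len(n)[-root]) {
    p <- parent[i]
    children[[p]] <- c(children[[p]], i)
  }
  seen <- logical(n)
  stack <- root
  while (length(stack)) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    seen[i] <- TRUE
    stack <- c(stack, children[[i]])
  }
  if (!all(seen))
    stop("points not reachable from the root (cycle or disconnected): ",
         paste(head(which(!seen), 5L), collapse = ", "))

  # merge coincident consecutive points (tolerant ingest of hand tracings)
  degen <- vapply(seq_len(n)[-root], function(i) {
    all(coords[i, ] == coords[parent[i], ])
  }, logical(1))
  if (any(degen)) {
    drop <- seq_len(n)[-root][degen]
    warning(length(drop), " coincident consecutive point(s) merged")
    for (i in drop) parent[parent == i] <- parent[i]
    keep <- setdiff(seq_len(n), drop)
    remap <- match(seq_len(n), keep)
    points <- points[keep, , drop = FALSE]
    parent <- remap[parent[keep]]
    points$parent <- parent
    return(villous_tree(points, tree_id))
  }

  nkids <- lengths(children)
  if (nkids[root] > 1L)
    stop("root point must begin a single stem (found ", nkids[root],
         " children); the traced root is a proximal cut end")

  # walk out branches in depth-first preorder
  branches <- list()
  walk <- function(start) {
    # start is a root or node point; follow each child chain to next node/leaf
    for (child in children[[start]]) {
      chain <- c(start, child)
      at <- child
      while (nkids[at] == 1L) {
        at <- children[[at]][1L]
        chain <- c(chain, at)
      }
      branches[[length(branches) + 1L]] <<-
        list(points = chain, terminal = nkids[at] == 0L, head = start, tail = at)
      if (nkids[at] >= 2L) walk(at)
    }
  }
  walk(root)
  nb <- length(branches)
  ids <- sprintf("b%0*d", max(2L, nchar(nb)), seq_len(nb))
  tails <- vapply(branches, `[[`, integer(1), "tail")
  heads <- vapply(branches, `[[`, integer(1), "head")
  parent_id <- ids[match(heads, tails)]  # NA for the root branch
  br <- data.frame(branch_id = ids, parent_id = parent_id,
                   ends_terminal = vapply(branches, `[[`, logical(1), "terminal"),
                   stringsAsFactors = FALSE)
  br$points <- lapply(branches, `[[`, "points")
  structure(list(tree_id = tree_id,
                 points = points[, c("x", "y", "z", "diameter")],
                 branches = br),
            class = "villous_tree")
}

#' @export
print.villous_tree <- function(x, ...) {
  ord <- terminal_distance_order(x)
  cat("<villous_tree> ", x$tree_id, "\n", sep = "")
  cat("  points:    ", nrow(x$points), "\n", sep = "")
  cat("  branches:  ", nrow(x$branches),
      " (", sum(x$branches$ends_terminal), " terminal)\n", sep = "")
  tab <- table(ord)
  cat("  orders:    ", paste(sprintf("bT%s:%d", names(tab), as.integer(tab)),
                             collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Extract the point matrix of one branch
#'
#' @param tree a [villous_tree()].
#' @param branch_id branch identifier.
#' @return Numeric matrix with columns `x`, `y`, `z`, `diameter`, rows
#'   ordered proximal to distal.
#' @export
branch_points <- function(tree, branch_id) {
  i <- match(branch_id, tree$branches$branch_id)
  if (is.na(i)) stop("no branch ", branch_id, " in tree ", tree$tree_id)
  as.matrix(tree$points[tree$branches$points[[i]], , drop = FALSE])
}

#' Terminal distance ordering
#'
#' Classifies every branch by its distance, counted in branching nodes, from
#' the nearest terminal end reachable distally: terminal branches are bT0,
#' directly preterminal branches bT1, and so on.  For a non-terminal branch
#' the order is one plus the minimum order among its child branches.  The
#' root (the proximal cut end where tracing started) never counts as a
#' terminal end.
#'
#' @param tree a [villous_tree()].
#' @return Named integer vector of orders, one per branch.
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 0, -3, 3), y = 0, z = c(0, 5, 9, 9),
#'                   diameter = 40, parent = c(NA, 1, 2, 2))
#' terminal_distance_order(villous_tree(pts))  # stem bT1, two leaves bT0
terminal_distance_order <- function(tree) {
  br <- tree$branches
  nb <- nrow(br)
  ord <- integer(nb)
  kids <- split(seq_len(nb), factor(br$parent_id, levels = br$branch_id))
  # branches are stored in depth-first preorder: children after parents
  for (i in rev(seq_len(nb))) {
    if (br$ends_terminal[i]) {
      ord[i] <- 0L
    } else {
      ch <- kids[[br$branch_id[i]]]
      ord[i] <- 1L + min(ord[ch])
    }
  }
  setNames(ord, br$branch_id)
}

#' Diagnose a traced tree file
#'
#' Runs the structural checks of [read_swc()] without aborting: every
#' violation is collected and reported together with basic topology counts.
#'
#' @param path path to an SWC file.
#' @return A list of class `tree_diagnostics` with elements `path`,
#'   `violations` (character), `n_points`, `n_branches`, `n_nodes`,
#'   `n_terminals` and `order_histogram` (counts are `NA` when the file
#'   could not be parsed).
#' @export
validate_tree <- function(path) {
  out <- list(path = path, violations = character(), n_points = NA_integer_,
              n_branches = NA_integer_, n_nodes = NA_integer_,
              n_terminals = NA_integer_, order_histogram = NULL)
  class(out) <- "tree_diagnostics"
  if (!file.exists(path)) {
    out$violations <- "file does not exist"
    return(out)
  }
  raw <- tryCatch(.parse_swc_table(path), error = function(e) conditionMessage(e))
  if (is.character(raw)) {
    out$violations <- raw
    return(out)
  }
  if (nrow(raw) == 0L) {
    out$violations <- "no points"
    return(out)
  }
  out$n_points <- nrow(raw)
  tree <- withCallingHandlers(
    tryCatch(read_swc(path), error = function(e) conditionMessage(e)),
    warning = function(w) {
      out$violations <<- c(out$violations, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (is.character(tree)) {
    out$violations <- c(out$violations, tree)
    return(out)
  }
  ord <- terminal_distance_order(tree)
  out$n_points <- nrow(tree$points)
  out$n_branches <- nrow(tree$branches)
  out$n_terminals <- sum(tree$branches$ends_terminal)
  # nodes = distinct start points of non-root branches
  starts <- vapply(tree$branches$points, function(p) p[1L], integer(1))
  out$n_nodes <- length(unique(starts[!is.na(tree$branches$parent_id)]))
  out$order_histogram <- table(ord)
  out
}

#' @export
print.tree_diagnostics <- function(x, ...) {
  cat("<tree_diagnostics> ", x$path, "\n", sep = "")
  if (length(x$violations)) {
    cat("  violations (", length(x$violations), "):\n", sep = "")
    for (v in x$violations) cat("   - ", v, "\n", sep = "")
  } else cat("  violations: none\n")
  if (!is.na(x$n_branches)) {
    cat("  points ", x$n_points, ", branches ", x$n_branches,
        ", nodes ", x$n_nodes, ", terminals ", x$n_terminals, "\n", sep = "")
    tab <- x$order_histogram
    cat("  orders: ", paste(sprintf("bT%s:%d", names(tab), as.integer(tab)),
                            collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
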