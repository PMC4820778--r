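#' Measure every branch of a villous tree
#'
#' Computes the full per-branch measurement set: terminal distance order,
#' planar branching angle against the parent branch (absent for the root
#' branch, which has no previous branch), tortuosity, centerline length,
#' frustum surface area and volume, and mean diameter.
#'
#' @param tree a [villous_tree()].
#' @return A data.frame with one row per branch: `branch_id`, `parent_id`,
#'   `order`, `ends_terminal`, `n_points`, `planar_angle_deg` (`NA` for
#'   the root branch), `tortuosity`, `length_um`, `surface_um2`,
#'   `volume_um3`, `mean_diameter_um`.
#' @export
#' @examples
#' pts <- data.frame(x = c(0, 0, -3, 3), y = 0, z = c(0, 5, 9, 9),
#'                   diameter = 40, parent = c(NA, 1, 2, 2))
#' measure_tree(villous_tree(pts))
measure_tree <- function(tree) {
  br <- tree$branches
  ord <- terminal_distance_order(tree)
  n <- nrow(br)
  res <- data.frame(branch_id = br$branch_id, parent_id = br$parent_id,
                    order = as.integer(ord[br$branch_id]),
                    ends_terminal = br$ends_terminal,
                    n_points = lengths(br$points),
                    planar_angle_deg = NA_real_, tortuosity = NA_real_,
                    length_um = NA_real_, surface_um2 = NA_real_,
                    volume_um3 = NA_real_, mean_diameter_um = NA_real_,
                    stringsAsFactors = FALSE)
  mats <- lapply(br$points, function(ix)
    as.matrix(tree$points[ix, , drop = FALSE]))
  for (i in seq_len(n)) {
    pts <- mats[[i]]
    wrap <- function(expr) tryCatch(expr, error = function(e)
      stop("branch ", br$branch_id[i], " of tree ", tree$tree_id, ": ",
           conditionMessage(e), call. = FALSE))
    res$length_um[i] <- wrap(branch_length(pts))
    res$tortuosity[i] <- wrap(tortuosity(pts))
    res$surface_um2[i] <- wrap(frustum_surface_area(pts))
    res$volume_um3[i] <- wrap(frustum_volume(pts))
    res$mean_diameter_um[i] <- .mean_diameter(pts)
    if (!is.na(br$parent_id[i])) {
      j <- match(br$parent_id[i], br$branch_id)
      res$planar_angle_deg[i] <- wrap(planar_branching_angle(pts, mats[[j]]))
    }
  }
  res
}

#' Aggregate branch measurements per specimen and order
#'
#' Computes, for every specimen and terminal distance order, the unweighted
#' arithmetic mean of the per-branch measurements: mean planar angle
#' (`mpa`), mean tortuosity (`mt`), mean length (`ml`), mean surface area
#' (`msa`) and mean volume (`mv`).  A mean is `NA` when no branch of that
#' order contributes (e.g. trees too small to contain bT2 branches), and
#' `mpa` can be `NA` while the other means are defined when the only
#' branch of an order is the root branch, whose angle is undefined.
#' Several trees of one specimen are pooled before averaging.
#'
#' @param branch_metrics data.frame of per-branch rows as produced by
#'   [measure_tree()], with added columns `specimen_id` and `group`.
#' @param orders integer vector of terminal distance orders to aggregate
#'   (columns are produced per order; branches of other orders are kept in
#'   the counts but not summarized).
#' @return A data.frame with one row per specimen: `specimen_id`, `group`,
#'   `n_branches`, then per order `k` the columns `n_bTk`, `mpa_bTk`,
#'   `mt_bTk`, `ml_bTk`, `msa_bTk`, `mv_bTk`.
#' @export
aggregate_specimens <- function(branch_metrics, orders = 0:2) {
  stopifnot(all(c("specimen_id", "group", "order") %in% names(branch_metrics)))
  sp <- unique(branch_metrics[, c("specimen_id", "group")])
  if (anyDuplicated(sp$specimen_id))
    stop("specimen(s) with more than one group label: ",
         paste(sp$specimen_id[duplicated(sp$specimen_id)], collapse = ", "))
  sp <- sp[order(sp$specimen_id), , drop = FALSE]
  rownames(sp) <- NULL
  cols <- c(mpa = "planar_angle_deg", mt = "tortuosity", ml = "length_um",
            msa = "surface_um2", mv = "volume_um3")
  sp$n_branches <- as.integer(
    table(factor(branch_metrics$specimen_id, levels = sp$specimen_id)))
  for (k in orders) {
    sel <- branch_metrics$order == k
    f <- factor(branch_metrics$specimen_id[sel], levels = sp$specimen_id)
    sp[[paste0("n_bT", k)]] <- as.integer(table(f))
    for (nm in names(cols)) {
      v <- branch_metrics[[cols[[nm]]]][sel]
      m <- tapply(v, f, function(x) mean(x, na.rm = TRUE))
      m[is.nan(m)] <- NA_real_
      sp[[paste0(nm, "_bT", k)]] <- as.numeric(m)
    }
  }
  sp
}
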