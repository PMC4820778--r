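#' Per-branch geometric measurements
#'
#' These functions operate on a branch point matrix as returned by
#' [branch_points()]: rows ordered proximal to distal, columns `x`, `y`,
#' `z` and (where needed) `diameter`, all in micrometers.
#'
#' * `branch_length()`: summed Euclidean distance between consecutive
#'   center points.
#' * `chord_vector()`: vector from the proximal to the distal endpoint;
#'   the branch direction used for branching angles.
#' * `planar_branching_angle()`: change of direction of a branch relative
#'   to its parent branch, in degrees in \[0, 180\] — the angle between the
#'   two chord vectors (0 means continuation with no change of direction).
#' * `tortuosity()`: path length along the centerline divided by the
#'   straight-line distance between the branch endpoints; 1 for a straight
#'   branch.
#' * `frustum_surface_area()` / `frustum_volume()`: the villus segment
#'   between consecutive center points is modelled as a conical frustum
#'   with end radii `diameter/2`; lateral surfaces (no end caps, which are
#'   internal cross-sections of the continuous villus) and volumes are
#'   summed along the branch.
#'
#' @param pts numeric matrix of branch points (>= 2 rows, columns `x`,
#'   `y`, `z`, and `diameter` for the frustum measures).
#' @param parent_pts point matrix of the parent branch.
#' @return A scalar measurement: micrometers for `branch_length`, a
#'   3-vector for `chord_vector`, degrees for `planar_branching_angle`, a
#'   dimensionless ratio >= 1 for `tortuosity`, square and cubic
#'   micrometers for the frustum measures.
#' @name branch_geometry
#' @examples
#' b <- cbind(x = c(0, 3, 3), y = c(0, 0, 4), z = 0, diameter = 2)
#' branch_length(b)   # 7
#' tortuosity(b)      # 7/5
NULL

.seglen <- function(pts) {
  d <- diff(pts[, c("x", "y", "z"), drop = FALSE])
  sqrt(rowSums(d^2))
}

#' @rdname branch_geometry
#' @export
branch_length <- function(pts) {
  stopifnot(nrow(pts) >= 2L)
  sum(.seglen(pts))
}

#' @rdname branch_geometry
#' @export
chord_vector <- function(pts) {
  stopifnot(nrow(pts) >= 2L)
  v <- as.numeric(pts[nrow(pts), c("x", "y", "z")] - pts[1L, c("x", "y", "z")])
  if (all(v == 0))
    stop("degenerate branch: coincident endpoints")
  v
}

#' @rdname branch_geometry
#' @export
planar_branching_angle <- function(pts, parent_pts) {
  a <- chord_vector(parent_pts)
  b <- chord_vector(pts)
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' @rdname branch_geometry
#' @export
tortuosity <- function(pts) {
  chord <- sqrt(sum(chord_vector(pts)^2))
  branch_length(pts) / chord
}

#' @rdname branch_geometry
#' @export
frustum_surface_area <- function(pts) {
  stopifnot(nrow(pts) >= 2L, all(pts[, "diameter"] > 0))
  h <- .seglen(pts)
  r <- pts[, "diameter"] / 2
  r1 <- r[-length(r)]; r2 <- r[-1L]
  sum(pi * (r1 + r2) * sqrt(h^2 + (r1 - r2)^2))
}

#' @rdname branch_geometry
#' @export
frustum_volume <- function(pts) {
  stopifnot(nrow(pts) >= 2L, all(pts[, "diameter"] > 0))
  h <- .seglen(pts)
  r <- pts[, "diameter"] / 2
  r1 <- r[-length(r)]; r2 <- r[-1L]
  sum(pi * h / 3 * (r1^2 + r1 * r2 + r2^2))
}

.mean_diameter <- function(pts) {
  # length-weighted mean of segment mid-diameters
  h <- .seglen(pts)
  d <- pts[, "diameter"]
  mid <- (d[-length(d)] + d[-1L]) / 2
  if (sum(h) == 0) return(mean(d))
  sum(mid * h) / sum(h)
}
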