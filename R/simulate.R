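#' Group profiles for synthetic villous-tree cohorts
#'
#' A `villous_profile` holds the distributional parameters from which
#' synthetic specimens of one clinical (sub)group are drawn: the mixture
#' of terminal (bT0) branching-angle components, the preterminal (bT1)
#' tortuosity regime, branch length means per order, diameters, tree
#' size, and the probability that a tree is too small to contain bT2
#' branches.  Angle mixture components are drawn at the specimen level:
#' each placenta belongs to one component and its branch angles scatter
#' around that component's mean, which is what makes the distribution of
#' per-placenta mean angles multimodal.
#'
#' @param name profile name (subgroup label, e.g. `"HT-normal"`).
#' @param group_label clinical label written to the cohort manifest
#'   (`"IUGR"` or `"normal"`).
#' @param n_specimens number of specimens.
#' @param angle_means,angle_sds,angle_weights mixture components for
#'   branching angles, degrees; weights must sum to 1.
#' @param tort_mean,tort_sd,tort_range truncated-normal parameters for
#'   bT1 tortuosity targets; `tort_range` keeps the regime on one side of
#'   the subgrouping cutoff.
#' @param length_means,length_sd branch length means per order
#'   (bT0, bT1, bT2 and higher) and common sd, micrometers.
#' @param diameter_mean,diameter_sd branch diameter scale, micrometers.
#' @param diameter_scale multiplier applied to all diameters (used to
#'   give the high-tortuosity subgroup its thicker branches).
#' @param terminals_mean mean number of terminal ends per tree (shifted
#'   Poisson: `1 + Poisson(terminals_mean - 1)`).
#' @param prob_no_bT2 probability that a tree's topology contains no
#'   branch of order 2 (every internal node keeps a terminal child).
#' @return A `villous_profile` object (a validated list).
#' @export
villous_profile <- function(name, group_label, n_specimens,
                            angle_means, angle_sds, angle_weights,
                            tort_mean, tort_sd, tort_range,
                            length_means, length_sd,
                            diameter_mean, diameter_sd, diameter_scale = 1,
                            terminals_mean = 12, prob_no_bT2 = 0.25) {
  stopifnot(n_specimens >= 1, length(angle_means) == length(angle_sds),
            length(angle_means) == length(angle_weights),
            abs(sum(angle_weights) - 1) < 1e-9, all(angle_sds >= 0),
            tort_range[1] >= 1, tort_range[2] > tort_range[1],
            length(length_means) == 3L, all(length_means > 0),
            diameter_mean > 0, terminals_mean >= 1,
            prob_no_bT2 >= 0, prob_no_bT2 <= 1)
  structure(list(name = name, group_label = group_label,
                 n_specimens = as.integer(n_specimens),
                 angle_means = angle_means, angle_sds = angle_sds,
                 angle_weights = angle_weights,
                 tort_mean = tort_mean, tort_sd = tort_sd,
                 tort_range = tort_range,
                 length_means = length_means, length_sd = length_sd,
                 diameter_mean = diameter_mean, diameter_sd = diameter_sd,
                 diameter_scale = diameter_scale,
                 terminals_mean = terminals_mean,
                 prob_no_bT2 = prob_no_bT2),
            class = "villous_profile")
}

#' Default study profiles
#'
#' Profiles emulating the study conditions: 40 IUGR placentas with
#' specimen-level angle components at 58 and 76 degrees and bT1
#' tortuosity below 1.2; 36 low-tortuosity normals (components 52 and 64
#' degrees, bT1 tortuosity below 1.2); and 14 high-tortuosity normals
#' (single component at 67 degrees, bT1 tortuosity above 1.2, with longer
#' and thicker preterminal branches).  Both normal subgroups carry the
#' manifest label `"normal"`; rediscovering the subgroups from the
#' tortuosity data is part of the analysis.
#'
#' @return Named list of three [villous_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    IUGR = villous_profile(
      "IUGR", "IUGR", 40,
      angle_means = c(58, 76), angle_sds = c(6, 6), angle_weights = c(.5, .5),
      tort_mean = 1.08, tort_sd = 0.04, tort_range = c(1, 1.199),
      length_means = c(60, 80, 100), length_sd = 15,
      diameter_mean = 50, diameter_sd = 6,
      terminals_mean = 12, prob_no_bT2 = 18 / 40),
    `LT-normal` = villous_profile(
      "LT-normal", "normal", 36,
      angle_means = c(52, 64), angle_sds = c(6, 6), angle_weights = c(.5, .5),
      tort_mean = 1.08, tort_sd = 0.04, tort_range = c(1, 1.199),
      length_means = c(60, 80, 100), length_sd = 15,
      diameter_mean = 50, diameter_sd = 6,
      terminals_mean = 12, prob_no_bT2 = 11 / 50),
    `HT-normal` = villous_profile(
      "HT-normal", "normal", 14,
      angle_means = 67, angle_sds = 6, angle_weights = 1,
      tort_mean = 1.28, tort_sd = 0.05, tort_range = c(1.201, 1.45),
      length_means = c(60, 112, 100), length_sd = 15,
      diameter_mean = 50, diameter_sd = 6, diameter_scale = 1.1,
      terminals_mean = 12, prob_no_bT2 = 11 / 50))
}

# truncated normal via inverse-CDF (deterministic under the RNG stream)
.rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

.orthobasis <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  e <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u1 <- c(dir[2] * e[3] - dir[3] * e[2],
          dir[3] * e[1] - dir[1] * e[3],
          dir[1] * e[2] - dir[2] * e[1])
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(dir[2] * u1[3] - dir[3] * u1[2],
          dir[3] * u1[1] - dir[1] * u1[3],
          dir[1] * u1[2] - dir[2] * u1[1])
  list(dir = dir, u1 = u1, u2 = u2)
}

#' Generate one branch centerline with a prescribed tortuosity
#'
#' Builds a polyline of `n_points` center points whose chord (proximal
#' to distal endpoint) equals `direction * length / tortuosity_target`
#' exactly, and whose measured polyline tortuosity matches the target: a
#' sinusoidal perturbation orthogonal to the chord (vanishing at both
#' endpoints) is superposed on the straight chord, with its amplitude
#' solved by bisection against the measured polyline length.  A target of
#' 1 returns the exactly collinear chain.
#'
#' @param length total centerline length, micrometers.
#' @param tortuosity_target desired ratio `length / chord`, >= 1.
#' @param start 3-vector, proximal endpoint.
#' @param direction 3-vector, chord direction (normalized internally).
#' @param n_points number of center points (>= 2; >= 5 for a curved
#'   target).
#' @return Matrix `n_points x 3` of coordinates.
#' @export
generate_branch_path <- function(length, tortuosity_target, start, direction,
                                 n_points = 9) {
  stopifnot(length > 0, tortuosity_target >= 1, n_points >= 2)
  basis <- .orthobasis(direction)
  chord <- length / tortuosity_target
  tt <- seq(0, 1, length.out = n_points)
  base <- outer(tt * chord, basis$dir) +
    matrix(start, n_points, 3, byrow = TRUE)
  if (tortuosity_target <= 1 + 1e-12) return(base)
  if (n_points < 5)
    stop("a curved branch needs at least 5 sample points")
  phi <- runif(1, 0, 2 * pi)
  w <- cos(phi) * basis$u1 + sin(phi) * basis$u2
  wave <- sin(2 * pi * tt)
  arc <- function(A) {
    p <- base + outer(A * wave, w)
    sum(sqrt(rowSums(diff(p)^2)))
  }
  lo <- 0; hi <- chord
  it <- 0
  while (arc(hi) < length) {
    hi <- hi * 2; it <- it + 1
    if (it > 60) stop("tortuosity target unreachable")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (arc(mid) < length) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * chord) break
  }
  base + outer(hi * wave, w)
}

# recursive topology: number of terminals per subtree; caterpillar keeps a
# terminal child at every node so no order-2 branch can arise
.split_terminals <- function(T, caterpillar, at_root) {
  if (caterpillar) {
    s <- c(1L, T - 1L)
    if (runif(1) < 0.5) s <- rev(s)
  } else if (at_root && T >= 4L) {
    a <- sample(2:(T - 2L), 1L)
    s <- c(a, T - a)
  } else {
    a <- sample.int(T - 1L, 1L)
    s <- c(a, T - a)
  }
  s
}

#' Generate a synthetic villous tree
#'
#' Grows a rooted, strictly dichotomous tree distally from a root stub:
#' the number of terminal ends is drawn from a shifted Poisson, the
#' topology is split recursively (with probability `prob_no_bT2` as a
#' caterpillar, which contains no bT2 branch), and every branch is
#' realized with [generate_branch_path()].  Child chord directions are
#' placed at the drawn branching angle from the parent chord with uniform
#' azimuth, so the measured planar angle reproduces the draw exactly.
#' All draws use R's RNG: seed the session for reproducibility.
#'
#' @param profile a [villous_profile()].
#' @param tree_id identifier for the generated tree.
#' @return List with elements `tree` (a [villous_tree()]), `ground_truth`
#'   (data.frame of per-branch targets: `branch_id`, `order`,
#'   `angle_target_deg`, `angle_component`, `tortuosity_target`,
#'   `length_um`, `diameter_um`) and `angle_component` (the specimen's
#'   mixture component index).
#' @export
generate_tree <- function(profile, tree_id = "synthetic") {
  stopifnot(inherits(profile, "villous_profile"))
  comp <- sample.int(length(profile$angle_weights), 1L,
                     prob = profile$angle_weights)
  n_term <- 1L + rpois(1L, profile$terminals_mean - 1)
  caterpillar <- runif(1) < profile$prob_no_bT2
  if (!caterpillar) n_term <- max(n_term, 4L)

  # topology first: nested list with per-subtree terminal counts
  grow <- function(T, at_root) {
    if (T == 1L) return(list(T = 1L, children = NULL))
    s <- .split_terminals(T, caterpillar, at_root)
    list(T = T, children = list(grow(s[1L], FALSE), grow(s[2L], FALSE)))
  }
  topo <- grow(n_term, TRUE)
  # terminal-distance order of every subtree root branch
  order_of <- function(node) {
    if (is.null(node$children)) return(0L)
    1L + min(order_of(node$children[[1L]]), order_of(node$children[[2L]]))
  }

  env <- new.env()
  env$pts <- list()     # rows: x, y, z, diameter, parent
  env$gt <- list()
  add_point <- function(xyz, diam, parent) {
    env$pts[[length(env$pts) + 1L]] <- c(xyz, diam, parent)
    length(env$pts)
  }
  n_points <- 9L

  draw_len <- function(ord) {
    m <- profile$length_means[[min(ord, 2L) + 1L]]
    .rtnorm(1L, m, profile$length_sd, lo = 0.3 * m)
  }
  draw_tort <- function(ord) {
    if (ord == 1L)
      .rtnorm(1L, profile$tort_mean, profile$tort_sd,
              profile$tort_range[1L], profile$tort_range[2L])
    else .rtnorm(1L, 1.05, 0.03, 1, 1.15)
  }
  draw_diam <- function(ord) {
    m <- profile$diameter_mean * (1 + 0.12 * min(ord, 3L)) *
      profile$diameter_scale
    .rtnorm(1L, m, profile$diameter_sd, lo = 12)
  }

  # realize one branch, then recurse into its children (depth-first, so
  # the branch order here matches the villous_tree() decomposition order)
  realize <- function(node, start_idx, start_xyz, dir, angle, ord) {
    len <- draw_len(ord)
    tort <- draw_tort(ord)
    diam <- draw_diam(ord)
    path <- generate_branch_path(len, tort, start_xyz, dir,
                                 n_points = n_points)
    m <- nrow(path)
    taper <- seq(1.05, 0.95, length.out = m)
    prev <- start_idx
    for (i in 2:m)
      prev <- add_point(path[i, ], diam * taper[i], prev)
    env$gt[[length(env$gt) + 1L]] <-
      data.frame(order = ord, angle_target_deg = angle,
                 angle_component = comp, tortuosity_target = tort,
                 length_um = len, diameter_um = diam)
    if (!is.null(node$children)) {
      b <- .orthobasis(dir)
      end_xyz <- path[m, ]
      for (ch in node$children) {
        a <- .rtnorm(1L, profile$angle_means[[comp]],
                     profile$angle_sds[[comp]], 1, 179)
        phi <- runif(1, 0, 2 * pi)
        nd <- cos(a * pi / 180) * b$dir +
          sin(a * pi / 180) * (cos(phi) * b$u1 + sin(phi) * b$u2)
        realize(ch, prev, end_xyz, nd, a, order_of(ch))
      }
    }
  }

  root_diam <- draw_diam(order_of(topo) + 1L)
  root_idx <- add_point(c(0, 0, 0), root_diam, NA_real_)
  root_ord <- if (is.null(topo$children)) 0L
              else 1L + min(order_of(topo$children[[1L]]),
                            order_of(topo$children[[2L]]))
  # the root stub is itself the first branch; its distal end is the first node
  stub <- topo
  realize(stub, root_idx, c(0, 0, 0), c(0, 0, 1), NA_real_, root_ord)

  pts <- do.call(rbind, env$pts)
  points <- data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                       diameter = pts[, 4L], parent = as.integer(pts[, 5L]))
  tree <- villous_tree(points, tree_id)
  gt <- do.call(rbind, env$gt)
  stopifnot(nrow(gt) == nrow(tree$branches))
  gt <- cbind(branch_id = tree$branches$branch_id, gt)
  list(tree = tree, ground_truth = gt, angle_component = comp)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one SWC file per specimen plus a cohort manifest
#' (`manifest.csv`: `specimen_id`, `group`, `swc_path`) and a ground
#' truth table (`ground_truth.csv`).  High- and low-tortuosity normal
#' specimens are both labelled `"normal"` in the manifest — the analysis
#' pipeline must rediscover the split — while `ground_truth.csv` records
#' the generating profile.  Output is fully reproducible: the master
#' seed draws one sub-seed per specimen, so cohorts are extensible
#' without reshuffling.
#'
#' @param profiles named list of [villous_profile()] objects.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `manifest` (path), `ground_truth`
#'   (path) and `n_specimens`.
#' @export
generate_cohort <- function(profiles = default_profiles(), seed = 1,
                            out_dir) {
  stopifnot(length(profiles) >= 1,
            !anyDuplicated(vapply(profiles, `[[`, "", "name")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  # one row per specimen, profiles interleaved within each clinical group
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(profile = p$name, group = p$group_label,
               stringsAsFactors = FALSE)[rep(1L, p$n_specimens), ]))
  rows <- do.call(rbind, lapply(split(rows, rows$group), function(d) {
    d <- d[sample.int(nrow(d)), , drop = FALSE]
    prefix <- if (d$group[1L] == "IUGR") "IUGR" else "NORM"
    d$specimen_id <- sprintf("%s_%02d", prefix, seq_len(nrow(d)))
    d
  }))
  rownames(rows) <- NULL
  rows$seed <- sample.int(2147483646L, nrow(rows))

  gt_all <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    set.seed(rows$seed[i])
    g <- generate_tree(profiles[[match(rows$profile[i],
                                       vapply(profiles, `[[`, "", "name"))]],
                       tree_id = rows$specimen_id[i])
    write_swc(g$tree, file.path(out_dir, paste0(rows$specimen_id[i], ".swc")))
    gt_all[[i]] <- cbind(specimen_id = rows$specimen_id[i],
                         true_group = rows$profile[i], g$ground_truth)
  }
  manifest <- data.frame(specimen_id = rows$specimen_id, group = rows$group,
                         swc_path = paste0(rows$specimen_id, ".swc"),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$specimen_id), ]
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  gt <- do.call(rbind, gt_all)
  gpath <- file.path(out_dir, "ground_truth.csv")
  write.csv(gt, gpath, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = mpath, ground_truth = gpath,
                 n_specimens = nrow(rows)))
}
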