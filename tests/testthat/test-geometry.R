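mkb <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("x", "y", "z", "diameter")[seq_len(ncol(m))]
  if (ncol(m) == 3L) m <- cbind(m, diameter = 1)
  colnames(m) <- c("x", "y", "z", "diameter")
  m
}

test_that("branch length sums segment lengths", {
  expect_equal(branch_length(mkb(c(0, 0, 0), c(0, 0, 5), c(0, 0, 9))), 9)
  expect_equal(branch_length(mkb(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))), 7)
  th <- seq(0, pi, length.out = 101)   # 100-segment unit semicircle
  semi <- cbind(x = cos(th), y = sin(th), z = 0, diameter = 1)
  expect_equal(branch_length(semi), pi, tolerance = 1e-3)
})

test_that("chord vector is the endpoint difference and antisymmetric", {
  b <- mkb(c(0, 0, 0), c(0.5, 0, 1), c(1, 0, 2))
  expect_equal(chord_vector(b), c(1, 0, 2))
  expect_equal(chord_vector(b[3:1, ]), -c(1, 0, 2))
  # chord never exceeds path length
  set.seed(1)
  for (i in 1:20) {
    b <- cbind(matrix(rnorm(15), 5), diameter = 1)
    colnames(b) <- c("x", "y", "z", "diameter")
    expect_lte(sqrt(sum(chord_vector(b)^2)), branch_length(b) + 1e-12)
  }
  expect_error(chord_vector(mkb(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))),
               "degenerate")
})

test_that("planar branching angle matches closed forms", {
  par <- mkb(c(0, 0, -1), c(0, 0, 0))
  expect_equal(planar_branching_angle(mkb(c(0, 0, 0), c(0, 0, 1)), par), 0)
  expect_equal(planar_branching_angle(mkb(c(0, 0, 0), c(1, 0, 1)), par), 45)
  expect_equal(planar_branching_angle(mkb(c(0, 0, 0), c(1, 0, 0)), par), 90)
  expect_equal(planar_branching_angle(mkb(c(0, 0, 0), c(0, 0, -1)), par), 180)
})

test_that("tortuosity is 1 exactly for collinear points and matches ratios", {
  coll <- mkb(c(0, 0, 0), c(0, 0, 5), c(0, 0, 9))
  expect_identical(tortuosity(coll), 1)
  expect_equal(tortuosity(mkb(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))), 1.4)
  th <- seq(0, pi, length.out = 101)
  semi <- cbind(x = cos(th), y = sin(th), z = 0, diameter = 1)
  expect_equal(tortuosity(semi), pi / 2, tolerance = 1e-3)
  # >= 1 with equality iff collinear, over random perturbations
  set.seed(2)
  for (i in 1:20) {
    straight <- outer(sort(runif(5)), c(1, 2, -1))
    b <- cbind(straight, diameter = 1)
    colnames(b) <- c("x", "y", "z", "diameter")
    expect_equal(tortuosity(b), 1)
    b[3, 1:3] <- b[3, 1:3] + rnorm(3, sd = 0.1)
    expect_gt(tortuosity(b), 1)
  }
})

test_that("frustum surface and volume match cylinder and cone closed forms", {
  cyl <- mkb(c(0, 0, 0, 2), c(0, 0, 5, 2), c(0, 0, 10, 2))
  expect_equal(frustum_surface_area(cyl), 20 * pi, tolerance = 1e-12)
  expect_equal(frustum_volume(cyl), 10 * pi, tolerance = 1e-12)
  fru <- mkb(c(0, 0, 0, 2), c(0, 0, 4, 4))
  expect_equal(frustum_surface_area(fru), 3 * pi * sqrt(17), tolerance = 1e-12)
  fru2 <- mkb(c(0, 0, 0, 2), c(0, 0, 3, 4))
  expect_equal(frustum_volume(fru2), 7 * pi, tolerance = 1e-12)
  cone <- mkb(c(0, 0, 0, 2), c(0, 0, 3, 1e-12))
  expect_equal(frustum_volume(cone), pi, tolerance = 1e-6)
})

test_that("refinement by collinear midpoints leaves measures unchanged", {
  b <- mkb(c(0, 0, 0, 2), c(0, 0, 10, 4))
  refine <- function(b, k) {
    t <- seq(0, 1, length.out = k)
    cbind(x = 0, y = 0, z = 10 * t, diameter = 2 + 2 * t)
  }
  for (k in c(3, 7, 41)) {
    r <- refine(b, k)
    expect_equal(branch_length(r), branch_length(b), tolerance = 1e-9)
    expect_equal(frustum_volume(r), frustum_volume(b), tolerance = 1e-9)
    expect_equal(frustum_surface_area(r), frustum_surface_area(b),
                 tolerance = 1e-9)
    expect_equal(tortuosity(r), 1, tolerance = 1e-12)
  }
})

test_that("all metrics are invariant under rigid motion", {
  set.seed(9)
  g <- generate_tree(default_profiles()$IUGR, "rigid")
  m1 <- measure_tree(g$tree)
  m2 <- measure_tree(apply_rigid(g$tree, seed = 4))
  for (col in c("planar_angle_deg", "tortuosity", "length_um",
                "surface_um2", "volume_um3", "mean_diameter_um"))
    expect_equal(m2[[col]], m1[[col]], tolerance = 1e-9)
})
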