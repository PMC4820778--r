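test_that("default profiles encode the study conditions", {
  pr <- default_profiles()
  expect_equal(pr$IUGR$angle_means, c(58, 76))
  expect_equal(pr$`LT-normal`$angle_means, c(52, 64))
  expect_equal(pr$`HT-normal`$angle_means, 67)
  expect_equal(pr$IUGR$n_specimens + 0L, 40L)
  expect_equal(pr$`HT-normal`$n_specimens + pr$`LT-normal`$n_specimens, 50L)
  expect_true(all(vapply(pr, function(p) p$tort_range[1], 0) >= 1))
  # tortuosity regimes sit on opposite sides of the 1.2 cutoff
  expect_lt(pr$IUGR$tort_range[2], 1.2)
  expect_gt(pr$`HT-normal`$tort_range[1], 1.2)
})

test_that("branch paths honour chord, length and tortuosity targets", {
  set.seed(41)
  start <- c(1, 2, 3)
  for (tt in c(1, 1.05, 1.3, 1.45)) {
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    p <- generate_branch_path(80, tt, start, dirv, n_points = 9)
    pts <- cbind(p, diameter = 10)
    colnames(pts) <- c("x", "y", "z", "diameter")
    expect_equal(unname(p[1, ]), start)
    expect_equal(chord_vector(pts), dirv * 80 / tt, tolerance = 1e-8)
    expect_equal(branch_length(pts), 80, tolerance = 1e-6)
    expect_equal(tortuosity(pts), tt, tolerance = 1e-6)
    if (tt == 1) expect_identical(tortuosity(pts), 1)  # exactly collinear
  }
  expect_error(generate_branch_path(10, 0.9, c(0, 0, 0), c(0, 0, 1)))
})

test_that("generated trees carry exact ground truth", {
  set.seed(42)
  pr <- default_profiles()
  for (nm in names(pr)) {
    g <- generate_tree(pr[[nm]], nm)
    m <- measure_tree(g$tree)
    expect_equal(m$order, g$ground_truth$order)
    expect_equal(m$planar_angle_deg, g$ground_truth$angle_target_deg,
                 tolerance = 1e-6)
    expect_equal(m$tortuosity, g$ground_truth$tortuosity_target,
                 tolerance = 1e-4)
    expect_equal(m$length_um, g$ground_truth$length_um, tolerance = 1e-6)
  }
})

test_that("angle draws across trees recover the mixture component means", {
  set.seed(43)
  pr <- default_profiles()$`LT-normal`
  drawn <- list()
  for (i in 1:60) {
    g <- generate_tree(pr, paste0("t", i))
    gt <- g$ground_truth
    sel <- gt$order == 0 & !is.na(gt$angle_target_deg)
    drawn[[i]] <- gt[sel, c("angle_component", "angle_target_deg")]
  }
  d <- do.call(rbind, drawn)
  for (comp in 1:2) {
    got <- mean(d$angle_target_deg[d$angle_component == comp])
    expect_lt(abs(got - pr$angle_means[comp]), 1)
  }
})

test_that("caterpillar probability controls the absence of bT2 branches", {
  set.seed(44)
  pr <- default_profiles()$IUGR   # prob_no_bT2 = 0.45
  lacks <- logical(60)
  for (i in 1:60) {
    g <- generate_tree(pr, paste0("t", i))
    lacks[i] <- !any(g$ground_truth$order >= 2)
  }
  # binomial 3-sigma band around 0.45 with n = 60
  expect_lt(abs(mean(lacks) - 0.45), 3 * sqrt(0.45 * 0.55 / 60))
})

test_that("cohorts are reproducible byte for byte and internally consistent", {
  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  pr <- lapply(default_profiles(), function(p) { p$n_specimens <- 4L; p })
  generate_cohort(pr, seed = 11, out_dir = d1)
  generate_cohort(pr, seed = 11, out_dir = d2)
  f1 <- list.files(d1)
  expect_equal(f1, list.files(d2))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(sum(man$group == "IUGR"), 4L)
  expect_equal(sum(man$group == "normal"), 8L)
  expect_true(all(file.exists(file.path(d1, man$swc_path))))
  # manifest hides the subgroup; ground truth keeps it
  gt <- read.csv(file.path(d1, "ground_truth.csv"))
  expect_setequal(unique(gt$true_group), c("IUGR", "HT-normal", "LT-normal"))
  expect_false("HT-normal" %in% man$group)
  unlink(c(d1, d2), recursive = TRUE)
})
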