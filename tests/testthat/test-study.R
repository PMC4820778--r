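# small cohort shared across pipeline tests
study_dir <- local({
  dir <- file.path(tempdir(), "study_cohort")
  if (!dir.exists(dir)) {
    pr <- default_profiles()
    pr$IUGR$n_specimens <- 8L
    pr$`LT-normal`$n_specimens <- 7L
    pr$`HT-normal`$n_specimens <- 5L
    generate_cohort(pr, seed = 301, out_dir = dir)
  }
  dir
})

test_that("the pipeline discovers the subgroups and reports all specimens", {
  st <- run_study(file.path(study_dir, "manifest.csv"),
                  dip_n_boot = 1000, seed = 5)
  agg <- st$aggregates
  expect_equal(nrow(agg), 20L)
  gt <- read.csv(file.path(study_dir, "ground_truth.csv"))
  truth <- unique(gt[, c("specimen_id", "true_group")])
  expect_equal(agg$subgroup,
               truth$true_group[match(agg$specimen_id, truth$specimen_id)])
  expect_equal(nrow(st$exclusions), 0L)
  expect_s3_class(st, "villous_study")
  tab <- summary(st)
  expect_true(all(c("mpa", "mt", "ml", "msa", "mv") %in% tab$metric))
})

test_that("identical cloned trees in both groups give omnibus p = 1", {
  dir <- file.path(tempdir(), "clone_cohort")
  dir.create(dir, showWarnings = FALSE)
  set.seed(9)
  g <- generate_tree(default_profiles()$IUGR, "clone")
  for (i in 1:8) write_swc(g$tree, file.path(dir, sprintf("c%d.swc", i)))
  man <- data.frame(specimen_id = sprintf("C%02d", 1:8),
                    group = rep(c("IUGR", "normal"), each = 4),
                    swc_path = sprintf("c%d.swc", 1:8))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  st <- suppressWarnings(run_study(file.path(dir, "manifest.csv"),
                                   dip_n_boot = 1000, seed = 5))
  for (ts in st$tests) {
    if (!is.null(ts$two_group)) {
      expect_equal(ts$two_group$kw$p.value, 1)
      expect_equal(ts$two_group$t$p.value, 1)
    }
  }
  unlink(dir, recursive = TRUE)
})

test_that("unreadable trees are excluded with a reason, not fatal", {
  dir <- file.path(tempdir(), "bad_cohort")
  dir.create(dir, showWarnings = FALSE)
  set.seed(10)
  for (i in 1:6) {
    g <- generate_tree(default_profiles()$`LT-normal`, paste0("s", i))
    write_swc(g$tree, file.path(dir, sprintf("s%d.swc", i)))
  }
  writeLines("1 0 0 0 0 0 -1", file.path(dir, "s1.swc"))  # zero radius
  man <- data.frame(specimen_id = sprintf("S%d", 1:6),
                    group = c(rep("IUGR", 3), rep("normal", 3)),
                    swc_path = sprintf("s%d.swc", 1:6))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_warning(st <- run_study(file.path(dir, "manifest.csv"),
                                 dip_n_boot = 1000, seed = 5),
                 "excluded")
  expect_equal(st$exclusions$specimen_id, "S1")
  expect_equal(nrow(st$aggregates), 5L)
  unlink(dir, recursive = TRUE)
})

test_that("reports are a pure function of inputs and configuration", {
  out1 <- file.path(tempdir(), "rep1")
  out2 <- file.path(tempdir(), "rep2")
  st1 <- run_study(file.path(study_dir, "manifest.csv"), out_dir = out1,
                   dip_n_boot = 1000, seed = 5)
  st2 <- run_study(file.path(study_dir, "manifest.csv"), out_dir = out2,
                   dip_n_boot = 1000, seed = 5)
  for (f in c("report.json", "aggregates.csv", "branch_metrics.csv")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("validate_tree reports counts for good trees, reasons for bad", {
  d <- validate_tree(y_tree_swc())
  expect_length(d$violations, 0L)
  expect_equal(d$n_branches, 3L)
  expect_equal(d$n_terminals, 2L)
  expect_equal(d$n_nodes, 1L)
  expect_equal(as.integer(d$order_histogram), c(2L, 1L))
  orphan <- write_swc_text(c("1 0 0 0 0 5 -1", "2 0 0 0 5 5 9"))
  expect_match(validate_tree(orphan)$violations, "parent id", all = FALSE)
  empty <- write_swc_text("# nothing")
  expect_equal(validate_tree(empty)$violations, "no points")
})
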