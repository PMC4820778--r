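test_that("Kruskal-Wallis H matches the hand-ranked value and kruskal.test", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(kw$statistic), 3.8571428571, tolerance = 1e-9)
  expect_equal(kw$p.value, 0.0495346134, tolerance = 1e-8)
  # identical groups: H = 0, p = 1 under the tie convention
  kw0 <- kruskal_wallis(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(unname(kw0$statistic), 0)
  # fully tied data
  expect_equal(kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))$p.value, 1)
  # against stats::kruskal.test on tied random data
  set.seed(4)
  for (i in 1:10) {
    x <- round(rnorm(24), 1)
    g <- sample(rep(c("a", "b", "c"), 8))
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Dunn z ordering follows mean-rank gaps; identical groups give p 1", {
  d <- dunn_posthoc(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  tab <- d$table
  ac <- abs(tab$z[tab$group_i == "a" & tab$group_j == "c"])
  expect_equal(which.max(abs(tab$z)),
               which(tab$group_i == "a" & tab$group_j == "c"))
  expect_true(all(abs(tab$z) <= ac + 1e-12))
  d0 <- dunn_posthoc(rep(c(1, 2), 3), rep(c("a", "b", "c"), each = 2))
  expect_true(all(d0$table$p_adj == 1))
  expect_error(dunn_posthoc(1:4, rep(c("a", "b"), 2)), ">= 3 groups")
})

test_that("Dunn adjustment equals p.adjust on the raw pairwise p-values", {
  set.seed(8)
  x <- rnorm(15); g <- rep(c("a", "b", "c"), each = 5)
  for (adj in c("bonferroni", "holm", "none")) {
    d <- dunn_posthoc(x, g, adjust = adj)
    expect_equal(d$table$p_adj, p.adjust(d$table$p_raw, adj))
    expect_true(all(d$table$p_adj >= d$table$p_raw - 1e-15))
  }
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(12)
  x <- rnorm(18); g <- rep(c("a", "b", "c"), each = 6)
  f <- function(v) exp(3 * v) - 2
  expect_equal(unname(kruskal_wallis(x, g)$statistic),
               unname(kruskal_wallis(f(x), g)$statistic))
  expect_equal(dunn_posthoc(x, g)$table$z, dunn_posthoc(f(x), g)$table$z)
})

test_that("pooled t matches the textbook value and handles degeneracy", {
  tt <- two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(unname(tt$statistic), -2.1908902300, tolerance = 1e-9)
  expect_equal(tt$p.value, 0.0709876543, tolerance = 1e-8)
  # identical samples
  t0 <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)
  # separated constants: p -> 0, flagged
  ts <- two_sample_t(c(0, 0, 0), c(1, 1, 1))
  expect_equal(ts$p.value, 0)
  expect_match(ts$method, "degenerate")
  # near-separation with tiny jitter
  tj <- two_sample_t(c(0, 1e-9, 0, -1e-9), c(1, 1 + 1e-9, 1, 1 - 1e-9))
  expect_lt(tj$p.value, 1e-10)
  # Welch variant agrees with t.test
  set.seed(3)
  a <- rnorm(8); b <- rnorm(6, 1, 2)
  expect_equal(two_sample_t(a, b, welch = TRUE)$p.value,
               t.test(a, b)$p.value)
})

test_that("permutation p-values agree with exact enumeration at small n", {
  # groups of (4,4,4): all 34650 assignments enumerable exactly
  set.seed(21)
  x <- c(rnorm(4), rnorm(4, 1.5), rnorm(4, 0.7))
  g <- rep(c("a", "b", "c"), each = 4)
  r <- rank(x)
  asg <- enumerate_assignments(c(4L, 4L, 4L))
  hstat <- function(rr) {
    Rs <- vapply(rr, function(ix) sum(r[ix]), numeric(1))
    12 / (12 * 13) * sum(Rs^2 / 4) - 3 * 13
  }
  h_obs <- hstat(list(1:4, 5:8, 9:12))
  h_all <- vapply(asg, hstat, numeric(1))
  p_exact <- mean(h_all >= h_obs - 1e-12)
  kw <- kruskal_wallis(x, g, p_method = "permutation", n_perm = 4000,
                       seed = 99)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(kw$p.value - p_exact), 3 * se + 1e-12)
})

test_that("significance stars follow the figure convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})
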