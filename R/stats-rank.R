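#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected Kruskal-Wallis H with midranks.  The p-value comes from
#' the chi-square approximation with `groups - 1` degrees of freedom
#' (default) or from a seeded label-permutation null, which is preferable
#' for the small per-group n typical of placenta cohort studies.
#'
#' @param values numeric observations (one per specimen).
#' @param groups group labels, coercible to factor; every group must be
#'   non-empty.
#' @param p_method `"chisq"` for the chi-square approximation,
#'   `"permutation"` for a Monte-Carlo permutation p-value.
#' @param n_perm number of label permutations when
#'   `p_method = "permutation"`.
#' @param seed optional integer seed for the permutation draw (the
#'   caller's RNG state is preserved).
#' @return An object of class `htest` with the tie-corrected statistic
#'   `H`, degrees of freedom and p-value.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(values, groups,
                           p_method = c("chisq", "permutation"),
                           n_perm = 10000, seed = NULL) {
  p_method <- match.arg(p_method)
  g <- .check_grouped(values, groups, min_groups = 2L)
  values <- g$values; groups <- g$groups
  k <- nlevels(groups)
  N <- length(values)
  r <- rank(values)
  H <- .kw_h(r, groups, N)
  if (p_method == "chisq") {
    p <- pchisq(H, df = k - 1L, lower.tail = FALSE)
    if (is.na(p)) p <- 1  # fully tied data: H = 0/0 treated as no evidence
  } else {
    p <- .with_seed(seed, {
      ge <- 0L
      for (b in seq_len(n_perm))
        if (.kw_h(sample(r), groups, N) >= H - 1e-12) ge <- ge + 1L
      ge / n_perm
    })
  }
  if (is.nan(H)) H <- 0
  structure(list(statistic = c(`Kruskal-Wallis H` = H),
                 parameter = c(df = k - 1L), p.value = p,
                 method = paste0("Kruskal-Wallis rank sum test (",
                                 if (p_method == "chisq") "chi-square"
                                 else sprintf("%d permutations", n_perm),
                                 " p-value)"),
                 data.name = deparse1(substitute(values))),
            class = "htest")
}

.kw_h <- function(r, groups, N) {
  Rs <- tapply(r, groups, sum)
  ns <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rs^2 / ns) - 3 * (N + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0)  # all observations tied
  H / corr
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the joint midranks after a Kruskal-Wallis
#' test, with the standard tie correction in the denominator:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups.  Two-sided p-values per pair
#' (normal approximation, or a seeded permutation null), with multiplicity
#' adjustment over all pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjust multiplicity adjustment over the pairs: `"bonferroni"`
#'   (default), `"holm"` or `"none"`.
#' @return An object of class `dunn_test`: a list with the pairwise table
#'   (`group_i`, `group_j`, `z`, `p_raw`, `p_adj`, `stars`), the
#'   adjustment method and group sizes.
#' @export
dunn_posthoc <- function(values, groups,
                         adjust = c("bonferroni", "holm", "none"),
                         p_method = c("normal", "permutation"),
                         n_perm = 10000, seed = NULL) {
  adjust <- match.arg(adjust)
  p_method <- match.arg(p_method)
  g <- .check_grouped(values, groups, min_groups = 2L)
  values <- g$values; groups <- g$groups
  k <- nlevels(groups)
  if (k < 3L)
    stop("Dunn's test needs >= 3 groups; use the omnibus test for 2 groups")
  N <- length(values)
  r <- rank(values)
  zs <- .dunn_z(r, groups, N)
  pairs <- t(utils::combn(levels(groups), 2L))
  p_raw <- 2 * pnorm(-abs(zs))
  if (p_method == "permutation") {
    p_raw <- .with_seed(seed, {
      ge <- integer(length(zs))
      for (b in seq_len(n_perm)) {
        zb <- .dunn_z(sample(r), groups, N)
        ge <- ge + (abs(zb) >= abs(zs) - 1e-12)
      }
      ge / n_perm
    })
  }
  p_adj <- p.adjust(p_raw, method = adjust)
  tab <- data.frame(group_i = pairs[, 1L], group_j = pairs[, 2L],
                    z = zs, p_raw = p_raw, p_adj = p_adj,
                    stars = significance_stars(p_adj),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, adjust = adjust,
                 n = tabulate(groups), levels = levels(groups),
                 p_method = p_method),
            class = "dunn_test")
}

.dunn_z <- function(r, groups, N) {
  Rbar <- tapply(r, groups, mean)
  ns <- tabulate(groups)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  idx <- utils::combn(seq_along(Rbar), 2L)
  se <- sqrt(v * (1 / ns[idx[1L, ]] + 1 / ns[idx[2L, ]]))
  z <- (Rbar[idx[1L, ]] - Rbar[idx[2L, ]]) / se
  z[se == 0] <- 0
  as.numeric(z)
}

#' @export
print.dunn_test <- function(x, ...) {
  cat("Dunn's pairwise comparisons (", x$p_method, " p, ",
      x$adjust, " adjustment)\n", sep = "")
  tab <- x$table
  tab$z <- round(tab$z, 3)
  tab$p_raw <- signif(tab$p_raw, 3)
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Two-sample Student's t test
#'
#' Pooled-variance Student's t (default) or Welch's variant, two-sided.
#' Degenerate zero-variance cases follow the conventions: equal constant
#' samples give `t = 0, p = 1`; distinct constant samples give the
#' separation limit `p = 0` with an infinite statistic (flagged in the
#' method string).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param welch use the Welch unequal-variance form.
#' @return An object of class `htest`.
#' @export
two_sample_t <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L,
            all(is.finite(a)), all(is.finite(b)))
  if (sd(a) == 0 && sd(b) == 0) {
    sep <- mean(a) != mean(b)
    return(structure(list(
      statistic = c(t = if (sep) sign(mean(a) - mean(b)) * Inf else 0),
      parameter = c(df = length(a) + length(b) - 2),
      p.value = if (sep) 0 else 1,
      estimate = c(`mean of x` = mean(a), `mean of y` = mean(b)),
      method = paste("Two Sample t-test",
                     if (sep) "(degenerate: zero variance, distinct means)"
                     else "(degenerate: identical constant samples)"),
      data.name = "a and b"), class = "htest"))
  }
  t.test(a, b, var.equal = !welch)
}

#' Significance stars
#'
#' Maps p-values to the star convention used in the figures:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param p numeric vector of p-values.
#' @return Character vector of stars (`""` for p >= 0.05).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

.check_grouped <- function(values, groups, min_groups = 2L) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (!all(is.finite(values))) stop("values must be finite")
  if (nlevels(groups) < min_groups)
    stop("need at least ", min_groups, " non-empty groups")
  if (any(tabulate(groups) == 0L)) stop("empty group")
  list(values = values, groups = groups)
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}
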