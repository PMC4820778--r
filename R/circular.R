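#' Rose histogram of branching angles
#'
#' Bins angles into sectors of `bin_width` degrees starting at 0, the
#' binning used for rose diagrams.  Branching angles live in \[0, 180\];
#' the sector grid covers the full circle so the object can be drawn as a
#' standard rose diagram.
#'
#' @param angles numeric angles in degrees in `[0, 180]`.
#' @param bin_width sector width in degrees; must divide 360.
#' @return An object of class `rose_histogram`: list with `breaks`
#'   (sector edges), `counts` and `n`.
#' @export
#' @examples
#' rose_histogram(c(45, 45, 52, 66), bin_width = 10)
rose_histogram <- function(angles, bin_width = 10) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no angles")
  stopifnot(all(angles >= 0 & angles <= 180))
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  breaks <- seq(0, 360, by = bin_width)
  idx <- pmin(floor(angles / bin_width) + 1L, length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts, n = length(angles)),
            class = "rose_histogram")
}

#' @export
print.rose_histogram <- function(x, ...) {
  nz <- which(x$counts > 0)
  cat("<rose_histogram> n = ", x$n, "\n", sep = "")
  for (i in nz)
    cat(sprintf("  [%3g, %3g): %d\n", x$breaks[i], x$breaks[i + 1L],
                x$counts[i]))
  invisible(x)
}

#' @param x a `rose_histogram`.
#' @param col fill colour of the sectors.
#' @param main plot title.
#' @param ... ignored.
#' @rdname rose_histogram
#' @export
plot.rose_histogram <- function(x, col = "steelblue", main = "", ...) {
  r <- sqrt(x$counts / max(x$counts))  # area-proportional sectors
  op <- par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(par(op))
  plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), axes = FALSE,
       xlab = "", ylab = "", main = main, asp = 1)
  th <- seq(0, 2 * pi, length.out = 200)
  lines(cos(th), sin(th), col = "grey70")
  for (a in seq(0, 330, by = 30)) {
    segments(0, 0, cos(a * pi / 180), sin(a * pi / 180), col = "grey85")
    text(1.08 * cos(a * pi / 180), 1.08 * sin(a * pi / 180), a, cex = 0.7)
  }
  for (i in seq_along(x$counts)) {
    if (x$counts[i] == 0) next
    a0 <- x$breaks[i] * pi / 180
    a1 <- x$breaks[i + 1L] * pi / 180
    th <- seq(a0, a1, length.out = 20)
    polygon(c(0, r[i] * cos(th)), c(0, r[i] * sin(th)),
            col = col, border = "white")
  }
  invisible(x)
}

#' Modes of an angular sample
#'
#' Locates the frequency maxima of branching-angle data: local maxima of
#' a wrapped (circular, period 360 degrees) Gaussian kernel density,
#' evaluated on a 1-degree grid over \[0, 180\].  Maxima closer together
#' than the bandwidth are merged into the higher one, so the result never
#' contains two modes within one bandwidth.
#'
#' @param angles numeric angles in degrees in `[0, 180]`, `length >= 1`.
#' @param bandwidth kernel standard deviation in degrees.
#' @return Numeric vector of mode locations in degrees, ascending.
#' @export
#' @examples
#' angular_modes(c(rnorm(40, 52, 2), rnorm(40, 66, 2)), bandwidth = 4)
angular_modes <- function(angles, bandwidth = 4) {
  angles <- angles[!is.na(angles)]
  if (!length(angles)) stop("no angles")
  stopifnot(all(angles >= 0 & angles <= 180), bandwidth > 0)
  grid <- 0:180
  f <- rowSums(vapply(c(-360, 0, 360), function(off)
    rowSums(outer(grid, angles + off, function(g, a)
      dnorm(g, a, bandwidth))), numeric(length(grid))))
  # local maxima on the grid (plateau-tolerant, endpoints allowed)
  left <- c(-Inf, f[-length(f)])
  right <- c(f[-1L], -Inf)
  cand <- which(f > left & f >= right)
  if (!length(cand)) cand <- which.max(f)
  # merge candidates closer than the bandwidth, keeping the higher
  ord <- cand[order(-f[cand])]
  kept <- numeric(0)
  for (i in ord) {
    if (!length(kept) || all(abs(grid[i] - kept) >= bandwidth))
      kept <- c(kept, grid[i])
  }
  sort(kept)
}
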