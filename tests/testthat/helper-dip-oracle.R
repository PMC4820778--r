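# Brute-force dip oracle: minimize the band half-width d over explicit
# piecewise-linear unimodal CDF fits by linear programming (boot::simplex).
# The mode is placed at every data point (exact, with the atom the unimodal
# class allows there) and on a grid inside every gap.  Independent of the
# package's hull-based computation.

dip_oracle <- function(x, n_grid = 10) {
  x <- sort(x); n <- length(x)
  u <- unique(x); m <- length(u)
  if (m == 1L) return(0)
  Fk <- cumsum(tabulate(match(x, u), m)) / n
  Fp <- c(0, Fk[-m])
  nv <- m + 3L
  ia <- m + 1L; ib <- m + 2L; idd <- m + 3L

  solve_cfg <- function(s, mu, at_point) {
    A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
    ge <- function(row, rhs) {
      if (rhs >= 0) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
      else { A1 <<- rbind(A1, -row); b1 <<- c(b1, -rhs) }
    }
    for (k in 1:m) {
      if (at_point && k == s + 1L) next
      r <- numeric(nv); r[k] <- 1; r[idd] <- 1; ge(r, Fk[k])
      r <- numeric(nv); r[k] <- -1; r[idd] <- 1; ge(r, -Fp[k])
      r <- numeric(nv); r[k] <- -1; ge(r, -1)
    }
    FL <- if (at_point) Fp[s + 1L] else Fk[s]
    FB <- if (at_point) Fk[s + 1L] else Fk[s]
    r <- numeric(nv); r[ia] <- -1; r[idd] <- 1; ge(r, -FL)
    r <- numeric(nv); r[ia] <- 1; r[idd] <- 1; ge(r, FL)
    r <- numeric(nv); r[ib] <- -1; r[idd] <- 1; ge(r, -FB)
    r <- numeric(nv); r[ib] <- 1; r[idd] <- 1; ge(r, FB)
    r <- numeric(nv); r[ib] <- 1; r[ia] <- -1; ge(r, 0)
    chain_left <- c(seq_len(s), ia)
    xl <- c(u[seq_len(s)], mu)
    first_right <- if (at_point) s + 2L else s + 1L
    chain_right <- c(ib, if (first_right <= m) first_right:m)
    xr <- c(mu, if (first_right <= m) u[first_right:m])
    mono <- function(idx) {
      if (length(idx) < 2L) return()
      for (k in 1:(length(idx) - 1L)) {
        r <- numeric(nv); r[idx[k + 1L]] <- 1; r[idx[k]] <- -1; ge(r, 0)
      }
    }
    mono(chain_left); mono(chain_right)
    if (length(chain_left) >= 3L) for (k in 2:(length(chain_left) - 1L)) {
      i1 <- chain_left[k - 1L]; i2 <- chain_left[k]; i3 <- chain_left[k + 1L]
      h1 <- xl[k] - xl[k - 1L]; h2 <- xl[k + 1L] - xl[k]
      r <- numeric(nv); r[i3] <- 1 / h2; r[i2] <- -1 / h2 - 1 / h1
      r[i1] <- 1 / h1; ge(r, 0)
    }
    if (length(chain_right) >= 3L) for (k in 2:(length(chain_right) - 1L)) {
      i1 <- chain_right[k - 1L]; i2 <- chain_right[k]; i3 <- chain_right[k + 1L]
      h1 <- xr[k] - xr[k - 1L]; h2 <- xr[k + 1L] - xr[k]
      r <- numeric(nv); r[i1] <- -1 / h1; r[i2] <- 1 / h1 + 1 / h2
      r[i3] <- -1 / h2; ge(r, 0)
    }
    obj <- numeric(nv); obj[idd] <- 1
    res <- try(boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                             maxi = FALSE), silent = TRUE)
    if (inherits(res, "try-error") || res$solved != 1) return(Inf)
    res$value
  }

  best <- Inf
  for (t in 1:m)
    best <- min(best, solve_cfg(t - 1L, u[t], TRUE))
  if (m >= 2L) for (s in 1:(m - 1L))
    for (fr in seq(0.03, 0.97, length.out = n_grid))
      best <- min(best, solve_cfg(s, u[s] + fr * (u[s + 1L] - u[s]), FALSE))
  best
}
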