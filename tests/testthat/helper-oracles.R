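# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force loops, closed forms, and dense
# zero-temperature steepest descent.

kT0 <- stringpmf::thermal_energy()

# simple quadratic bowl for engine tests
quad_pot <- function(k = 2, d = 2) {
  model_potential(list(harmonic_term(rep(0, d), rep(k, d))),
                  domain = matrix(rep(c(-10, 10), each = d), 2, d,
                                  byrow = TRUE),
                  wall_height = 0)
}

flat_pot <- function(d = 2, lim = 10) {
  model_potential(list(), domain = matrix(rep(c(-lim, lim), each = d), 2, d,
                                          byrow = TRUE), wall_height = 0)
}

# dense zero-temperature string: plain gradient descent of a 201-point path
# with equal-arc redistribution each sweep; the MFEP oracle for the
# swarm-based string method
oracle_mfep <- function(pot, a, b, n = 201, h = 2e-3, iters = 3000) {
  path <- cbind(seq(a[1], b[1], length.out = n),
                seq(a[2], b[2], length.out = n))
  for (it in seq_len(iters)) {
    g <- evaluate_potential(pot, path, check_domain = FALSE)$gradient
    path <- path - h * g
    path[1, ] <- a
    path[n, ] <- b
    seg <- sqrt(rowSums((path[-1, , drop = FALSE] - path[-n, , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    tgt <- seq(0, s[n], length.out = n)
    path <- apply(path, 2, function(col) approx(s, col, tgt, ties = "ordered")$y)
  }
  path
}

descend_to_minimum <- function(pot, x, h = 1e-3, iters = 3000) {
  for (i in seq_len(iters)) x <- x - h * evaluate_potential(pot, x)$gradient
  x
}

# distance of each point to the nearest vertex of a dense path
dist_to_path <- function(pts, path) {
  d2 <- outer(rowSums(pts^2), rowSums(path^2), `+`) - 2 * pts %*% t(path)
  sqrt(pmax(0, apply(d2, 1, min)))
}

# Independent WHAM oracle: the self-consistency equations are the
# stationarity conditions of the convex objective
#   F(g) = sum_i N_i g_i - sum_b c_b log( sum_i N_i e^{g_i - beta w_i(b)} ),
# g_i = beta f_i. Maximizing F with BFGS (analytic gradient) is a genuinely
# different algorithm from the package's fixed-point iteration.
oracle_wham_loglik <- function(series_list, windows, bin_size, range,
                               temperature = 298.15) {
  kT <- stringpmf::thermal_energy(temperature)
  centers <- as.matrix(windows[, grep("^c[0-9]", names(windows)), drop = FALSE])
  ks <- as.matrix(windows[, grep("^k[0-9]", names(windows)), drop = FALSE])
  edges <- seq(range[1], range[2], by = bin_size)
  mids <- (head(edges, -1) + tail(edges, -1)) / 2
  counts <- sapply(series_list, function(s) {
    x <- if (inherits(s, "biased_series")) s$series[, 1] else as.matrix(s)[, 1]
    i <- findInterval(x, edges, rightmost.closed = TRUE)
    tabulate(i[i >= 1 & i <= length(mids)], nbins = length(mids))
  })
  N <- colSums(counts)
  w <- sapply(seq_len(nrow(centers)), function(i)
    0.5 * ks[i, 1] * (mids - centers[i, 1])^2)   # n_bins x n_windows
  c_tot <- rowSums(counts)
  E <- exp(-w / kT)                              # n_bins x n_windows
  negF <- function(g2) {
    g <- c(0, g2)
    den <- as.numeric(E %*% (N * exp(g)))
    -(sum(N * g) - sum(c_tot[c_tot > 0] * log(den[c_tot > 0])))
  }
  gradF <- function(g2) {
    g <- c(0, g2)
    den <- as.numeric(E %*% (N * exp(g)))
    r <- ifelse(c_tot > 0, c_tot / den, 0)
    gr <- N - (N * exp(g)) * as.numeric(t(E) %*% r)
    -gr[-1]
  }
  opt <- optim(rep(0, length(N) - 1), negF, gradF, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  g <- c(0, opt$par)
  den <- as.numeric(E %*% (N * exp(g)))
  p <- ifelse(c_tot > 0, c_tot / den, NA_real_)
  p <- p / sum(p, na.rm = TRUE)
  pmf <- -kT * log(p)
  list(pmf = pmf - min(pmf, na.rm = TRUE), mids = mids, f = kT * g)
}
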