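# Weighted histogram analysis. The solver iterates the standard WHAM
# self-consistency equations
#   p(b)          = sum_i n_i(b) / sum_i N_i exp(-beta [w_i(b) - f_i])
#   exp(-beta f_i) = sum_b p(b) exp(-beta w_i(b))
# from f_i = 0 (p-step first), converging on max |delta f_i| below the
# tolerance (0.001 kcal/mol by default, the convention of common WHAM
# programs). Bias energies are evaluated at bin centers; empty bins are
# masked, never smoothed. Works for 1D and 2D collective-variable spaces.

bin_index <- function(x, edges) {
  # half-open [edge, edge+delta), right-most bin closed
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

wham_prepare <- function(series_list, windows, bin_size, range, cv_names) {
  centers <- window_centers(windows)
  ks <- window_ks(windows)
  d <- ncol(centers)
  stopifnot(length(series_list) == nrow(windows))
  smat <- lapply(series_list, function(s) {
    m <- if (inherits(s, "biased_series")) s$series else as.matrix(s)
    stopifnot(all(is.finite(m)), ncol(m) == d)
    m
  })
  if (is.null(range)) {
    all_pts <- do.call(rbind, smat)
    range <- rbind(apply(all_pts, 2, min), apply(all_pts, 2, max))
  }
  bin_size <- rep_len(bin_size, d)
  edges <- lapply(seq_len(d), function(j)
    axis_edges(range[1, j], range[2, j], bin_size[j]))
  nb <- vapply(edges, length, integer(1)) - 1L
  n_bins <- prod(nb)
  # flat bin index, first axis fastest
  flat_index <- function(m) {
    idx <- bin_index(m[, 1], edges[[1]])
    if (d == 2) {
      i2 <- bin_index(m[, 2], edges[[2]])
      idx <- idx + (i2 - 1L) * nb[1]
      idx[is.na(i2)] <- NA_integer_
    }
    idx
  }
  counts <- vapply(smat, function(m) {
    fi <- flat_index(m)
    tabulate(fi[!is.na(fi)], nbins = n_bins)
  }, numeric(n_bins))                       # n_bins x n_windows
  N <- colSums(counts)
  # bias at bin centers: n_windows x n_bins
  ctr <- lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  grid <- if (d == 1) matrix(ctr[[1]], ncol = 1)
  else cbind(rep(ctr[[1]], times = nb[2]), rep(ctr[[2]], each = nb[1]))
  w <- matrix(0, nrow(windows), n_bins)
  for (i in seq_len(nrow(windows))) {
    dev <- sweep(grid, 2, centers[i, ])
    w[i, ] <- as.numeric(dev^2 %*% (ks[i, ] / 2))
  }
  axes <- lapply(seq_len(d), function(j)
    list(name = cv_names[j] %||% paste0("cv", j), edges = edges[[j]]))
  list(counts = counts, N = N, w = w, nb = nb, axes = axes, d = d)
}

check_window_overlap <- function(counts) {
  nw <- ncol(counts)
  if (nw == 1) return(invisible(TRUE))
  occupied <- counts > 0
  # union-find over windows sharing at least one sampled bin
  parent <- seq_len(nw)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (b in which(rowSums(occupied) > 1)) {
    ws <- which(occupied[b, ])
    r <- find(ws[1])
    for (wj in ws[-1]) parent[find(wj)] <- r
  }
  roots <- vapply(seq_len(nw), find, integer(1))
  comps <- split(seq_len(nw), roots)
  if (length(comps) > 1)
    stop(sprintf(
      "window histograms are disconnected: %d components (%s)",
      length(comps),
      paste(vapply(comps, function(x)
        paste0("{", paste(head(x, 6), collapse = ","),
               if (length(x) > 6) ",..." else "", "}"), character(1)),
        collapse = " ")))
  invisible(TRUE)
}

#' Reconstruct a PMF from umbrella-sampling data by WHAM
#'
#' @param series_list List of `biased_series` (or plain sample matrices),
#'   one per window, in the order of `windows`.
#' @param windows The `umbrella_windows` grid the series were sampled
#'   under.
#' @param bin_size Histogram bin width in Angstrom (default 0.25 on every
#'   axis, independent of the window spacing).
#' @param tolerance Convergence tolerance on the window free-energy
#'   constants, kcal/mol (default 0.001).
#' @param range Optional 2 x d matrix of histogram bounds; defaults to the
#'   sampled range.
#' @param temperature Kelvin.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @param cv_names Optional axis names.
#' @return A [pmf_surface()], min-shifted to zero over sampled bins, with
#'   unsampled bins masked. The per-window free-energy constants are
#'   attached as attribute `f`.
#' @export
wham_2d <- function(series_list, windows, bin_size = 0.25, tolerance = 0.001,
                    range = NULL, temperature = .default_temperature,
                    max_iter = 100000L, cv_names = NULL) {
  prep <- wham_prepare(series_list, windows, bin_size, range,
                       cv_names %||% prep_default_names(series_list))
  check_window_overlap(prep$counts)
  kT <- thermal_energy(temperature)
  c_tot <- rowSums(prep$counts)              # total counts per bin
  sampled <- c_tot > 0
  N <- prep$N
  keep_w <- N > 0
  if (!any(keep_w)) stop("all windows are empty")
  M <- exp(-prep$w[keep_w, , drop = FALSE] / kT)   # n_w x n_bins
  Nw <- N[keep_w]
  f <- rep(0, length(Nw))
  delta_prev <- Inf
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(crossprod(M, Nw * exp(f / kT)))  # sum_i N_i e^{bf_i} e^{-bw_i(b)}
    p <- ifelse(sampled & denom > 0, c_tot / denom, 0)
    p <- p / sum(p)
    f_new <- -kT * log(as.numeric(M %*% p))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    # The fixed point is approached geometrically with contraction rho that
    # can sit very close to 1 for long window chains, so the per-iteration
    # change understates the remaining error by a factor rho/(1 - rho).
    # Stop on the geometric-extrapolation bound, not on delta itself.
    rho <- min(delta / delta_prev, 1 - 1e-6)
    delta_prev <- delta
    err_bound <- if (it > 1) delta * rho / (1 - rho) else delta
    if (err_bound < tolerance || delta == 0) break
    if (it == max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                   max_iter, delta))
  }
  denom <- as.numeric(crossprod(M, Nw * exp(f / kT)))
  p <- ifelse(sampled & denom > 0, c_tot / denom, NA_real_)
  vals <- -kT * log(p)
  if (prep$d == 2) {
    vals <- matrix(vals, prep$nb[1], prep$nb[2])
    counts <- matrix(c_tot, prep$nb[1], prep$nb[2])
  } else counts <- c_tot
  out <- pmf_surface(vals, prep$axes, temperature = temperature)
  attr(out, "f") <- f
  attr(out, "counts") <- counts
  out
}

prep_default_names <- function(series_list) {
  s1 <- series_list[[1]]
  m <- if (inherits(s1, "biased_series")) s1$series else as.matrix(s1)
  colnames(m) %||% paste0("cv", seq_len(ncol(m)))
}

#' Per-bin block errors of a WHAM PMF
#'
#' Every window's series is split into `n_blocks` contiguous equal-length
#' blocks (preserving autocorrelation structure within a block), WHAM is
#' solved per block, each block PMF is min-shifted, and the per-bin
#' standard deviation across blocks is reported. Bins masked in any block
#' are masked in the error map.
#'
#' @inheritParams wham_2d
#' @param n_blocks Number of contiguous blocks (default 3).
#' @return A [pmf_surface()] like the full-data solution, with `errors`
#'   filled in.
#' @export
block_errors <- function(series_list, windows, n_blocks = 3, bin_size = 0.25,
                         tolerance = 0.001, range = NULL,
                         temperature = .default_temperature,
                         max_iter = 100000L, cv_names = NULL) {
  get_mat <- function(s) if (inherits(s, "biased_series")) s$series else as.matrix(s)
  lens <- vapply(series_list, function(s) nrow(get_mat(s)), integer(1))
  if (any(lens < n_blocks)) {
    bad <- which(lens < n_blocks)[1]
    stop(sprintf("series for window %d has %d samples, fewer than %d blocks",
                 bad, lens[bad], n_blocks))
  }
  if (is.null(range)) {   # common grid across blocks and full solution
    all_pts <- do.call(rbind, lapply(series_list, get_mat))
    range <- rbind(apply(all_pts, 2, min), apply(all_pts, 2, max))
  }
  full <- wham_2d(series_list, windows, bin_size, tolerance, range,
                  temperature, max_iter, cv_names)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    sl <- lapply(series_list, function(s) {
      m <- get_mat(s)
      n <- nrow(m)
      size <- floor(n / n_blocks)
      m[((b - 1) * size + 1):(b * size), , drop = FALSE]
    })
    wham_2d(sl, windows, bin_size, tolerance, range, temperature, max_iter,
            cv_names)
  })
  stack <- vapply(blocks, function(p) as.numeric(p$values),
                  numeric(length(full$values)))
  errs <- apply(stack, 1, function(v) if (anyNA(v)) NA_real_ else sd(v))
  full$errors <- if (is.matrix(full$values))
    matrix(errs, nrow(full$values), ncol(full$values)) else errs
  full
}

#' Strip-integrate a 2D PMF to a 1D profile
#'
#' `W1(x) = -kBT log sum_{y in strip} exp(-W2(x, y)/kBT) * dy` over sampled
#' bins, then min-shifted to zero. Columns with no sampled bin inside the
#' strip are masked.
#'
#' @param pmf2d A 2D [pmf_surface()].
#' @param kept_axis Axis to keep (1 or 2).
#' @param strip Length-2 range on the other axis; bins whose centers fall
#'   inside are integrated.
#' @return A 1D [pmf_surface()].
#' @export
integrate_1d <- function(pmf2d, kept_axis = 1, strip) {
  stopifnot(inherits(pmf2d, "pmf_surface"), length(pmf2d$axes) == 2,
            kept_axis %in% 1:2, length(strip) == 2, strip[2] > strip[1])
  other <- 3L - as.integer(kept_axis)
  yc <- bin_centers(pmf2d, other)
  in_strip <- yc >= strip[1] & yc <= strip[2]
  if (!any(in_strip)) stop("strip overlaps no bins on the integration axis")
  kT <- thermal_energy(pmf2d$temperature)
  dy <- diff(pmf2d$axes[[other]]$edges)[1]
  vals <- pmf2d$values
  if (kept_axis == 2) vals <- t(vals)
  sub <- vals[, in_strip, drop = FALSE]
  if (all(is.na(sub))) stop("strip overlaps no sampled bins")
  w1 <- apply(sub, 1, function(row) {
    ok <- is.finite(row)
    if (!any(ok)) return(NA_real_)
    m <- min(row[ok])
    -kT * log(sum(exp(-(row[ok] - m) / kT)) * dy) + m
  })
  pmf_surface(w1, pmf2d$axes[kept_axis], temperature = pmf2d$temperature)
}
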