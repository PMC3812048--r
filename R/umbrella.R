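# Umbrella-window generation, seeding from string images, and biased
# sampling. Window-size defaults follow the workflow's configuration:
# 0.25 A along the thick-gate axis, 0.5 A along the other order parameters,
# force constant 5 kcal/mol/A^2, 14000 engine steps per window (the stand-in
# for 560 ps) with the first 60/560 of samples discarded.

#' Build a regular grid of umbrella windows
#'
#' Window centers spaced by `window_sizes` covering `bounds` inclusively,
#' in row-major order (first axis fastest). Bounds narrower than one window
#' give a single window at the midpoint.
#'
#' @param bounds 2 x d matrix of per-axis bounds (row 1 = lower, row 2 =
#'   upper), or a length-2 vector in 1D.
#' @param window_sizes Per-axis center spacing in Angstrom (default 0.25 on
#'   the first axis and 0.5 on the others).
#' @param force_constants Per-axis restraint stiffness, kcal/mol/A^2
#'   (default 5).
#' @return Object of class `umbrella_windows`: a data frame with center
#'   columns `c1..cd`, force constants `k1..kd`, and a `window` index.
#' @export
make_window_grid <- function(bounds, window_sizes = NULL,
                             force_constants = 5) {
  if (is.null(dim(bounds))) bounds <- matrix(bounds, nrow = 2)
  bounds <- as.matrix(bounds)
  d <- ncol(bounds)
  stopifnot(all(is.finite(bounds)))
  if (any(bounds[2, ] < bounds[1, ])) stop("inverted bounds")
  window_sizes <- rep_len(window_sizes %||% c(0.25, rep(0.5, max(0, d - 1))), d)
  force_constants <- rep_len(force_constants, d)
  stopifnot(all(window_sizes > 0), all(force_constants > 0))
  axes <- lapply(seq_len(d), function(j) {
    lo <- bounds[1, j]; hi <- bounds[2, j]
    if (hi - lo < window_sizes[j]) return((lo + hi) / 2)
    n <- ceiling((hi - lo) / window_sizes[j] - 1e-9)
    lo + (0:n) * window_sizes[j]
  })
  centers <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(centers) <- paste0("c", seq_len(d))
  df <- data.frame(window = seq_len(nrow(centers)), centers)
  for (j in seq_len(d)) df[[paste0("k", j)]] <- force_constants[j]
  attr(df, "window_sizes") <- window_sizes
  class(df) <- c("umbrella_windows", "data.frame")
  df
}

window_centers <- function(windows) {
  as.matrix(windows[, grep("^c[0-9]+$", names(windows)), drop = FALSE])
}

window_ks <- function(windows) {
  as.matrix(windows[, grep("^k[0-9]+$", names(windows)), drop = FALSE])
}

#' Select the seed image for an umbrella window
#'
#' Picks the string image whose CVs best match the window center. When an
#' image matches every axis within half a window size, the full-vector
#' nearest image is used; otherwise the image minimizing the distance on
#' the priority axis (the coordinate that needs longest to relax) wins.
#' Exact ties go to the lower image index.
#'
#' @param window_center Numeric window center (length d).
#' @param string A [transition_string()] or image matrix.
#' @param priority_axis Axis index given priority (default 1, the gate
#'   axis).
#' @param window_sizes Per-axis window sizes used for the "matches both
#'   axes" test (default 0.25/0.5).
#' @return The selected image index.
#' @export
select_seed_image <- function(window_center, string, priority_axis = 1,
                              window_sizes = NULL) {
  images <- if (inherits(string, "transition_string")) string$images
  else as.matrix(string)
  if (nrow(images) == 0) stop("string has no images")
  d <- ncol(images)
  window_sizes <- rep_len(window_sizes %||% c(0.25, rep(0.5, max(0, d - 1))), d)
  dev <- abs(sweep(images, 2, as.numeric(window_center)))
  full <- which(apply(sweep(dev, 2, window_sizes / 2, `<=`), 1, all))
  if (length(full)) {
    dist <- sqrt(rowSums(dev[full, , drop = FALSE]^2))
    return(full[which.min(dist)])
  }
  which.min(dev[, priority_axis])
}

#' Assign seed images for a window grid
#'
#' @param windows An `umbrella_windows` grid.
#' @param string A [transition_string()].
#' @inheritParams select_seed_image
#' @return The grid with a `seed_image` column.
#' @export
assign_seed_images <- function(windows, string, priority_axis = 1) {
  ws <- attr(windows, "window_sizes")
  centers <- window_centers(windows)
  windows$seed_image <- vapply(seq_len(nrow(centers)), function(i)
    select_seed_image(centers[i, ], string, priority_axis, ws), integer(1))
  windows
}

#' Sample one umbrella window
#'
#' Runs the Langevin engine under `potential` plus the window's harmonic
#' bias, starting from `start` (typically the seed image's state), and
#' discards the first `discard_fraction` of samples (default 60/560,
#' mirroring a 560 ps window of which the last 500 ps are kept).
#'
#' @param window One row of an `umbrella_windows` grid (or a list with
#'   `center` and `k`).
#' @param potential A [model_potential()].
#' @param settings A [langevin_settings()]; `n_steps` is the total window
#'   length (default 14000 when `settings$n_steps` is missing).
#' @param start Starting CV point.
#' @param discard_fraction Fraction of initial samples dropped, in [0, 1).
#' @return Object of class `biased_series`: list with `series` (matrix of
#'   kept samples), `center`, `k`, `samples_total`, `samples_discarded`,
#'   `seed`.
#' @export
sample_window <- function(window, potential, settings, start,
                          discard_fraction = 60 / 560) {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  if (is.data.frame(window)) {
    center <- as.numeric(window_centers(window)[1, ])
    k <- as.numeric(window_ks(window)[1, ])
  } else {
    center <- as.numeric(window$center)
    k <- rep_len(as.numeric(window$k), length(center))
  }
  bias <- harmonic_bias(center, k)
  traj <- tryCatch(
    propagate_langevin(start, potential, settings, bias),
    error = function(e) stop(sprintf("window at (%s): %s",
                                     paste(signif(center, 6), collapse = ", "),
                                     conditionMessage(e))))
  samples <- traj[-1, , drop = FALSE]   # drop the seed point itself
  total <- nrow(samples)
  n_drop <- floor(discard_fraction * total)
  kept <- samples[(n_drop + 1):total, , drop = FALSE]
  structure(list(series = kept, center = center, k = k,
                 samples_total = total, samples_discarded = n_drop,
                 seed = settings$seed),
            class = "biased_series")
}

#' Sample every window of a grid
#'
#' Orchestrates seeding and biased sampling for a window grid: each window
#' starts from its seed image's CVs and uses a per-window random stream
#' derived from `seed`.
#'
#' @param windows An `umbrella_windows` grid (seed images are assigned if
#'   missing).
#' @param potential A [model_potential()].
#' @param string A [transition_string()] supplying seed images.
#' @param settings A [langevin_settings()] template (its seed is ignored).
#' @param seed Master seed.
#' @param discard_fraction Passed to [sample_window()].
#' @return List of `biased_series`, one per window, in grid order.
#' @export
sample_windows <- function(windows, potential, string, settings, seed = 1L,
                           discard_fraction = 60 / 560) {
  if (is.null(windows$seed_image))
    windows <- assign_seed_images(windows, string)
  images <- if (inherits(string, "transition_string")) string$images
  else as.matrix(string)
  lapply(seq_len(nrow(windows)), function(i) {
    s <- settings
    s$seed <- derive_seed(seed, i)
    sample_window(windows[i, ], potential, s,
                  start = images[windows$seed_image[i], ],
                  discard_fraction = discard_fraction)
  })
}
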