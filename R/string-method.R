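# Minimum free energy path machinery: RMSD-steered path initialization,
# image chains, swarm-of-trajectories drift, constrained relaxation, equal
# arc-length reparametrization, and the 4-step string iteration with its
# convergence diagnostics. CV-space RMSD between two points is
# sqrt(mean((a - b)^2)) over CV components, unweighted.

cv_rmsd <- function(a, b) sqrt(mean((a - b)^2))

#' Ordered chain of path images
#'
#' @param images Matrix, one row per image, columns = collective variables.
#' @param endpoints_fixed Keep the first and last image immutable across
#'   string iterations (default TRUE; the endpoints are the known end
#'   states).
#' @param states Optional list of engine states (CV vectors) used to launch
#'   swarms; defaults to the image CVs themselves.
#' @return An object of class `transition_string`.
#' @export
transition_string <- function(images, endpoints_fixed = TRUE, states = NULL) {
  images <- as.matrix(images)
  stopifnot(nrow(images) >= 3, all(is.finite(images)))
  states <- states %||% lapply(seq_len(nrow(images)), function(i) images[i, ])
  structure(list(images = images, endpoints_fixed = endpoints_fixed,
                 states = states, iteration = 0L,
                 history = list(images), convergence = NULL),
            class = "transition_string")
}

#' @export
print.transition_string <- function(x, ...) {
  sp <- adjacent_rmsd(x$images)
  cat(sprintf("<transition_string> %d images, %dD, iteration %d\n",
              nrow(x$images), ncol(x$images), x$iteration))
  cat(sprintf("  mean adjacent-image RMSD %.4g A (max %.4g)\n",
              mean(sp), max(sp)))
  invisible(x)
}

adjacent_rmsd <- function(images) {
  n <- nrow(images)
  vapply(seq_len(n - 1), function(i) cv_rmsd(images[i, ], images[i + 1, ]),
         numeric(1))
}

#' Swarm settings for the string iteration
#'
#' @param n_trajectories Trajectories per swarm (default 100).
#' @param swarm_steps Engine steps per swarm trajectory (default 50, the
#'   configured stand-in for a 2 ps swarm).
#' @param relax_steps Steps of constrained relaxation per image (default
#'   1250, the stand-in for 50 ps).
#' @param relax_force_constant Harmonic constraint on the CVs during
#'   relaxation, kcal/mol/A^2 (default 40).
#' @return An object of class `swarm_settings`.
#' @export
swarm_settings <- function(n_trajectories = 100L, swarm_steps = 50L,
                           relax_steps = 1250L, relax_force_constant = 40) {
  stopifnot(n_trajectories >= 1, swarm_steps >= 1, relax_steps >= 1,
            relax_force_constant > 0)
  structure(list(n_trajectories = as.integer(n_trajectories),
                 swarm_steps = as.integer(swarm_steps),
                 relax_steps = as.integer(relax_steps),
                 relax_force_constant = relax_force_constant),
            class = "swarm_settings")
}

#' Initialize a path by RMSD steering
#'
#' Steered dynamics toward `target_cv`: a one-sided harmonic restraint acts
#' on the CV-space RMSD to the target whenever it exceeds a reference value
#' that ramps down from the initial RMSD at `speed` per step. Terminates
#' when the RMSD drops to `stop_rmsd`; errors (reporting the final RMSD) if
#' `max_steps` is exhausted first.
#'
#' @param start Starting CV point.
#' @param target_cv Target CV point.
#' @param potential A [model_potential()].
#' @param settings A [langevin_settings()] (its `n_steps` is ignored;
#'   steering runs until convergence or `max_steps`).
#' @param speed Ramp speed in A/step (default 5e-5).
#' @param stop_rmsd Termination threshold in A (default 0.02).
#' @param k_steer Restraint stiffness, kcal/mol/A^2 (default 200).
#' @param max_steps Step budget.
#' @param max_adjacent_rmsd Image spacing passed to
#'   [subsample_to_images()].
#' @return List with the steering `trajectory` (recorded at
#'   `settings$stride`), the initial `string`, `steps` and `final_rmsd`.
#' @export
steer_path <- function(start, target_cv, potential, settings,
                       speed = 5e-5, stop_rmsd = 0.02, k_steer = 200,
                       max_steps = NULL, max_adjacent_rmsd = 0.2) {
  stopifnot(speed > 0, stop_rmsd > 0, k_steer > 0)
  start <- as.numeric(start); target_cv <- as.numeric(target_cv)
  if (!in_domain(potential, target_cv)) stop("target is outside the domain")
  r0 <- cv_rmsd(start, target_cv)
  max_steps <- max_steps %||% as.integer(ceiling(r0 / speed * 1.5) + 200000)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  beta <- 1 / thermal_energy(settings$temperature)
  out <- cpp_steer(pack_potential(potential), start, target_cv, speed,
                   stop_rmsd, k_steer, beta, settings$diffusion,
                   settings$timestep, as.integer(max_steps), settings$stride)
  if (!out$converged)
    stop(sprintf("steering did not reach stop_rmsd within %d steps (final RMSD %.4g A)",
                 max_steps, out$final_rmsd))
  traj <- out$trajectory
  colnames(traj) <- potential$cv_names
  string <- if (nrow(traj) >= 2 && out$steps > 0)
    subsample_to_images(traj, max_adjacent_rmsd) else NULL
  list(trajectory = structure(traj, class = c("cv_trajectory", "matrix", "array")),
       string = string, steps = out$steps, final_rmsd = out$final_rmsd)
}

#' Subsample a trajectory into a chain of images
#'
#' Greedy arc-length walk in the CV-RMSD metric: a frame is emitted just
#' before the accumulated RMSD since the last emitted frame would exceed
#' `max_adjacent_rmsd`; both endpoints are always kept, so the mean
#' adjacent-image RMSD is below the threshold.
#'
#' @param trajectory Matrix of CV points (>= 2 rows).
#' @param max_adjacent_rmsd Target spacing in A (default 0.2).
#' @return A [transition_string()].
#' @export
subsample_to_images <- function(trajectory, max_adjacent_rmsd = 0.2) {
  traj <- as.matrix(trajectory)
  if (nrow(traj) < 2) stop("trajectory must have at least 2 frames")
  stopifnot(max_adjacent_rmsd > 0)
  idx <- 1L
  acc <- 0
  for (i in 2:nrow(traj)) {
    step <- cv_rmsd(traj[i - 1, ], traj[i, ])
    if (acc + step > max_adjacent_rmsd && i - 1L > idx[length(idx)]) {
      idx <- c(idx, i - 1L)
      acc <- step
    } else acc <- acc + step
  }
  if (acc > max_adjacent_rmsd && nrow(traj) - 1L > idx[length(idx)])
    idx <- c(idx, nrow(traj) - 1L)
  idx <- unique(c(idx, nrow(traj)))
  images <- traj[idx, , drop = FALSE]
  mean_adj <- function(m) mean(adjacent_rmsd(m))
  if (nrow(images) >= 2 && mean_adj(images) >= max_adjacent_rmsd) {
    # recorded frames are spaced more coarsely than the threshold: place
    # interpolated images at equal arc length along the trajectory instead
    L <- sum(adjacent_rmsd(traj))
    m <- max(3L, as.integer(floor(L / max_adjacent_rmsd)) + 2L)
    images <- redistribute_once(traj, m)
  }
  if (nrow(images) < 3) {      # endpoints plus midpoint at minimum
    mid <- (traj[1, ] + traj[nrow(traj), ]) / 2
    images <- rbind(traj[1, ], mid, traj[nrow(traj), ])
  }
  transition_string(images)
}

#' Mean swarm drift of an image
#'
#' Launches `n_trajectories` short unbiased trajectories from the image's
#' engine state and averages (final CV - initial CV).
#'
#' @param image_state CV vector: the state the swarm launches from.
#' @param potential A [model_potential()].
#' @param settings A [langevin_settings()] (temperature, diffusion,
#'   timestep).
#' @param swarm A [swarm_settings()].
#' @param seed Integer seed for the swarm's random stream.
#' @return Drift vector in Angstrom.
#' @export
swarm_drift <- function(image_state, potential, settings, swarm, seed) {
  set.seed(seed)
  beta <- 1 / thermal_energy(settings$temperature)
  packed <- pack_potential(potential)
  d <- length(image_state)
  drift <- numeric(d)
  for (t in seq_len(swarm$n_trajectories)) {
    fin <- cpp_propagate(packed, image_state, swarm$swarm_steps, beta,
                         settings$diffusion, settings$timestep, NULL, NULL,
                         swarm$swarm_steps)
    drift <- drift + (fin[nrow(fin), ] - image_state)
  }
  drift / swarm$n_trajectories
}

#' Relax an engine state onto a CV target
#'
#' Constrained dynamics under a strong harmonic restraint at `target_cv`;
#' the returned state's CV sits within about `sqrt(kBT/k)` of the target.
#'
#' @param state Current CV state.
#' @param target_cv Restraint center.
#' @param potential A [model_potential()].
#' @param settings A [langevin_settings()].
#' @param relax_steps Number of relaxation steps.
#' @param relax_force_constant Restraint stiffness, kcal/mol/A^2.
#' @return Relaxed CV state.
#' @export
relax_to_cv <- function(state, target_cv, potential, settings,
                        relax_steps = 1250, relax_force_constant = 40) {
  stopifnot(relax_force_constant > 0)
  beta <- 1 / thermal_energy(settings$temperature)
  fin <- cpp_propagate(pack_potential(potential), as.numeric(state),
                       as.integer(relax_steps), beta, settings$diffusion,
                       settings$timestep, as.numeric(target_cv),
                       rep_len(relax_force_constant, length(state)),
                       as.integer(relax_steps))
  fin[nrow(fin), ]
}

# Redistribute points at equal spacing along the piecewise-linear
# interpolant through `pts`; one pass of the classic string-method
# reparametrization.
redistribute_once <- function(pts, m = nrow(pts)) {
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[n] <= 0) stop("total arc length is zero")
  targets <- seq(0, s[n], length.out = m)
  out <- matrix(0, m, ncol(pts))
  for (j in seq_len(ncol(pts)))
    out[, j] <- approx(s, pts[, j], xout = targets, ties = "ordered")$y
  out
}

#' Reparametrize a string to even image spacing
#'
#' Images are redistributed along the piecewise-linear interpolant of the
#' current images at equal arc-length spacing, iterated to a fixed point so
#' that adjacent-image distances are equal to machine precision and the
#' operation is idempotent. Endpoints are preserved exactly. Duplicate
#' consecutive images are collapsed before redistribution (an all-duplicate
#' string with zero arc length is rejected).
#'
#' @param string A [transition_string()] or a plain image matrix.
#' @param tol Fixed-point tolerance on image movement, relative to total
#'   arc length (default 1e-13).
#' @param max_iter Safety cap on fixed-point passes.
#' @return Same type as the input, with images evenly spaced.
#' @export
reparametrize <- function(string, tol = 1e-15, max_iter = 5000) {
  is_string <- inherits(string, "transition_string")
  pts <- if (is_string) string$images else as.matrix(string)
  n0 <- nrow(pts)
  # collapse exact consecutive duplicates
  if (n0 >= 2) {
    dup <- c(FALSE, rowSums(abs(pts[-1, , drop = FALSE] -
                                  pts[-n0, , drop = FALSE])) == 0)
    pts_u <- pts[!dup, , drop = FALSE]
  } else pts_u <- pts
  if (nrow(pts_u) < 2) stop("total arc length is zero: cannot reparametrize")
  if (nrow(pts_u) < n0)        # restore requested image count on the clean path
    pts <- redistribute_once(pts_u, n0)
  L <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
  if (L <= 0) stop("total arc length is zero: cannot reparametrize")
  for (it in seq_len(max_iter)) {
    new <- redistribute_once(pts)
    move <- max(sqrt(rowSums((new - pts)^2)))
    pts <- new
    if (move <= tol * L) break
  }
  if (is_string) {
    string$images <- pts
    string
  } else pts
}

#' Iterate the string method with swarms of trajectories
#'
#' Each iteration applies, to every non-endpoint image: (1) a swarm of
#' short unbiased trajectories launched from the image state, (2) evolution
#' of the image CVs by the mean swarm drift, (3) constrained relaxation of
#' the state onto the evolved CVs under a strong harmonic restraint, and
#' (4) reparametrization of the image chain to even spacing. Per-iteration
#' image CVs are recorded in the history.
#'
#' @param string A [transition_string()].
#' @param potential A [model_potential()].
#' @param swarm A [swarm_settings()].
#' @param settings A [langevin_settings()] for the engine.
#' @param n_iterations Number of string iterations (0 returns the input).
#' @param seed Master seed; per-image/per-iteration streams are derived
#'   with [derive_seed()].
#' @return The evolved `transition_string`; `$history` holds one image
#'   matrix per iteration and `$convergence` the [convergence_metrics()].
#' @export
iterate_string <- function(string, potential, swarm, settings,
                           n_iterations, seed = 1L) {
  stopifnot(inherits(string, "transition_string"), n_iterations >= 0)
  if (n_iterations == 0) return(string)
  n <- nrow(string$images)
  interior <- if (string$endpoints_fixed) 2:(n - 1) else 1:n
  for (iter in seq_len(n_iterations)) {
    it <- string$iteration + 1L
    drifts <- matrix(0, n, ncol(string$images))
    for (i in interior) {
      drifts[i, ] <- swarm_drift(string$states[[i]], potential, settings,
                                 swarm, derive_seed(seed, it, i, 1L))
    }
    evolved <- string$images + drifts
    if (string$endpoints_fixed) {
      evolved[1, ] <- string$images[1, ]
      evolved[n, ] <- string$images[n, ]
    }
    for (i in interior) {
      set.seed(derive_seed(seed, it, i, 2L))
      string$states[[i]] <- relax_to_cv(string$states[[i]], evolved[i, ],
                                        potential, settings,
                                        swarm$relax_steps,
                                        swarm$relax_force_constant)
    }
    string$images <- reparametrize(evolved)
    string$iteration <- it
    string$history[[length(string$history) + 1]] <- string$images
  }
  string$convergence <- convergence_metrics(string$history)
  string
}

#' String convergence diagnostics
#'
#' Per iteration: the mean over images of the CV RMSD to the same image at
#' iteration 0 (`rmsd_to_initial`) and to the same image `lag` iterations
#' before (`rmsd_to_lag`, `NA` for the first `lag` iterations). The string
#' is flagged as plateaued when, over the last `window` iterations, each
#' series shows no systematic trend toward further change: the
#' RMSD-to-initial series must not be increasing, and the lag series must
#' not be decreasing, beyond `slope_tol` plus twice the slope's standard
#' error. The directional test makes the visual plateau judgment robust to
#' swarm noise (see the methods vignette).
#'
#' @param history List of image matrices, `history[[1]]` = iteration 0.
#' @param lag Lag for the second diagnostic (default 4).
#' @param slope_tol Absolute plateau slope threshold, A/iteration.
#' @param window Tail window for the plateau fit.
#' @return List with `rmsd_to_initial`, `rmsd_to_lag`, `plateau`.
#' @export
convergence_metrics <- function(history, lag = 4L, slope_tol = 1e-3,
                                window = 10L) {
  stopifnot(length(history) >= 1)
  mean_rmsd <- function(a, b)
    mean(vapply(seq_len(nrow(a)), function(i) cv_rmsd(a[i, ], b[i, ]),
                numeric(1)))
  n_it <- length(history) - 1L
  iters <- seq_len(n_it + 1L) - 1L
  r0 <- vapply(seq_along(history), function(i)
    mean_rmsd(history[[i]], history[[1]]), numeric(1))
  rlag <- rep(NA_real_, length(history))
  if (length(history) > lag) {
    for (i in (lag + 1L):length(history))
      rlag[i] <- mean_rmsd(history[[i]], history[[i - lag]])
  }
  flat <- function(series, direction) {
    # direction +1: series approaches the plateau from below (must not keep
    # rising); -1: approaches from above (must not keep falling)
    ok <- is.finite(series)
    xs <- iters[ok]; ys <- series[ok]
    if (length(ys) < 3) return(TRUE)
    k <- min(window, length(ys))
    xs <- tail(xs, k); ys <- tail(ys, k)
    if (sd(ys) == 0) return(TRUE)
    fit <- lm(ys ~ xs)
    sl <- unname(coef(fit)[2])
    # suppressed: "essentially perfect fit" on constructed noise-free series
    se <- suppressWarnings(summary(fit)$coefficients[2, 2])
    if (!is.finite(se)) se <- 0
    abs(sl) < slope_tol || direction * sl < slope_tol + 2 * se
  }
  list(rmsd_to_initial = r0, rmsd_to_lag = rlag,
       plateau = flat(r0, +1) && flat(rlag, -1))
}

#' Write / read a string checkpoint
#'
#' Plain-text blocks, one per recorded iteration, of
#' `(image index, cv values...)` at full precision; round-trips exactly.
#'
#' @param string A [transition_string()].
#' @param path File path.
#' @return `read_string_checkpoint` returns a `transition_string` with the
#'   recorded history.
#' @export
write_string_checkpoint <- function(string, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# transition_string images=%d dim=%d endpoints_fixed=%d",
                     nrow(string$images), ncol(string$images),
                     as.integer(string$endpoints_fixed)), con)
  for (h in seq_along(string$history)) {
    writeLines(sprintf("# iteration %d", h - 1L), con)
    m <- string$history[[h]]
    writeLines(vapply(seq_len(nrow(m)), function(i)
      paste(c(i, sprintf("%.17g", m[i, ])), collapse = " "), character(1)), con)
  }
  invisible(path)
}

#' @rdname write_string_checkpoint
#' @export
read_string_checkpoint <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# transition_string ", "", lines[1]), " ")[[1]]
  fields <- setNames(as.integer(sub(".*=", "", hdr)), sub("=.*", "", hdr))
  marks <- which(startsWith(lines, "# iteration"))
  history <- lapply(seq_along(marks), function(k) {
    from <- marks[k] + 1L
    to <- if (k < length(marks)) marks[k + 1] - 1L else length(lines)
    do.call(rbind, lapply(lines[from:to], function(l) {
      v <- as.numeric(strsplit(l, " ")[[1]])
      v[-1]
    }))
  })
  st <- transition_string(history[[length(history)]],
                          endpoints_fixed = as.logical(fields["endpoints_fixed"]))
  st$history <- history
  st$iteration <- length(history) - 1L
  st
}
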