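# Overdamped Langevin (Brownian) engine on model landscapes. This is the
# synthetic stand-in for the all-atom MD engine: only equilibrium statistics
# in collective-variable space matter downstream, so inertial dynamics,
# thermostats and solvent are deliberately absent.

#' Langevin propagation settings
#'
#' @param temperature Kelvin (default 298.15 K).
#' @param diffusion Diffusion coefficient D in A^2/step (default 0.01; sets
#'   the CV mobility scale, see the methods vignette).
#' @param timestep Dimensionless step size dt (default 0.25; small enough
#'   that the Euler-Maruyama stationary distribution is Boltzmann to well
#'   within the package's recovery tolerances on the designed landscapes).
#' @param n_steps Number of steps to take.
#' @param seed Optional integer seed; when given, [set.seed()] is called
#'   before propagation so identical settings give identical trajectories.
#' @param stride Record every `stride`-th step (step 0 always recorded).
#' @return An object of class `langevin_settings`.
#' @export
langevin_settings <- function(temperature = .default_temperature,
                              diffusion = 0.01, timestep = 0.25,
                              n_steps = 1000L, seed = NULL, stride = 1L) {
  stopifnot(temperature > 0, diffusion >= 0, timestep > 0, n_steps >= 0,
            stride >= 1)
  structure(list(temperature = temperature, diffusion = diffusion,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 seed = seed, stride = as.integer(stride)),
            class = "langevin_settings")
}

#' Harmonic bias (umbrella restraint)
#'
#' Bias energy `sum(0.5 * k * (x - center)^2)`; non-negative, exactly zero at
#' the center. A zero force constant disables the restraint on that
#' coordinate.
#'
#' @param center Restraint center, Angstrom.
#' @param k Force constants, kcal/mol/A^2, one per coordinate (recycled if
#'   scalar).
#' @return An object of class `harmonic_bias`.
#' @export
harmonic_bias <- function(center, k) {
  center <- as.numeric(center)
  k <- rep_len(as.numeric(k), length(center))
  stopifnot(all(is.finite(center)), all(k >= 0))
  structure(list(center = center, k = k), class = "harmonic_bias")
}

#' Bias energy at points
#'
#' @param bias A [harmonic_bias()].
#' @param point Vector or matrix of points.
#' @return Numeric vector of bias energies (kcal/mol).
#' @export
bias_energy <- function(bias, point) {
  pts <- if (is.null(dim(point))) matrix(as.numeric(point), nrow = 1) else as.matrix(point)
  dev <- sweep(pts, 2, bias$center)
  as.numeric(dev^2 %*% (bias$k / 2))
}

#' Propagate overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of `dx = -beta D grad(U + bias) dt +
#' sqrt(2 D dt) xi`. With a bias, long runs sample the Boltzmann weight of
#' `potential + bias` (up to O(dt) discretization bias).
#'
#' @param start Starting point (inside the potential domain).
#' @param potential A [model_potential()].
#' @param settings A [langevin_settings()].
#' @param bias Optional [harmonic_bias()].
#' @return Matrix of recorded points (class `cv_trajectory`), first row =
#'   start; attributes carry the settings.
#' @export
propagate_langevin <- function(start, potential, settings, bias = NULL) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(settings, "langevin_settings"))
  start <- as.numeric(start)
  if (!in_domain(potential, start)) stop("start point is outside the potential domain")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  beta <- 1 / thermal_energy(settings$temperature)
  bc <- if (is.null(bias)) NULL else bias$center
  bk <- if (is.null(bias)) NULL else bias$k
  traj <- cpp_propagate(pack_potential(potential), start, settings$n_steps,
                        beta, settings$diffusion, settings$timestep, bc, bk,
                        settings$stride)
  colnames(traj) <- potential$cv_names
  structure(traj, class = c("cv_trajectory", "matrix", "array"),
            settings = settings)
}

#' Write / read a trajectory as columnar text
#'
#' Plain text columns `step coord1 coord2 ...` at full double precision;
#' round-trips losslessly.
#'
#' @param trajectory Matrix of points (rows = recorded steps).
#' @param path File path.
#' @return `read_trajectory` returns the matrix.
#' @export
write_trajectory <- function(trajectory, path) {
  m <- as.matrix(trajectory)
  df <- data.frame(step = seq_len(nrow(m)) - 1L,
                   apply(m, 2, function(x) sprintf("%.17g", x)))
  names(df) <- c("step", colnames(m) %||% paste0("coord", seq_len(ncol(m))))
  write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.table(path, header = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- NULL
  structure(m, class = c("cv_trajectory", "matrix", "array"))
}
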