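# Analytic model landscapes: sums of Gaussian basins/barriers and harmonic
# terms over a rectangular collective-variable domain, with quartic confining
# walls so trajectories never need reflecting boundaries.

#' Gaussian well term
#'
#' A basin of the model landscape: an isotropic-per-axis Gaussian depression
#' `-depth * exp(-sum((x - center)^2 / (2 width^2)))`.
#'
#' @param center Numeric vector, basin center in Angstrom (one entry per
#'   collective variable).
#' @param depth Well depth in kcal/mol (> 0); the energy at the center of an
#'   isolated well is `baseline - depth`.
#' @param width Numeric vector of Gaussian widths (sigma) in Angstrom.
#' @return A term object for [model_potential()].
#' @export
gaussian_well <- function(center, depth, width) {
  stopifnot(depth > 0, length(center) == length(width), all(width > 0))
  structure(list(kind = "gauss", center = as.numeric(center),
                 amplitude = -depth, width = as.numeric(width)),
            class = "potential_term")
}

#' Gaussian barrier term
#'
#' Like [gaussian_well()] but with positive amplitude: a localized bump used
#' to build benchmark surfaces with nontrivial saddle structure.
#'
#' @inheritParams gaussian_well
#' @param height Barrier height in kcal/mol (> 0).
#' @return A term object for [model_potential()].
#' @export
gaussian_barrier <- function(center, height, width) {
  stopifnot(height > 0, length(center) == length(width), all(width > 0))
  structure(list(kind = "gauss", center = as.numeric(center),
                 amplitude = height, width = as.numeric(width)),
            class = "potential_term")
}

#' Harmonic term
#'
#' `sum(0.5 * k * (x - center)^2)`, mainly for closed-form validation
#' surfaces.
#'
#' @inheritParams gaussian_well
#' @param k Force constants in kcal/mol/A^2, one per coordinate (0 disables a
#'   coordinate).
#' @return A term object for [model_potential()].
#' @export
harmonic_term <- function(center, k) {
  stopifnot(length(center) == length(k), all(k >= 0))
  structure(list(kind = "harmonic", center = as.numeric(center),
                 k = as.numeric(k)), class = "potential_term")
}

#' Construct an analytic model landscape
#'
#' The landscape is a sum of Gaussian wells/barriers and harmonic terms plus a
#' constant baseline, confined by quartic walls that switch on `wall_margin`
#' Angstrom inside each edge of the rectangular domain and reach
#' `wall_height` at the edge. Energies are in kcal/mol, coordinates in
#' Angstrom; the surface is continuously differentiable everywhere and the
#' gradient returned by [evaluate_potential()] is analytic.
#'
#' @param terms List of terms from [gaussian_well()], [gaussian_barrier()] or
#'   [harmonic_term()]. May be empty (constant surface).
#' @param domain 2 x d matrix; row 1 = lower bounds, row 2 = upper bounds.
#' @param baseline Constant offset in kcal/mol.
#' @param wall_height Energy (kcal/mol) the confining wall reaches at the
#'   domain edge; 0 disables walls.
#' @param wall_margin Distance (A) inside the edge where the wall starts.
#' @param cv_names Optional coordinate names (default `g`, `z`, ...).
#' @return An object of class `model_potential`.
#' @export
model_potential <- function(terms = list(), domain, baseline = 0,
                            wall_height = 25, wall_margin = 1,
                            cv_names = NULL) {
  domain <- as.matrix(domain)
  stopifnot(nrow(domain) == 2, all(domain[2, ] > domain[1, ]),
            wall_height >= 0, wall_margin > 0)
  d <- ncol(domain)
  if (inherits(terms, "potential_term")) terms <- list(terms)
  for (tm in terms) {
    stopifnot(inherits(tm, "potential_term"), length(tm$center) == d)
  }
  if (is.null(cv_names)) {
    cv_names <- if (d == 2) c("g", "z") else paste0("cv", seq_len(d))
  }
  structure(list(terms = terms, domain = domain, baseline = baseline,
                 wall_height = wall_height, wall_margin = wall_margin,
                 cv_names = cv_names, dim = d),
            class = "model_potential")
}

#' @export
print.model_potential <- function(x, ...) {
  ng <- sum(vapply(x$terms, function(t) t$kind == "gauss", logical(1)))
  nh <- length(x$terms) - ng
  cat(sprintf("<model_potential> %dD (%s), %d Gaussian + %d harmonic term(s)\n",
              x$dim, paste(x$cv_names, collapse = ", "), ng, nh))
  cat(sprintf("  domain: %s\n", paste(sprintf("[%g, %g]", x$domain[1, ],
                                              x$domain[2, ]), collapse = " x ")))
  cat(sprintf("  baseline %g kcal/mol, wall %g kcal/mol over %g A\n",
              x$baseline, x$wall_height, x$wall_margin))
  invisible(x)
}

# flatten to the matrix form the C++ evaluator consumes
pack_potential <- function(pot) {
  stopifnot(inherits(pot, "model_potential"))
  d <- pot$dim
  gauss <- Filter(function(t) t$kind == "gauss", pot$terms)
  harm <- Filter(function(t) t$kind == "harmonic", pot$terms)
  mat <- function(lst, field) {
    if (length(lst) == 0) return(matrix(0, 0, d))
    do.call(rbind, lapply(lst, `[[`, field))
  }
  list(gc = mat(gauss, "center"), gw = mat(gauss, "width"),
       ga = if (length(gauss)) vapply(gauss, `[[`, numeric(1), "amplitude") else numeric(0),
       hc = mat(harm, "center"), hk = mat(harm, "k"),
       baseline = pot$baseline, lo = pot$domain[1, ], hi = pot$domain[2, ],
       wall_h = pot$wall_height, wall_m = pot$wall_margin)
}

in_domain <- function(pot, point) {
  all(point >= pot$domain[1, ] & point <= pot$domain[2, ])
}

#' Evaluate a model landscape
#'
#' @param potential A [model_potential()].
#' @param point Numeric vector (one point) or matrix (one row per point).
#' @param check_domain Reject points outside the declared domain (default
#'   TRUE, matching the engine's contract that designed landscapes confine
#'   trajectories by construction).
#' @return For a single point, `list(energy, gradient)` (kcal/mol and
#'   kcal/mol/A); for a matrix, `list(energy = vector, gradient = matrix)`.
#' @export
evaluate_potential <- function(potential, point, check_domain = TRUE) {
  single <- is.null(dim(point))
  pts <- if (single) matrix(as.numeric(point), nrow = 1) else as.matrix(point)
  stopifnot(ncol(pts) == potential$dim, all(is.finite(pts)))
  if (check_domain) {
    ok <- pts >= matrix(potential$domain[1, ], nrow(pts), potential$dim, byrow = TRUE) &
      pts <= matrix(potential$domain[2, ], nrow(pts), potential$dim, byrow = TRUE)
    if (!all(ok)) {
      bad <- which(!apply(ok, 1, all))[1]
      stop(sprintf("point (%s) is outside the potential domain",
                   paste(signif(pts[bad, ], 6), collapse = ", ")))
    }
  }
  out <- cpp_potential_eval(pack_potential(potential), pts)
  if (single) list(energy = out$energy[1], gradient = drop(out$gradient)) else out
}

#' Energy of a model landscape at points
#'
#' Convenience wrapper around [evaluate_potential()] returning energies only.
#'
#' @inheritParams evaluate_potential
#' @return Numeric vector of energies in kcal/mol.
#' @export
potential_energy <- function(potential, point, check_domain = TRUE) {
  pts <- if (is.null(dim(point))) matrix(as.numeric(point), nrow = 1) else as.matrix(point)
  evaluate_potential(potential, pts, check_domain = check_domain)$energy
}

#' Cycle landscape designs
#'
#' Parameter sets for the designed gate (g) x ion (z) landscapes that stand in
#' for the transporter's conformational cycle. All values are designer
#' choices fixed once (see the methods vignette), expressed so every
#' downstream stage has analytic ground truth:
#'
#' * `"ion-bound"` (default): the full cycle surface. A deep outward-facing
#'   basin at (5.5, 0) with the ion bound, a shallow inward-facing basin at
#'   (10, 0), a metastable intermediate ion site (Na2'-like) at (5.5, -1.8)
#'   sitting 5 kBT above the main site, and a nearly flat apo region at the
#'   released ion coordinate z = -6 with outward/inward wells of ~4 kBT and a
#'   designed outward-vs-inward imbalance under 1 kBT. The designed
#'   ion-bound outward-vs-inward stabilization is 16 kBT.
#' * `"apo-flat"`: just the two nearly-degenerate apo basins.
#' * `"three-well"`: a benchmark surface for the string method - two deep
#'   end wells, a shallow intermediate well displaced off the straight line,
#'   and a central barrier, giving a curved, well-conditioned minimum free
#'   energy path.
#'
#' @param variant One of `"ion-bound"`, `"apo-flat"`, `"three-well"`.
#' @return A design list (basins, coupling, barriers, domain, baseline,
#'   designed values) consumable by [build_cycle_potential()] and
#'   serializable with [write_potential_config()].
#' @export
cycle_design <- function(variant = c("ion-bound", "apo-flat", "three-well")) {
  variant <- match.arg(variant)
  kT <- thermal_energy()
  beta <- 1 / kT
  basin <- function(center, depth, width) {
    list(center = center, depth = depth, width = width)
  }
  # Apo region at the released ion coordinate z = -6: two nearly-degenerate
  # wells of ~4 kBT (giving inter-state barriers in the stated 2-4 kBT
  # range) with a sub-kBT inward preference.
  apo_depth_out <- 4 * kT
  apo_depth_in <- 4 * kT + 0.3
  apo <- list(basin(c(5.5, -6), apo_depth_out, c(1.0, 1.2)),
              basin(c(10.0, -6), apo_depth_in, c(1.0, 1.2)))
  des <- switch(variant,
    "apo-flat" = list(
      basins = apo, coupling = list(), barriers = list(),
      designed = list(apo_delta_g_kcal = apo_depth_in - apo_depth_out)),
    "ion-bound" = {
      # The designed value is the Boltzmann-weighted outward-vs-inward state
      # free energy over the bound-ion strip (z in [-2, 0], the default gate
      # state windows), not a naive depth difference: Gaussian wells carry a
      # Laplace entropy term ~ kT ln(A) and the metastable intermediate
      # overlaps the main well along z. The outward depth is therefore
      # solved by direct quadrature of the analytic design so that the
      # designed stabilization is exactly 16 kBT.
      d_in <- 2.0
      dg_target <- 16
      sz_main <- 0.9; sz_na <- 0.7; dz <- 1.8
      t_main <- exp(-dz^2 / (2 * sz_main^2))
      t_na <- exp(-dz^2 / (2 * sz_na^2))
      mk_coupling <- function(A) list(
        basin(c(5.5, 0), A, c(1.1, sz_main)),      # outward, ion bound
        basin(c(10.0, 0), d_in, c(1.1, sz_main)),  # inward, ion bound (shallow)
        # intermediate 5 kBT above the main site on the 2D map, tail overlap
        # included
        basin(c(5.5, -dz), (A * (1 - t_main) - 5 * kT) / (1 - t_na),
              c(0.9, sz_na)))
      strip_dg <- function(A) {
        wells <- c(apo, mk_coupling(A))
        gs_o <- seq(4.75, 6.25, length.out = 120)
        gs_i <- seq(9.25, 11.25, length.out = 160)
        zs <- seq(-2, 0, length.out = 160)
        u <- function(gs) {
          pts <- cbind(rep(gs, times = length(zs)), rep(zs, each = length(gs)))
          e <- rep(0, nrow(pts))
          for (w in wells)
            e <- e - w$depth * exp(-(pts[, 1] - w$center[1])^2 / (2 * w$width[1]^2)
                                   - (pts[, 2] - w$center[2])^2 / (2 * w$width[2]^2))
          mean(exp(-e / kT)) * (max(gs) - min(gs))
        }
        -log(u(gs_o) / u(gs_i))
      }
      d_out <- stats::uniroot(function(A) strip_dg(A) + dg_target,
                              interval = c(5, 25), tol = 1e-10)$root
      list(basins = apo, coupling = mk_coupling(d_out), barriers = list(),
           designed = list(bound_delta_g_kbt = -dg_target,
                           na2p_offset_kbt = 5,
                           apo_delta_g_kcal = apo_depth_in - apo_depth_out))
    },
    "three-well" = list(
      basins = list(basin(c(5.5, -1.5), 5, c(1.1, 1.1)),
                    basin(c(8.0, 1.0), 3.5, c(1.1, 1.1)),
                    basin(c(10.5, -1.5), 5, c(1.1, 1.1))),
      coupling = list(),
      barriers = list(list(center = c(8.0, -1.8), height = 4, width = c(1.4, 1.4))),
      designed = list()))
  # walls start one margin inside the domain edge, outside the region any
  # umbrella window samples, so the windowed landscape is wall-free
  des$domain <- switch(variant,
    "three-well" = rbind(c(3.5, -5), c(12.5, 4)),
    rbind(c(2.5, -8.5), c(13.5, 2.5)))
  des$baseline <- 0
  des$variant <- variant
  des
}

#' Build a model landscape from a cycle design
#'
#' Validates the design (basin centers inside the domain, depths positive, no
#' duplicated centers) and assembles the [model_potential()]. The designed
#' state free-energy differences are recoverable by quadrature with
#' [reference_pmf()] over the stated integration strips.
#'
#' @param design A design list from [cycle_design()] or
#'   [read_potential_config()].
#' @return A `model_potential` carrying the design in its
#'   `design` attribute.
#' @export
build_cycle_potential <- function(design = cycle_design()) {
  stopifnot(is.list(design), !is.null(design$domain))
  domain <- as.matrix(design$domain)
  wells <- c(design$basins, design$coupling %||% list())
  if (length(wells) == 0) stop("design contains no basins")
  centers <- do.call(rbind, lapply(wells, `[[`, "center"))
  if (anyDuplicated(round(centers, 8)))
    stop("degenerate design: two basins share the same center")
  for (w in wells) {
    if (!(all(w$center >= domain[1, ]) && all(w$center <= domain[2, ])))
      stop("basin center outside domain")
    if (w$depth <= 0) stop("basin depths must be > 0")
  }
  terms <- lapply(wells, function(w) gaussian_well(w$center, w$depth, w$width))
  for (b in design$barriers %||% list())
    terms <- c(terms, list(gaussian_barrier(b$center, b$height, b$width)))
  pot <- model_potential(terms, domain = domain,
                         baseline = design$baseline %||% 0)
  attr(pot, "design") <- design
  pot
}

#' Write / read a landscape design config
#'
#' Designs round-trip through JSON at full double precision.
#'
#' @param design A design list ([cycle_design()]).
#' @param path File path.
#' @return `read_potential_config` returns the design list.
#' @export
write_potential_config <- function(design, path) {
  jsonlite::write_json(design, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_potential_config
#' @export
read_potential_config <- function(path) {
  des <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix <- function(lst) lapply(lst, function(w)
    lapply(w, function(v) as.numeric(unlist(v))))
  des$basins <- fix(des$basins)
  des$coupling <- if (length(des$coupling %||% list())) fix(des$coupling) else list()
  des$barriers <- if (length(des$barriers %||% list())) fix(des$barriers) else list()
  des$domain <- matrix(as.numeric(unlist(des$domain)), nrow = 2, byrow = TRUE)
  des$baseline <- as.numeric(des$baseline %||% 0)
  des$variant <- as.character(des$variant %||% "custom")
  if (!is.null(des$designed)) des$designed <- lapply(des$designed, as.numeric)
  des
}
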