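# Landscape interpretation: basins, saddles/barriers, Boltzmann-weighted
# state free energies in kBT, state classification from order-parameter
# values, and the cycle report.

#' Conformational state definition
#'
#' @param name State name (e.g. `"outward"`).
#' @param range Per-axis range(s) in Angstrom: a length-2 vector for 1D or
#'   a list of length-2 vectors.
#' @return Object of class `state_definition`.
#' @export
state_definition <- function(name, range) {
  if (!is.list(range)) range <- list(range)
  for (r in range) stopifnot(length(r) == 2, r[2] > r[1])
  structure(list(name = name, range = range), class = "state_definition")
}

#' Default gate-distance state windows
#'
#' Outward-facing: thick gate in [4.75, 6.25] A (anchored on the ~5.5 A
#' crystal value); inward-facing: [9.25, 11.25] A (anchored on ~10-10.4 A);
#' both six WHAM bins wide.
#'
#' @return Named list of [state_definition()]s.
#' @export
default_gate_states <- function() {
  list(outward = state_definition("outward", c(4.75, 6.25)),
       inward = state_definition("inward", c(9.25, 11.25)))
}

state_range_1d <- function(state) {
  if (inherits(state, "state_definition")) state$range[[1]] else as.numeric(state)
}

#' Locate local minima of a PMF
#'
#' Local minima over sampled bins (8-neighborhood in 2D, 2-neighborhood in
#' 1D); minima closer than `min_separation` are merged to the deeper one;
#' results are sorted by increasing free energy.
#'
#' @param pmf A [pmf_surface()].
#' @param min_separation Merge radius in Angstrom.
#' @return Data frame with the minima locations (bin centers) and `value`
#'   (kcal/mol above the global minimum).
#' @export
find_minima <- function(pmf, min_separation = 0.75) {
  stopifnot(inherits(pmf, "pmf_surface"))
  if (!any(pmf$mask)) stop("PMF has no sampled bins")
  d <- length(pmf$axes)
  if (d == 1) {
    v <- pmf$values
    n <- length(v)
    is_min <- vapply(seq_len(n), function(i) {
      if (!is.finite(v[i])) return(FALSE)
      nb <- c(if (i > 1) v[i - 1], if (i < n) v[i + 1])
      nb <- nb[is.finite(nb)]
      length(nb) == 0 || all(v[i] <= nb)
    }, logical(1))
    loc <- matrix(bin_centers(pmf, 1)[is_min], ncol = 1)
    vals <- v[is_min]
  } else {
    v <- pmf$values
    nr <- nrow(v); nc <- ncol(v)
    idx <- which(pmf$mask, arr.ind = TRUE)
    keep <- logical(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      nb <- v[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      keep[r] <- is.finite(v[i, j]) && v[i, j] <= min(nb, na.rm = TRUE)
    }
    sel <- idx[keep, , drop = FALSE]
    loc <- cbind(bin_centers(pmf, 1)[sel[, 1]], bin_centers(pmf, 2)[sel[, 2]])
    vals <- v[sel]
  }
  ord <- order(vals)
  loc <- loc[ord, , drop = FALSE]; vals <- vals[ord]
  # merge within min_separation, deeper minimum wins (list is depth-sorted)
  kept <- integer(0)
  for (i in seq_along(vals)) {
    if (!length(kept) ||
        all(sqrt(rowSums((loc[kept, , drop = FALSE] -
                            matrix(loc[i, ], length(kept), d,
                                   byrow = TRUE))^2)) >= min_separation))
      kept <- c(kept, i)
  }
  out <- data.frame(loc[kept, , drop = FALSE])
  names(out) <- vapply(pmf$axes, `[[`, character(1), "name")
  out$value <- vals[kept]
  out
}

#' State free-energy difference from a 1D PMF
#'
#' Boltzmann-weighted state populations (not point minima):
#' `dG = -log[ sum_a exp(-W/kBT) dx / sum_b exp(-W/kBT) dx ]` in units of
#' kBT. Negative values mean state `a` is more stable.
#'
#' @param pmf1d A 1D [pmf_surface()].
#' @param state_a,state_b [state_definition()]s or length-2 ranges on the
#'   PMF axis.
#' @param temperature Kelvin (default: the PMF's own temperature).
#' @return Free-energy difference G_a - G_b in kBT.
#' @export
state_delta_g <- function(pmf1d, state_a, state_b, temperature = NULL) {
  stopifnot(inherits(pmf1d, "pmf_surface"), length(pmf1d$axes) == 1)
  kT <- thermal_energy(temperature %||% pmf1d$temperature)
  x <- bin_centers(pmf1d, 1)
  w <- pmf1d$values
  pop <- function(rng) {
    rng <- state_range_1d(rng)
    ok <- x >= rng[1] & x <= rng[2] & is.finite(w)
    if (!any(ok)) stop(sprintf("state range [%g, %g] overlaps no sampled bins",
                               rng[1], rng[2]))
    m <- min(w[ok])
    sum(exp(-(w[ok] - m) / kT)) * exp(-m / kT)
  }
  -log(pop(state_a) / pop(state_b))
}

#' Barrier heights between two states on a 1D PMF
#'
#' The transition bottleneck is the maximum PMF value on the axis interval
#' between the two state minima; forward and reverse barriers are that
#' maximum minus each state's minimum, in kBT. A masked bin between the
#' states means the landscape is disconnected and is an error.
#'
#' @inheritParams state_delta_g
#' @return Named numeric `c(forward, reverse)` in kBT: forward = leaving
#'   state `a`, reverse = leaving state `b`.
#' @export
barrier_height <- function(pmf1d, state_a, state_b, temperature = NULL) {
  stopifnot(inherits(pmf1d, "pmf_surface"), length(pmf1d$axes) == 1)
  kT <- thermal_energy(temperature %||% pmf1d$temperature)
  x <- bin_centers(pmf1d, 1)
  w <- pmf1d$values
  argmin_in <- function(rng) {
    rng <- state_range_1d(rng)
    ok <- which(x >= rng[1] & x <= rng[2] & is.finite(w))
    if (!length(ok)) stop(sprintf("state range [%g, %g] overlaps no sampled bins",
                                  rng[1], rng[2]))
    ok[which.min(w[ok])]
  }
  ia <- argmin_in(state_a); ib <- argmin_in(state_b)
  if (ia == ib) return(c(forward = 0, reverse = 0))
  span <- seq(min(ia, ib), max(ia, ib))
  if (any(!is.finite(w[span])))
    stop("landscape is disconnected: masked bins between the two states")
  peak <- max(w[span])
  c(forward = (peak - w[ia]) / kT, reverse = (peak - w[ib]) / kT)
}

#' Classify a conformation from order-parameter values
#'
#' @param cv_values Numeric vector of order-parameter values (length =
#'   number of axes in the state definitions).
#' @param states List of [state_definition()]s (must not overlap).
#' @return The unique containing state's name, else `"intermediate"`.
#' @export
classify_state <- function(cv_values, states = default_gate_states()) {
  contains <- function(st) {
    rngs <- st$range
    all(vapply(seq_along(rngs), function(j)
      cv_values[j] >= rngs[[j]][1] && cv_values[j] <= rngs[[j]][2],
      logical(1)))
  }
  hits <- vapply(states, contains, logical(1))
  # overlap detection on the supplied point is cheap but partial; check ranges
  for (i in seq_along(states)) for (j in seq_len(i - 1L)) {
    ri <- states[[i]]$range; rj <- states[[j]]$range
    if (all(vapply(seq_along(ri), function(k)
      ri[[k]][1] <= rj[[k]][2] && rj[[k]][1] <= ri[[k]][2], logical(1))))
      stop(sprintf("state definitions '%s' and '%s' overlap",
                   states[[i]]$name, states[[j]]$name))
  }
  if (sum(hits) == 1) states[[which(hits)]]$name else "intermediate"
}

#' Full cycle report
#'
#' Deterministically assembles the landscape interpretation for one or two
#' transitions from completed WHAM outputs: strip-integrated 1D profiles,
#' alignment of profile pairs at a shared state (whose PMF is set to 0 in
#' both), minima, barrier and state-dG tables. Numeric tables are written
#' as CSV when `output_dir` is given; regenerating from the same inputs is
#' byte-identical.
#'
#' @param config List with elements:
#'   * `transitions`: named list; each element has `pmf` (2D
#'     [pmf_surface()]), `strip` (range on the ion axis), optionally
#'     `kept_axis` (default 1).
#'   * `states`: list of [state_definition()]s on the kept axis (default
#'     [default_gate_states()]).
#'   * `align_state`: name of the state shared between the two profiles at
#'     which both are set to zero (optional, requires >= 2 transitions).
#' @param output_dir Optional directory for CSV tables.
#' @return List with per-transition `profiles` (1D surfaces, aligned),
#'   `minima`, `delta_g` and `barriers` tables.
#' @export
run_cycle_report <- function(config, output_dir = NULL) {
  if (is.null(config$transitions) || !length(config$transitions))
    stop("usage: config$transitions must name at least one transition with a 'pmf' and a 'strip'")
  states <- config$states %||% default_gate_states()
  profiles <- lapply(names(config$transitions), function(nm) {
    tr <- config$transitions[[nm]]
    if (is.null(tr$pmf)) stop(sprintf("transition '%s': missing WHAM output (stage: wham_2d)", nm))
    if (is.null(tr$strip)) stop(sprintf("transition '%s': missing strip (stage: config)", nm))
    integrate_1d(tr$pmf, tr$kept_axis %||% 1, tr$strip)
  })
  names(profiles) <- names(config$transitions)
  if (!is.null(config$align_state)) {
    st <- states[[config$align_state]]
    if (is.null(st)) stop(sprintf("align_state '%s' not among the state definitions",
                                  config$align_state))
    rng <- state_range_1d(st)
    profiles <- lapply(profiles, function(p) {
      x <- bin_centers(p, 1)
      ok <- x >= rng[1] & x <= rng[2] & is.finite(p$values)
      if (!any(ok)) stop(sprintf("align_state '%s' overlaps no sampled bins",
                                 config$align_state))
      p$values <- p$values - min(p$values[ok])
      p
    })
  }
  pair_names <- t(utils::combn(names(states), 2))
  summarize <- function(p) {
    dg <- apply(pair_names, 1, function(ab)
      state_delta_g(p, states[[ab[1]]], states[[ab[2]]]))
    ba <- t(apply(pair_names, 1, function(ab)
      barrier_height(p, states[[ab[1]]], states[[ab[2]]])))
    data.frame(state_a = pair_names[, 1], state_b = pair_names[, 2],
               delta_g_kbt = dg, barrier_forward_kbt = ba[, 1],
               barrier_reverse_kbt = ba[, 2])
  }
  tables <- lapply(profiles, summarize)
  minima <- lapply(profiles, find_minima)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(profiles)) {
      write_pmf(profiles[[nm]], file.path(output_dir, paste0("profile_", nm, ".txt")))
      write.csv(format(tables[[nm]], digits = 15),
                file.path(output_dir, paste0("states_", nm, ".csv")),
                row.names = FALSE, quote = FALSE)
      write.csv(format(minima[[nm]], digits = 15),
                file.path(output_dir, paste0("minima_", nm, ".csv")),
                row.names = FALSE, quote = FALSE)
    }
  }
  list(profiles = profiles, state_tables = tables, minima = minima)
}

#' @importFrom utils combn write.csv
NULL
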