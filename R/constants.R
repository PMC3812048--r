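#' @useDynLib stringpmf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef lm optim rnorm runif sd setNames var
#' @importFrom utils head read.table tail write.table
NULL

#' Boltzmann constant in kcal/mol/K
#'
#' @format Length-one numeric, 0.0019872041 kcal/mol/K.
#' @export
kB <- 0.0019872041

.default_temperature <- 298.15

#' Thermal energy k_B T
#'
#' @param temperature Temperature in Kelvin. Defaults to 298.15 K, the
#'   simulation temperature the workflow assumes throughout.
#' @return Thermal energy in kcal/mol (about 0.5925 kcal/mol at the default).
#' @export
thermal_energy <- function(temperature = .default_temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  kB * temperature
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one integer master seed;
#' per-window, per-swarm and per-image streams are derived deterministically
#' from it and a stable index tuple, so runs are reproducible regardless of
#' scheduling order.
#'
#' @param master Integer master seed.
#' @param ... One or more non-negative integer indices (window index, swarm
#'   index, iteration number, ...).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (i in seq_along(idx)) {
    # multiplicative hash kept in double precision; all intermediates < 2^53
    h <- (h * 48271 + as.double(idx[i]) * 16807 + i) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
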