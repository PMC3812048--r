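# Deterministic generators for test inputs: toy PDB texts with analytically
# known geometry, exact draws from the closed-form biased distributions of a
# harmonic landscape, and string histories with known convergence behavior.
# Every fixture regenerates byte-identically from its parameters and seed.

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          occupancy = 1, element = NULL, altloc = " ",
                          hetatm = FALSE) {
  element <- element %||% substr(trimws(name), 1, 1)
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (hetatm) "HETATM" else "ATOM", serial, name_f, altloc, resname,
          chain, resid, x, y, z, occupancy, 0, toupper(element))
}

# idealized heavy-atom templates (local coordinates, A); geometry is
# schematic - fixtures only need masses and well-defined positions
.residue_templates <- list(
  ALA = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20)),
  ILE = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.10, -0.95, 1.20),
             CG1 = c(-1.35, -1.75, 1.15), CG2 = c(1.10, -1.85, 1.30),
             CD1 = c(-1.40, -2.70, 2.30)),
  SER = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20),
             OG = c(-1.25, -1.70, 1.15)),
  THR = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20),
             OG1 = c(-1.20, -1.70, 1.10), CG2 = c(1.15, -1.80, 1.30)),
  ASN = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20),
             CG = c(-1.25, -1.75, 1.25), OD1 = c(-2.40, -1.40, 1.50),
             ND2 = c(-0.95, -3.00, 1.10)),
  PHE = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20),
             CG = c(-1.20, -1.80, 1.25), CD1 = c(-2.45, -1.40, 1.70),
             CD2 = c(-1.05, -3.10, 0.85), CE1 = c(-3.50, -2.25, 1.75),
             CE2 = c(-2.10, -3.95, 0.90), CZ = c(-3.35, -3.55, 1.35)),
  GLN = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20),
             CG = c(-1.25, -1.75, 1.25), CD = c(-1.30, -2.75, 2.35),
             OE1 = c(-2.35, -3.40, 2.55), NE2 = c(-0.20, -2.90, 3.10)),
  TRP = list(N = c(-1.20, 0.85, 0), CA = c(0, 0, 0), C = c(1.35, 0.70, 0),
             O = c(1.45, 1.95, 0), CB = c(-0.05, -0.95, 1.20),
             CG = c(-1.20, -1.80, 1.25), CD1 = c(-2.45, -1.55, 1.75),
             CD2 = c(-1.15, -3.15, 0.95), NE1 = c(-3.30, -2.60, 1.65),
             CE2 = c(-2.50, -3.65, 1.10), CE3 = c(-0.15, -4.05, 0.45),
             CZ2 = c(-2.90, -4.95, 0.85), CZ3 = c(-0.55, -5.35, 0.20),
             CH2 = c(-1.90, -5.80, 0.40)))

#' Build a toy PDB text from a residue layout
#'
#' @param layout Data frame with columns `resname`, `resid`, and either
#'   placement columns `x`, `y`, `z` (residue anchor; template atoms are
#'   offset from it) or `atom` plus exact coordinates for single-atom rows.
#'   Optional columns: `chain` (default `"A"`), `atom` (place one named
#'   atom instead of the residue template), `occupancy`, `altloc`,
#'   `hetatm`, `element`.
#' @return Character scalar of PDB text. Atom serials are sequential;
#'   duplicated explicit serials are rejected.
#' @export
make_toy_pdb <- function(layout) {
  stopifnot(is.data.frame(layout), all(c("resname", "resid", "x", "y", "z")
                                       %in% names(layout)))
  if (!is.null(layout$serial) && anyDuplicated(layout$serial))
    stop("duplicate atom serials in layout")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    chain <- if (is.null(row$chain) || is.na(row$chain)) "A" else row$chain
    occ <- if (is.null(row$occupancy) || is.na(row$occupancy)) 1 else row$occupancy
    alt <- if (is.null(row$altloc) || is.na(row$altloc)) " " else row$altloc
    het <- isTRUE(row$hetatm)
    if (!is.null(row$atom) && !is.na(row$atom)) {
      serial <- serial + 1L
      elem <- if (!is.null(row$element) && !is.na(row$element)) row$element else NULL
      lines <- c(lines, pdb_atom_line(serial, row$atom, row$resname, chain,
                                      row$resid, row$x, row$y, row$z, occ,
                                      elem, alt, het))
    } else {
      tmpl <- .residue_templates[[toupper(row$resname)]]
      if (is.null(tmpl))
        stop(sprintf("no residue template for '%s'; give an explicit 'atom'",
                     row$resname))
      for (at in names(tmpl)) {
        serial <- serial + 1L
        p <- tmpl[[at]] + c(row$x, row$y, row$z)
        lines <- c(lines, pdb_atom_line(serial, at, row$resname, chain,
                                        row$resid, p[1], p[2], p[3], occ,
                                        NULL, alt, het))
      }
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Synthetic stand-in structures for the gate-region worked examples
#'
#' SYNTHETIC DATA - these are not the real crystal structures. The true
#' outward-occluded, outward-open and inward-open coordinates (PDB entries
#' that this workflow's worked examples reference) cannot be redistributed
#' or fetched offline, so each stand-in is generated in code: the named
#' thick-gate residues (Ala38/Ile41 on the TM1 side; Ala309/Ser312/Thr313
#' on the TM8 side), the EC thin-gate residues, and a sodium ion are placed
#' with idealized internal geometry such that the heavy-atom COM gate
#' distance equals the printed crystal-structure value by construction
#' (5.3 A outward-occluded, 5.4 A outward-open, 10.2 A inward-open).
#' They validate the parse/select/COM/distance machinery against known
#' geometry, not the real crystals.
#'
#' @param state One of `"outward_occluded"`, `"outward_open"`,
#'   `"inward_open"`.
#' @return PDB text (character scalar).
#' @export
synthetic_gate_structure <- function(state = c("outward_occluded",
                                               "outward_open",
                                               "inward_open")) {
  state <- match.arg(state)
  target <- switch(state, outward_occluded = 5.3, outward_open = 5.4,
                   inward_open = 10.2)
  tm1 <- data.frame(resname = c("ALA", "ILE"), resid = c(38L, 41L),
                    x = c(0, 1.2), y = c(0, 3.8), z = c(0, 1.5))
  tm8 <- data.frame(resname = c("ALA", "SER", "THR"),
                    resid = c(309L, 312L, 313L),
                    x = c(10, 10.8, 9.6), y = c(0.5, 3.9, 6.2),
                    z = c(0.8, 2.0, 3.1))
  ec <- data.frame(resname = c("ASN", "THR", "PHE", "ILE", "ALA", "ALA"),
                   resid = c(360L, 361L, 362L, 47L, 48L, 49L),
                   x = c(3, 4.1, 5.2, 14, 15.1, 16.0),
                   y = c(14, 17.2, 20.1, 14.5, 17.6, 20.4),
                   z = c(10, 11.1, 12.3, 10.4, 11.6, 12.7))
  build_group <- function(df) {
    txt <- make_toy_pdb(df)
    read_structure(txt)
  }
  # shift the TM8 group along x so the heavy-atom COM distance is exact
  fa <- build_group(tm1)
  fb <- build_group(tm8)
  ca <- com(fa, "heavy"); cb <- com(fb, "heavy")
  gap <- cb - ca
  lateral <- sqrt(gap[2]^2 + gap[3]^2)
  if (lateral >= target) stop("internal: lateral offset exceeds target distance")
  tm8$x <- tm8$x + (ca[1] + sqrt(target^2 - lateral^2) - cb[1])
  na_z <- if (state == "inward_open") -26 else 0.4   # released vs bound ion
  na_row <- data.frame(resname = "NA", resid = 501L, x = 5, y = 2,
                       z = 1.0 + na_z, atom = "NA", element = "NA",
                       hetatm = TRUE)
  layout <- rbind(
    cbind(tm1, atom = NA, element = NA, hetatm = FALSE),
    cbind(tm8, atom = NA, element = NA, hetatm = FALSE),
    cbind(ec, atom = NA, element = NA, hetatm = FALSE),
    na_row[, c("resname", "resid", "x", "y", "z", "atom", "element", "hetatm")])
  make_toy_pdb(layout)
}

#' Exact draws from closed-form biased distributions
#'
#' For a 1D harmonic landscape `U = 0.5 k_true x^2` under an umbrella bias
#' `0.5 k_b (x - c)^2`, the biased stationary density is Gaussian with
#' variance `kBT / (k_true + k_b)` and mean `c k_b / (k_true + k_b)`. This
#' generator draws exactly from those Gaussians (no dynamics), giving a
#' sampling oracle for the WHAM solver.
#'
#' @param k_true True landscape stiffness, kcal/mol/A^2 (> 0).
#' @param windows An `umbrella_windows` grid (1D).
#' @param n Draws per window; 0 gives empty, flagged series.
#' @param seed Integer seed.
#' @param temperature Kelvin.
#' @return List of `biased_series`, one per window.
#' @export
make_analytic_biased_series <- function(k_true, windows, n, seed = 1L,
                                        temperature = .default_temperature) {
  stopifnot(k_true > 0, n >= 0)
  kT <- thermal_energy(temperature)
  centers <- window_centers(windows)
  ks <- window_ks(windows)
  stopifnot(ncol(centers) == 1)
  lapply(seq_len(nrow(centers)), function(i) {
    set.seed(derive_seed(seed, i))
    kb <- ks[i, 1]
    mu <- centers[i, 1] * kb / (k_true + kb)
    sigma <- sqrt(kT / (k_true + kb))
    vals <- if (n > 0) rnorm(n, mu, sigma) else numeric(0)
    structure(list(series = matrix(vals, ncol = 1), center = centers[i, ],
                   k = kb, samples_total = n, samples_discarded = 0L,
                   seed = seed, empty = n == 0),
              class = "biased_series")
  })
}

#' String histories with known convergence behavior
#'
#' * `"frozen"`: the string never moves; both convergence metrics are 0.
#' * `"drift-then-freeze"`: rigid drift of `amplitude` per iteration until
#'   `freeze_at`, frozen afterwards; the lag metric hits 0 exactly `lag`
#'   iterations after the freeze.
#' * `"noisy"`: iid Gaussian jitter of scale `amplitude` about a fixed
#'   string; the lag metric plateaus near `amplitude * sqrt(2)`.
#'
#' @param mode Fixture mode.
#' @param n_iterations Iterations recorded after iteration 0.
#' @param n_images,dim String shape.
#' @param amplitude Displacement scale, Angstrom.
#' @param freeze_at Iteration after which a drifting string freezes.
#' @param seed Seed for the noisy mode.
#' @return List of image matrices (`history[[1]]` = iteration 0).
#' @export
make_string_history <- function(mode = c("frozen", "drift-then-freeze",
                                         "noisy"),
                                n_iterations = 20, n_images = 10, dim = 2,
                                amplitude = 0.05, freeze_at = 8, seed = 1L) {
  mode <- match.arg(mode)
  base <- cbind(seq(0, 5, length.out = n_images),
                matrix(0, n_images, dim - 1))
  set.seed(seed)
  lapply(0:n_iterations, function(it) {
    switch(mode,
           frozen = base,
           "drift-then-freeze" = base + amplitude * min(it, freeze_at),
           noisy = base + matrix(rnorm(length(base), 0, amplitude),
                                 n_images, dim))
  })
}
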