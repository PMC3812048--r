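# Binned free-energy maps. A pmf_surface holds min-shifted PMF values on a
# regular bin grid (1D or 2D), a sampled-bin mask, and optional per-bin block
# errors. Masked (never-sampled) bins hold NA and are excluded from the
# min-shift; they are never interpolated.

axis_edges <- function(lo, hi, bin_size) {
  stopifnot(hi > lo, bin_size > 0)
  n <- max(1L, as.integer(ceiling((hi - lo) / bin_size - 1e-9)))
  lo + (0:n) * bin_size
}

#' PMF surface container
#'
#' @param values Numeric array (vector for 1D, matrix for 2D) of free
#'   energies in kcal/mol; `NA` marks unsampled bins.
#' @param axes List of axes, each `list(name =, edges =)` with `edges` of
#'   length `dim + 1`.
#' @param errors Optional array of per-bin standard deviations (kcal/mol).
#' @param temperature Kelvin, used for later kBT conversions.
#' @param shift Min-shift the sampled bins to zero (default TRUE).
#' @return An object of class `pmf_surface`.
#' @export
pmf_surface <- function(values, axes, errors = NULL,
                        temperature = .default_temperature, shift = TRUE) {
  values <- if (length(axes) == 1) as.numeric(values) else as.matrix(values)
  dims <- vapply(axes, function(a) length(a$edges) - 1L, integer(1))
  stopifnot(identical(unname(dims), unname(dim(values) %||% length(values))))
  if (shift && any(is.finite(values)))
    values <- values - min(values, na.rm = TRUE)
  if (!is.null(errors)) stopifnot(all(errors >= 0, na.rm = TRUE))
  structure(list(values = values, axes = axes, mask = is.finite(values),
                 errors = errors, temperature = temperature),
            class = "pmf_surface")
}

#' @export
print.pmf_surface <- function(x, ...) {
  cat(sprintf("<pmf_surface> %s; %d/%d bins sampled; max %s kcal/mol\n",
              paste(vapply(x$axes, function(a)
                sprintf("%s[%g..%g, %d bins]", a$name, min(a$edges),
                        max(a$edges), length(a$edges) - 1L), character(1)),
                collapse = " x "),
              sum(x$mask), length(x$mask),
              signif(suppressWarnings(max(x$values, na.rm = TRUE)), 4)))
  invisible(x)
}

#' Bin centers of a PMF axis
#'
#' @param pmf A [pmf_surface()].
#' @param axis Axis index (1 or 2).
#' @return Numeric vector of bin centers.
#' @export
bin_centers <- function(pmf, axis = 1) {
  e <- pmf$axes[[axis]]$edges
  (head(e, -1) + tail(e, -1)) / 2
}

#' Reference PMF by direct Boltzmann quadrature
#'
#' The ground-truth oracle for every recovery test: on each bin,
#' `-kBT log integral(exp(-U/kBT))` evaluated by midpoint quadrature with
#' `nquad` subdivisions per axis, min-shifted to zero. With `strip`, the
#' non-kept axis is integrated over the given range only, yielding the 1D
#' strip-integrated profile that umbrella sampling + WHAM should recover.
#'
#' @param potential A [model_potential()].
#' @param bin_size Bin width in Angstrom (scalar or per-axis).
#' @param range Optional 2 x d matrix of bounds (default: potential domain).
#' @param kept_axis For strip integration, the axis to keep (default 1).
#' @param strip Optional length-2 range on the other axis; triggers 1D
#'   output.
#' @param nquad Quadrature subdivisions per axis per bin.
#' @param temperature Kelvin.
#' @return A [pmf_surface()] (2D, or 1D when `strip` is given or the
#'   potential is 1D).
#' @export
reference_pmf <- function(potential, bin_size = 0.25, range = NULL,
                          kept_axis = 1, strip = NULL, nquad = 5,
                          temperature = .default_temperature) {
  stopifnot(inherits(potential, "model_potential"))
  d <- potential$dim
  range <- if (is.null(range)) potential$domain else as.matrix(range)
  stopifnot(ncol(range) == d, nrow(range) == 2)
  bin_size <- rep_len(bin_size, d)
  edges <- lapply(seq_len(d), function(j) axis_edges(range[1, j], range[2, j], bin_size[j]))
  if (any(vapply(edges, length, integer(1)) < 2)) stop("empty grid")
  kT <- thermal_energy(temperature)
  packed <- pack_potential(potential)
  sub_centers <- function(e) {      # nquad midpoints inside every bin
    w <- diff(e)
    lo <- head(e, -1)
    as.numeric(outer((seq_len(nquad) - 0.5) / nquad, w) + rep(lo, each = nquad))
  }
  if (d == 1) {
    x <- sub_centers(edges[[1]])
    u <- cpp_potential_eval(packed, matrix(x, ncol = 1))$energy
    w <- exp(-(u - min(u)) / kT)
    dens <- colMeans(matrix(w, nrow = nquad))
    return(pmf_surface(-kT * log(dens),
                       list(list(name = potential$cv_names[1], edges = edges[[1]])),
                       temperature = temperature))
  }
  if (d != 2) stop("reference_pmf supports 1D and 2D potentials")
  if (!is.null(strip)) {
    other <- 3L - as.integer(kept_axis)
    stopifnot(length(strip) == 2, strip[2] > strip[1])
    x <- sub_centers(edges[[kept_axis]])
    ny <- max(nquad * 8L, 40L)
    y <- strip[1] + (seq_len(ny) - 0.5) / ny * (strip[2] - strip[1])
    pts <- matrix(0, length(x) * ny, 2)
    pts[, kept_axis] <- rep(x, each = ny)
    pts[, other] <- rep(y, times = length(x))
    u <- cpp_potential_eval(packed, pts)$energy
    u0 <- min(u)
    wsum <- colMeans(matrix(exp(-(u - u0) / kT), nrow = ny))  # per x sub-center
    dens <- colMeans(matrix(wsum, nrow = nquad))              # per bin
    return(pmf_surface(-kT * log(dens),
                       list(list(name = potential$cv_names[kept_axis],
                                 edges = edges[[kept_axis]])),
                       temperature = temperature))
  }
  x <- sub_centers(edges[[1]])
  y <- sub_centers(edges[[2]])
  pts <- cbind(rep(x, times = length(y)), rep(y, each = length(x)))
  u <- cpp_potential_eval(packed, pts)$energy
  u0 <- min(u)
  w <- matrix(exp(-(u - u0) / kT), nrow = length(x))
  nx <- length(edges[[1]]) - 1L
  nyb <- length(edges[[2]]) - 1L
  vals <- matrix(0, nx, nyb)
  for (i in seq_len(nx)) {
    rows <- ((i - 1) * nquad + 1):(i * nquad)
    for (j in seq_len(nyb)) {
      cols <- ((j - 1) * nquad + 1):(j * nquad)
      vals[i, j] <- mean(w[rows, cols])
    }
  }
  pmf_surface(-kT * log(vals),
              list(list(name = potential$cv_names[1], edges = edges[[1]]),
                   list(name = potential$cv_names[2], edges = edges[[2]])),
              temperature = temperature)
}

#' Write / read a PMF surface as plain text
#'
#' Layout: comment header with axis names and bin edges at full precision,
#' then the value matrix (rows = first axis) with `NA` for masked bins, then
#' an optional error matrix. Identical layout for 1D (a single row).
#'
#' @param pmf A [pmf_surface()].
#' @param path File path.
#' @return `read_pmf` returns the [pmf_surface()].
#' @export
write_pmf <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in pmf$axes)
    writeLines(sprintf("# axis %s %s", a$name,
                       paste(sprintf("%.17g", a$edges), collapse = " ")), con)
  writeLines(sprintf("# temperature %.17g", pmf$temperature), con)
  vals <- if (is.matrix(pmf$values)) pmf$values else matrix(pmf$values, nrow = 1)
  writeLines("# values", con)
  writeLines(apply(vals, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  if (!is.null(pmf$errors)) {
    errs <- if (is.matrix(pmf$errors)) pmf$errors else matrix(pmf$errors, nrow = 1)
    writeLines("# errors", con)
    writeLines(apply(errs, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  ax_lines <- grep("^# axis ", lines, value = TRUE)
  axes <- lapply(ax_lines, function(l) {
    parts <- strsplit(sub("^# axis ", "", l), " ")[[1]]
    list(name = parts[1], edges = as.numeric(parts[-1]))
  })
  temperature <- as.numeric(sub("^# temperature ", "",
                                grep("^# temperature", lines, value = TRUE)))
  read_block <- function(tag) {
    i <- which(lines == paste0("# ", tag))
    if (!length(i)) return(NULL)
    j <- i + 1
    out <- list()
    while (j <= length(lines) && !startsWith(lines[j], "#")) {
      v <- strsplit(lines[j], " ")[[1]]
      v[v == "NA"] <- NA_character_
      out[[length(out) + 1]] <- as.numeric(v)
      j <- j + 1
    }
    do.call(rbind, out)
  }
  vals <- read_block("values")
  errs <- read_block("errors")
  if (length(axes) == 1) {
    vals <- as.numeric(vals)
    if (!is.null(errs)) errs <- as.numeric(errs)
  }
  pmf_surface(vals, axes, errors = errs, temperature = temperature,
              shift = FALSE)
}
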