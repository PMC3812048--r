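# Minimal fixed-column PDB reader. No pre-installed R package parses PDB, and
# the workflow pins specific altloc/MODEL semantics, so this is written here:
# ATOM/HETATM records, one frame per MODEL, altloc resolved to the highest
# occupancy conformer (ties -> 'A'), element inferred from the atom name when
# the element columns are blank.

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  NAotm = 22.990, CL = 35.45, K = 39.098, MG = 24.305, CA = 40.078,
  FE = 55.845, ZN = 65.38, MN = 54.938, BR = 79.904, I = 126.904, F = 18.998,
  SE = 78.971)

element_mass <- function(element, atom_label = element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NAotm"
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("unknown element '%s' (atom %s): no mass available",
                 element[bad], atom_label[bad]))
  }
  unname(m)
}

# PDB convention: element is the first letter of the left-justified atom name,
# except names starting in columns 13 with a digit/H* (hydrogens) or two-letter
# ions spelled in columns 13-14 (NA, CL, FE, MG, ZN, ...).
infer_element <- function(atom_name, resname) {
  nm <- toupper(trimws(atom_name))
  two <- substr(nm, 1, 2)
  ions <- c("NA", "CL", "FE", "MG", "ZN", "MN", "BR", "SE")
  el <- ifelse(grepl("^[0-9]", nm) | grepl("^H", nm), "H",
               substr(nm, 1, 1))
  ion_hit <- two %in% ions & toupper(trimws(resname)) %in% c(ions, "CLA", "SOD", "POT")
  el[ion_hit] <- two[ion_hit]
  el
}

parse_pdb_frame <- function(lines, frame_id) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) return(NULL)
  f <- function(a, b) substr(lines, a, b)
  df <- data.frame(
    record = trimws(f(1, 6)),
    serial = suppressWarnings(as.integer(f(7, 11))),
    name = trimws(f(13, 16)),
    altloc = f(17, 17),
    resname = trimws(f(18, 20)),
    chain = f(22, 22),
    resid = suppressWarnings(as.integer(f(23, 26))),
    insert = f(27, 27),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)), z = as.numeric(f(47, 54)),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    element = trimws(f(77, 78)),
    stringsAsFactors = FALSE)
  df$occupancy[is.na(df$occupancy)] <- 1
  blank <- df$element == ""
  df$element[blank] <- infer_element(df$name[blank], df$resname[blank])
  # altloc: keep the highest-occupancy conformer per atom; ties -> 'A'
  alt <- df$altloc != " " & df$altloc != ""
  if (any(alt)) {
    key <- paste(df$chain, df$resid, df$insert, df$resname, df$name)
    keep_rows <- rep(TRUE, nrow(df))
    for (k in unique(key[alt])) {
      rows <- which(key == k)
      if (length(rows) < 2) next
      occ <- df$occupancy[rows]
      best <- rows[occ == max(occ)]
      if (length(best) > 1) {
        pick <- best[order(df$altloc[best])][1]
      } else pick <- best
      keep_rows[setdiff(rows, pick)] <- FALSE
    }
    df <- df[keep_rows, , drop = FALSE]
  }
  df$mass <- element_mass(df$element,
                          paste0(df$resname, df$resid, "/", df$name))
  df$frame_id <- frame_id
  rownames(df) <- NULL
  class(df) <- c("frame_coordinates", "data.frame")
  df
}

#' Read a structure from PDB text
#'
#' One frame per `MODEL` record (a single frame when no MODEL records are
#' present). `ATOM` and `HETATM` records are retained; alternate locations
#' are resolved to the highest-occupancy conformer (ties broken toward
#' conformer `A`); missing element columns are inferred from the atom name.
#'
#' @param pdb_source Path to a PDB file, or a character vector of PDB lines
#'   (anything containing a newline or more than one element is treated as
#'   text).
#' @return A single `frame_coordinates` data frame, or a list of frames for
#'   multi-MODEL input. Columns include `resname`, `resid`, `chain`, `name`,
#'   `element`, `mass`, `x`, `y`, `z`.
#' @export
read_structure <- function(pdb_source) {
  lines <- if (length(pdb_source) == 1 && !grepl("\n", pdb_source) &&
               file.exists(pdb_source)) readLines(pdb_source)
  else unlist(strsplit(pdb_source, "\n", fixed = TRUE))
  starts <- which(startsWith(lines, "MODEL"))
  if (length(starts) == 0) {
    fr <- parse_pdb_frame(lines, 1L)
    if (is.null(fr)) stop("no ATOM/HETATM records found: empty structure")
    return(fr)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- lapply(seq_along(starts), function(i)
    parse_pdb_frame(lines[starts[i]:ends[i]], i))
  frames <- Filter(Negate(is.null), frames)
  if (!length(frames)) stop("no ATOM/HETATM records found: empty structure")
  if (length(frames) == 1) frames[[1]] else frames
}

#' Select atoms with a small selection language
#'
#' Expressions are `and`-joined clauses:
#' * `chain A` - chain identifier(s)
#' * `resid 38 41` or `resid 296:329` - residue numbers (author numbering)
#' * `resname ALA ILE` - residue names
#' * `name CA` or `name C*` - atom-name globs
#' * `heavy` / `noh` - drop hydrogens
#' * `protein` - standard amino-acid residues only
#' * `hetero` - HETATM records only
#'
#' @param frame A `frame_coordinates` data frame from [read_structure()].
#' @param expr Selection string, e.g. `"resid 38 41 and heavy"`.
#' @return The selected rows of `frame`; errors if the selection resolves to
#'   no atoms, naming the expression.
#' @export
select_atoms <- function(frame, expr) {
  stopifnot(is.data.frame(frame), is.character(expr), length(expr) == 1)
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
          "THR", "TRP", "TYR", "VAL")
  keep <- rep(TRUE, nrow(frame))
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (!length(tok)) next
    key <- tolower(tok[1])
    args <- tok[-1]
    keep <- keep & switch(key,
      chain = frame$chain %in% args,
      resid = {
        ids <- unlist(lapply(args, function(a) {
          if (grepl(":", a)) {
            r <- as.integer(strsplit(a, ":")[[1]])
            seq(r[1], r[2])
          } else as.integer(a)
        }))
        frame$resid %in% ids
      },
      resname = toupper(frame$resname) %in% toupper(args),
      name = {
        pats <- glob2rx(toupper(args))
        Reduce(`|`, lapply(pats, function(p) grepl(p, toupper(frame$name))))
      },
      heavy = frame$element != "H",
      noh = frame$element != "H",
      protein = toupper(frame$resname) %in% aa,
      hetero = frame$record == "HETATM",
      stop(sprintf("unknown selection keyword '%s' in '%s'", key, expr)))
  }
  out <- frame[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop(sprintf("selection '%s' resolves to no atoms", expr))
  out
}

#' @importFrom utils glob2rx
NULL
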