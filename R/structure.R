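#' Atomic structures
#'
#' An `atomic_structure` is a light S3 container for a set of atoms: a
#' data frame with one row per atom and the columns `serial`, `element`,
#' `vdw_radius` (Angstrom), `x`, `y`, `z` (Angstrom), `occupancy`,
#' `b_factor`, `chain_id`, `residue_number`, `residue_name`, `atom_name`
#' and `record` ("ATOM" or "HETATM").  An optional secondary-structure
#' annotation (see [sse_segments()]) is carried in the `sse` attribute.
#'
#' @param atoms data frame with the columns listed above (`vdw_radius`
#'   may be omitted and is then assigned from the element table).
#' @param sse optional data frame of secondary-structure segments, see
#'   [sse_segments()].
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(atoms, sse = NULL) {
  required <- c("serial", "element", "x", "y", "z", "occupancy",
                "b_factor", "chain_id", "residue_number", "residue_name",
                "atom_name")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$record)) atoms$record <- "ATOM"
  if (is.null(atoms$vdw_radius))
    atoms$vdw_radius <- vdw_radius(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be > 0")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), sse = sse, class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("atomic_structure: %d atoms, %d residue(s), chain(s): %s\n",
              nrow(a),
              length(unique(paste(a$chain_id, a$residue_number))),
              paste(unique(a$chain_id), collapse = ", ")))
  sse <- attr(x, "sse")
  if (!is.null(sse))
    cat(sprintf("  %d secondary-structure segment(s)\n", nrow(sse)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `atomic_structure`.
#' @return Integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as a matrix
#' @param structure an `atomic_structure`.
#' @return n x 3 numeric matrix of coordinates in Angstrom.
#' @export
coords <- function(structure) {
  unname(as.matrix(structure$atoms[, c("x", "y", "z")]))
}

#' Replace atom coordinates
#' @param structure an `atomic_structure`.
#' @param xyz n x 3 matrix of new coordinates, same atom order.
#' @return The structure with updated coordinates.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == n_atoms(structure), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# Bundled van der Waals radii (Angstrom); unlisted elements fall back to
# the carbon value.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.vdw_default <- 1.70

# Atomic numbers of the elements that occur in protein work.
.z_table <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16,
              MG = 12, CA = 20, MN = 25, FE = 26, ZN = 30, CL = 17,
              "NA" = 11, K = 19, I = 53)

#' Van der Waals radius lookup
#' @param element character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- .vdw_default
  unname(r)
}

#' Atomic number lookup
#' @param element character vector of element symbols.
#' @return Integer vector of atomic numbers (carbon for unknown symbols).
#' @export
atomic_number <- function(element) {
  z <- .z_table[toupper(element)]
  z[is.na(z)] <- 6
  unname(z)
}

#' Secondary-structure segment table
#'
#' @param kind character vector, each one of "helix", "strand", "loop".
#' @param chain_id chain identifiers.
#' @param start_residue,end_residue inclusive residue-number ranges.
#' @param label segment labels.
#' @return A data frame of class `sse_segments`.
#' @export
sse_segments <- function(kind, chain_id, start_residue, end_residue, label) {
  if (!all(kind %in% c("helix", "strand", "loop")))
    stop("kind must be helix, strand or loop")
  if (any(start_residue > end_residue))
    stop("start_residue must be <= end_residue")
  seg <- data.frame(kind = kind, chain_id = chain_id,
                    start_residue = as.integer(start_residue),
                    end_residue = as.integer(end_residue),
                    label = label, stringsAsFactors = FALSE)
  for (ch in unique(seg$chain_id)) {
    s <- seg[seg$chain_id == ch, ]
    s <- s[order(s$start_residue), ]
    if (nrow(s) > 1L && any(s$start_residue[-1L] <= s$end_residue[-nrow(s)]))
      stop("overlapping segments within chain ", ch)
  }
  class(seg) <- c("sse_segments", "data.frame")
  seg
}

#' Read an atomic structure from a PDB file
#'
#' Parses fixed-column PDB records via bio3d, resolves alternate
#' locations to the highest-occupancy conformer (ties broken by alt-loc
#' letter), assigns van der Waals radii from the bundled element table
#' and optionally restricts to a single chain.  HETATM records are
#' parsed and retained in the atom table but carry `record = "HETATM"`
#' so that downstream geometry can exclude them; hydrogens are kept in
#' the table for the same reason.
#'
#' @param path PDB file.
#' @param chain_filter optional chain identifier; only that chain is
#'   returned.
#' @return An `atomic_structure`.
#' @export
read_structure <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path,
                             ": ", conditionMessage(e)))
  a <- pdb$atom
  if (!is.null(chain_filter)) {
    a <- a[a$chain %in% chain_filter, , drop = FALSE]
    if (nrow(a) == 0L)
      stop("empty selection: chain '", chain_filter, "' not present")
  }
  # alt-loc resolution: highest occupancy wins, ties by letter order
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(a$chain, a$resno, a$elety, sep = "|")
    occ <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(key, -occ, alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1L, 1L)
  elem <- trimws(elem)
  blank <- is.na(elem) | elem == ""
  elem[blank] <- substr(trimws(a$elety[blank]), 1L, 1L)
  atoms <- data.frame(
    serial = a$eleno,
    element = toupper(elem),
    x = a$x, y = a$y, z = a$z,
    occupancy = pmin(1, pmax(0, ifelse(is.na(a$o), 1, a$o))),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    chain_id = ifelse(is.na(a$chain), "A", a$chain),
    residue_number = a$resno,
    residue_name = a$resid,
    atom_name = trimws(a$elety),
    record = a$type,
    stringsAsFactors = FALSE)
  atomic_structure(atoms)
}

#' Write an atomic structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records with coordinates to three
#' decimals.
#'
#' @param structure an `atomic_structure` with at least one atom.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords(structure))),
    type = a$record,
    resno = a$residue_number,
    resid = a$residue_name,
    eleno = a$serial,
    elety = a$atom_name,
    chain = a$chain_id,
    o = a$occupancy,
    b = a$b_factor,
    elesy = a$element)
  invisible(path)
}

#' Select the heavy (non-hydrogen) polymer atoms of a structure
#'
#' Downstream geometry (density simulation, SASA, contacts) operates on
#' heavy ATOM-record atoms by default; this helper applies that
#' convention.
#'
#' @param structure an `atomic_structure`.
#' @param include_hetatm keep HETATM records too (default FALSE).
#' @return An `atomic_structure` containing the selected atoms.
#' @export
heavy_atoms <- function(structure, include_hetatm = FALSE) {
  a <- structure$atoms
  keep <- toupper(a$element) != "H"
  if (!include_hetatm) keep <- keep & a$record == "ATOM"
  out <- atomic_structure(a[keep, , drop = FALSE], sse = attr(structure, "sse"))
  out
}

#' Apply a chain filter to a structure
#' @param structure an `atomic_structure`.
#' @param chain_id chain to keep.
#' @return The filtered `atomic_structure`; errors if the chain is absent.
#' @export
filter_chain <- function(structure, chain_id) {
  a <- structure$atoms
  keep <- a$chain_id %in% chain_id
  if (!any(keep)) stop("empty selection: chain '", chain_id, "' not present")
  atomic_structure(a[keep, , drop = FALSE], sse = attr(structure, "sse"))
}
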