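#' Conformer structure object
#'
#' A single protein conformer: named atoms with 3-D coordinates grouped by
#' residue. The atom table is ordered by residue; residue indices must be
#' non-decreasing, atom names unique within a residue, and all coordinates
#' finite.
#'
#' @param atoms data.frame with columns `resno` (1-based integer residue
#'   index), `resname` (3-letter residue code), `atom` (standard PDB atom
#'   name), `element` (element symbol), and `x`, `y`, `z` (coordinates, in
#'   Angstrom).
#' @param model_id integer model label (default 1).
#' @param meta named list of free-form provenance tags (pool source,
#'   generation parameters, ground-truth labels).
#' @return An object of class `xs_structure`.
#' @export
xs_structure <- function(atoms, model_id = 1L, meta = list()) {
  req <- c("resno", "resname", "atom", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom")
  if (is.unsorted(atoms$resno))
    stop("residue indices must be non-decreasing over the atom list")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  key <- paste(atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("atom names must be unique within a residue (duplicated: ",
         key[anyDuplicated(key)], ")")
  structure(list(atoms = atoms, model_id = as.integer(model_id), meta = meta),
            class = "xs_structure")
}

#' @export
print.xs_structure <- function(x, ...) {
  nres <- length(unique(x$atoms$resno))
  cat(sprintf("<xs_structure> model %d: %d atoms, %d residues, Rg %.2f A\n",
              x$model_id, nrow(x$atoms), nres, radius_of_gyration(x)))
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param s an `xs_structure`.
#' @param idx optional integer vector of atom rows to extract.
#' @return numeric n x 3 matrix in Angstrom.
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#'
#' @param s an `xs_structure`.
#' @param xyz numeric n x 3 matrix matching the atom count.
#' @return the modified `xs_structure`.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3L)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# ---- atom selections --------------------------------------------------------

.selection_atoms <- list(
  mainchain_cb = c("N", "CA", "C", "O", "CB"),
  amide_pair   = c("N", "H"),
  all_atoms    = NULL
)

#' Named atom selection
#'
#' Predicates used throughout the package: `mainchain_cb` selects
#' \{N, CA, C, O, CB\} (the clustering criterion set; glycine contributes
#' only its four backbone atoms), `amide_pair` selects \{N, H\}, and
#' `all_atoms` selects everything.
#'
#' @param name one of `"mainchain_cb"`, `"amide_pair"`, `"all_atoms"`.
#' @return An object of class `xs_selection`.
#' @export
atom_selection <- function(name = c("mainchain_cb", "amide_pair", "all_atoms")) {
  name <- match.arg(name)
  structure(list(name = name, atoms = .selection_atoms[[name]]),
            class = "xs_selection")
}

#' Resolve a selection on one structure
#'
#' @param sel an `xs_selection`.
#' @param s an `xs_structure`.
#' @return integer vector of atom row indices, in residue-then-name order.
#' @export
resolve_selection <- function(sel, s) {
  stopifnot(inherits(sel, "xs_selection"), inherits(s, "xs_structure"))
  if (is.null(sel$atoms)) return(seq_len(nrow(s$atoms)))
  which(s$atoms$atom %in% sel$atoms)
}

# Matched-pair resolution on two structures with identical residue sequences.
# An atom participates only if present (by residue index + atom name) in BOTH
# structures, so a missing glycine CB is skipped consistently on both sides.
#' Resolve a selection as matched atom pairs on two structures
#'
#' @param sel an `xs_selection`.
#' @param a,b `xs_structure` objects over the same residue sequence.
#' @return list with integer vectors `ia`, `ib` of equal length giving
#'   matched atom rows in `a` and `b`.
#' @export
resolve_pair <- function(sel, a, b) {
  ia <- resolve_selection(sel, a)
  ib <- resolve_selection(sel, b)
  ka <- paste(a$atoms$resno[ia], a$atoms$atom[ia])
  kb <- paste(b$atoms$resno[ib], b$atoms$atom[ib])
  common <- intersect(ka, kb)
  if (!length(common))
    stop("selection '", sel$name, "' resolves to zero matched atoms")
  list(ia = ia[match(common, ka)], ib = ib[match(common, kb)])
}

# ---- PDB I/O ----------------------------------------------------------------

.element_from_atom <- function(atom) {
  # PDB convention: element is the first alphabetic character of the atom
  # name unless a two-letter element is given in columns 77-78 (handled by
  # the parser when present).
  sub("^[0-9]*([A-Za-z]).*$", "\\1", atom)
}

#' Read a (multi-model) PDB file into a list of structures
#'
#' Reads the ATOM/MODEL/ENDMDL subset of the PDB format. One `xs_structure`
#' is returned per MODEL block (a single-model file yields a list of one).
#' Alternate locations other than blank or 'A' are discarded; residue
#' numbering is taken from the file.
#'
#' @param path path to a PDB file.
#' @return list of `xs_structure` objects with `model_id` from the file (or
#'   1 for a model-less file).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  # validate coordinate fields before handing off to the parser so malformed
  # records are reported with their line number
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed ATOM record at line ", i,
                             " (truncated before coordinates)")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM record at line ", i, " (non-numeric coordinates)")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .element_from_atom(at$elety[bad])
  nmod <- nrow(pdb$xyz)
  # model ids as written in the file, when MODEL records are present
  model_ids <- seq_len(nmod)
  mod_lines <- grep("^MODEL", lines, value = TRUE)
  if (length(mod_lines) == nmod) {
    ids <- suppressWarnings(as.integer(sub("^MODEL\\s+", "", mod_lines)))
    if (!any(is.na(ids))) model_ids <- ids
  }
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    xs_structure(data.frame(resno = at$resno, resname = at$resid,
                            atom = at$elety, element = toupper(elem),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE),
                 model_id = model_ids[m],
                 meta = list(source = path))
  })
}

#' Write structures to a (multi-model) PDB file
#'
#' Writes standard fixed-width ATOM records with occupancy 1.00 and B-factor
#' 0.00, rounding coordinates to 3 decimals (PDB precision). With
#' `ensemble = TRUE` (default) MODEL/ENDMDL blocks are written even for a
#' single conformer, so multi-model handling stays uniform.
#'
#' @param structures list of `xs_structure` objects (or a single one).
#' @param path output file path.
#' @param ensemble write MODEL/ENDMDL blocks even for one structure.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path, ensemble = TRUE) {
  if (inherits(structures, "xs_structure")) structures <- list(structures)
  if (!length(structures)) stop("no structures to write")
  con <- file(path, "w")
  on.exit(close(con))
  multi <- ensemble || length(structures) > 1L
  for (k in seq_along(structures)) {
    s <- structures[[k]]
    xyz <- coords(s)
    if (any(abs(xyz) >= 10000))
      stop("coordinate magnitude >= 10000 A cannot be written in PDB fixed width")
    if (multi) writeLines(sprintf("MODEL     %4d", s$model_id), con)
    a <- s$atoms
    nm <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom), a$atom)
    writeLines(sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)), nm, a$resname, a$resno,
      a$x, a$y, a$z, 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
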