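#' @importFrom stats setNames
#' @importFrom utils head read.csv write.csv
NULL

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

#' Construct a structure model from an atom table
#'
#' A `structure_model` is the package's representation of a single protein
#' conformation: an ordered atom table grouped into residues, with free-form
#' metadata.  Residues follow the author numbering of the source file
#' (1-based, inclusive ranges).  All coordinates are in Angstrom.
#'
#' @param atoms data frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resnum`, `icode`, `x`, `y`, `z`, `occupancy`, `bfactor`, `element`.
#'   Rows must be grouped by residue in file order.
#' @param metadata named list of free-form metadata (e.g. source path,
#'   HETATM records).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, metadata = list()) {
  required <- c("serial", "name", "resname", "chain", "resnum", "icode",
                "x", "y", "z", "occupancy", "bfactor", "element")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  atoms$icode[is.na(atoms$icode)] <- ""

  key <- residue_key_string(atoms$chain, atoms$resnum, atoms$icode)
  runs <- rle(key)
  if (anyDuplicated(runs$values)) {
    dup <- runs$values[duplicated(runs$values)][1]
    stop("duplicate residue key: ", dup)
  }
  atoms$ridx <- rep(seq_along(runs$values), runs$lengths)

  first <- !duplicated(atoms$ridx)
  residues <- data.frame(
    ridx = atoms$ridx[first],
    chain = atoms$chain[first],
    resnum = atoms$resnum[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    standard = atoms$resname[first] %in% STANDARD_AA,
    stringsAsFactors = FALSE
  )

  structure(
    list(atoms = atoms, residues = residues, metadata = metadata),
    class = "structure_model"
  )
}

residue_key_string <- function(chain, resnum, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(chain, ":", resnum, ifelse(nzchar(icode), icode, ""))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d atoms, %d chain(s)\n",
              nrow(x$residues), nrow(x$atoms),
              length(unique(x$residues$chain))))
  invisible(x)
}

#' Number of residues / atoms in a structure
#' @param structure a `structure_model`
#' @return integer count
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' @rdname n_residues
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param structure a `structure_model`
#' @return numeric matrix with one row per atom
#' @export
atom_coords <- function(structure) {
  cbind(x = structure$atoms$x, y = structure$atoms$y, z = structure$atoms$z)
}

# Resolve a residue to its internal index; errors if absent.
residue_index <- function(structure, resnum, chain = NULL, icode = "") {
  res <- structure$residues
  if (is.null(chain)) chain <- res$chain[1]
  hit <- which(res$chain == chain & res$resnum == resnum & res$icode == icode)
  if (length(hit) == 0) {
    stop("residue not found: ", residue_key_string(chain, resnum, icode))
  }
  hit
}

# Row index in the atom table of a named atom of one residue (NA if absent).
atom_row <- function(structure, ridx, name) {
  rows <- which(structure$atoms$ridx == ridx & structure$atoms$name == name)
  if (length(rows) == 0) NA_integer_ else rows[1]
}

#' Look up one atom of one residue
#'
#' Returns the coordinates of a named atom (e.g. `"CA"`, `"CB"`, `"N"`) of a
#' residue, or `NULL` when that atom is absent.  Glycine has no beta carbon,
#' so `residue_atom(s, r, "CB")` is `NULL` for glycine residues.
#'
#' @param structure a `structure_model`
#' @param resnum author residue number
#' @param name atom name
#' @param chain chain identifier; defaults to the first chain
#' @param icode insertion code, default empty
#' @return length-3 numeric vector of coordinates (Angstrom), or `NULL`
#' @export
residue_atom <- function(structure, resnum, name, chain = NULL, icode = "") {
  ridx <- residue_index(structure, resnum, chain, icode)
  row <- atom_row(structure, ridx, name)
  if (is.na(row)) return(NULL)
  unname(c(structure$atoms$x[row], structure$atoms$y[row], structure$atoms$z[row]))
}

#' Read a single-conformation PDB file
#'
#' Parses a PDB file into a [structure_model()].  For multi-model files only
#' MODEL 1 is used.  HETATM records are kept in `metadata$hetatm` and excluded
#' from the residue list.  Alternate locations other than blank or `'A'` are
#' dropped with a warning.
#'
#' @param path path to a PDB file
#' @return a `structure_model`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atom <- pdb$atom
  is_atom <- atom$type == "ATOM"
  if (!any(is_atom)) stop("no ATOM records in ", path)

  alt <- atom$alt
  keep_alt <- is.na(alt) | alt %in% c("", "A")
  if (any(is_atom & !keep_alt)) {
    warning("dropping ", sum(is_atom & !keep_alt),
            " alternate-location atoms (keeping altloc 'A'/blank)")
  }

  het <- atom[!is_atom, , drop = FALSE]
  atom <- atom[is_atom & keep_alt, , drop = FALSE]
  if (nrow(atom) == 0) stop("no ATOM records in ", path)

  atoms <- data.frame(
    serial = atom$eleno,
    name = atom$elety,
    resname = atom$resid,
    chain = ifelse(is.na(atom$chain), "A", atom$chain),
    resnum = atom$resno,
    icode = ifelse(is.na(atom$insert), "", atom$insert),
    x = atom$x, y = atom$y, z = atom$z,
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    bfactor = ifelse(is.na(atom$b), 0, atom$b),
    element = ifelse(is.na(atom$elesy), substr(atom$elety, 1, 1), atom$elesy),
    stringsAsFactors = FALSE
  )
  metadata <- list(source = path)
  if (nrow(het) > 0) metadata$hetatm <- het
  structure_model(atoms, metadata)
}

#' Write a structure to a PDB file
#'
#' Standard fixed-column PDB formatting; coordinates are rounded to three
#' decimals by the format.  Atom serials above 99999 wrap around, per the
#' fixed-width convention.
#'
#' @param structure a `structure_model`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_pdb <- function(structure, path) {
  if (!inherits(structure, "structure_model")) stop("not a structure_model")
  a <- structure$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(atom_coords(structure))),
    type = rep("ATOM", nrow(a)),
    eleno = a$serial %% 100000L,
    elety = a$name,
    resid = a$resname,
    chain = a$chain,
    resno = a$resnum,
    insert = ifelse(nzchar(a$icode), a$icode, ""),
    o = a$occupancy,
    b = a$bfactor,
    elesy = a$element
  )
  invisible(path)
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' The ensemble stands in for an MD trajectory sampled at one simulated
#' temperature: an ordered set of frames sharing one topology.  Frames are
#' ordered by MODEL number; the topology is taken from the first model.
#' Every model must contain the same number of ATOM records.
#'
#' @param path path to a (possibly multi-model) PDB file
#' @param temperature temperature label in Kelvin (e.g. 300), or `NA`
#' @return an object of class `structure_ensemble` with fields `topology`
#'   (a `structure_model`), `xyz` (frames x 3*n_atoms coordinate matrix),
#'   `frame_times` (ps, or `NULL`) and `temperature`
#' @export
read_ensemble <- function(path, temperature = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  rec <- substr(lines, 1, 6)
  is_atom_line <- rec == "ATOM  "
  if (length(model_starts) > 1) {
    model_id <- findInterval(seq_along(lines), model_starts)
    counts <- tapply(is_atom_line[model_id > 0], model_id[model_id > 0], sum)
    model_no <- suppressWarnings(as.integer(substr(lines[model_starts], 7, 20)))
    if (anyNA(model_no)) model_no <- seq_along(model_starts)
    if (length(unique(counts)) > 1) {
      bad <- model_no[counts != counts[1]]
      stop("inconsistent atom counts across models; model(s) ",
           paste(bad, collapse = ", "), " differ from model ", model_no[1])
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  atom <- pdb$atom
  keep <- atom$type == "ATOM" & (is.na(atom$alt) | atom$alt %in% c("", "A"))
  if (!any(keep)) stop("no ATOM records in ", path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " HETATM/altloc atoms from ensemble")
    xyz <- xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
    atom <- atom[keep, , drop = FALSE]
  }
  topo_atoms <- data.frame(
    serial = atom$eleno,
    name = atom$elety,
    resname = atom$resid,
    chain = ifelse(is.na(atom$chain), "A", atom$chain),
    resnum = atom$resno,
    icode = ifelse(is.na(atom$insert), "", atom$insert),
    x = xyz[1, bio3d::atom2xyz(seq_len(nrow(atom)))[c(TRUE, FALSE, FALSE)]],
    y = xyz[1, bio3d::atom2xyz(seq_len(nrow(atom)))[c(FALSE, TRUE, FALSE)]],
    z = xyz[1, bio3d::atom2xyz(seq_len(nrow(atom)))[c(FALSE, FALSE, TRUE)]],
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    bfactor = ifelse(is.na(atom$b), 0, atom$b),
    element = ifelse(is.na(atom$elesy), substr(atom$elety, 1, 1), atom$elesy),
    stringsAsFactors = FALSE
  )
  topology <- structure_model(topo_atoms, metadata = list(source = path))
  new_ensemble(topology, xyz, frame_times = NULL, temperature = temperature)
}

new_ensemble <- function(topology, xyz, frame_times = NULL,
                         temperature = NA_real_) {
  if (ncol(xyz) != 3L * n_atoms(topology)) {
    stop("frame width (", ncol(xyz), ") does not match topology atom count (",
         n_atoms(topology), " atoms)")
  }
  if (!is.null(frame_times)) {
    if (length(frame_times) != nrow(xyz)) stop("frame_times length mismatch")
    if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  }
  structure(
    list(topology = topology, xyz = xyz, frame_times = frame_times,
         temperature = temperature),
    class = "structure_ensemble"
  )
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d frame(s), %d atoms, temperature %s K\n",
              n_frames(x), n_atoms(x$topology),
              ifelse(is.na(x$temperature), "?", format(x$temperature))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `structure_ensemble`
#' @return integer
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Extract one frame of an ensemble as an atom coordinate matrix
#' @param ensemble a `structure_ensemble`
#' @param i frame index (1-based)
#' @return n_atoms x 3 coordinate matrix (Angstrom)
#' @export
frame_coords <- function(ensemble, i) {
  if (i < 1 || i > n_frames(ensemble)) stop("frame index out of range: ", i)
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

# Replace the coordinates of a structure (atom order preserved).
set_coords <- function(structure, coords) {
  stopifnot(nrow(coords) == n_atoms(structure))
  structure$atoms$x <- coords[, 1]
  structure$atoms$y <- coords[, 2]
  structure$atoms$z <- coords[, 3]
  structure
}

# A structure holding frame i of an ensemble.
frame_structure <- function(ensemble, i) {
  set_coords(ensemble$topology, frame_coords(ensemble, i))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Each frame becomes one MODEL/ENDMDL block in frame order.
#'
#' @param ensemble a `structure_ensemble`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_ensemble <- function(ensemble, path) {
  a <- ensemble$topology$atoms
  n <- nrow(a)
  con <- file(path, "w")
  on.exit(close(con))
  fmt_name <- function(nm) {
    # PDB atom-name column: element right-aligned in cols 13-14
    ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  name_field <- fmt_name(a$name)
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- frame_coords(ensemble, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, name_field, "", a$resname, a$chain, a$resnum,
      ifelse(nzchar(a$icode), a$icode, " "),
      xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, a$bfactor, a$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
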