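#' Default analysis window of an ensemble
#'
#' Analysis windows are frame-index based.  The default keeps the last 75%
#' of frames, discarding the initial quarter as equilibration — the same
#' proportion as analysing 5-20 ns of a 20 ns run.
#'
#' @param n total number of frames
#' @param fraction fraction of trailing frames to keep, in (0, 1]
#' @return integer vector of frame indices
#' @export
default_window <- function(n, fraction = 0.75) {
  if (n < 1) stop("ensemble has no frames")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  start <- n - ceiling(n * fraction) + 1L
  seq.int(max(1L, start), n)
}

# Resolve an atom selection on a topology to atom row indices.
# selection: "calpha", "backbone", or a character vector of atom names.
selection_rows <- function(structure, selection = "calpha") {
  names_wanted <- switch(
    selection[1],
    calpha = "CA",
    backbone = c("N", "CA", "C", "O"),
    selection
  )
  which(structure$atoms$name %in% names_wanted)
}

# Match selected atoms of `structure` against `reference` by residue key +
# atom name; returns list(rows_a, rows_b) of equal length.
match_selection <- function(structure, reference, selection = "calpha") {
  rows_a <- selection_rows(structure, selection)
  rows_b <- selection_rows(reference, selection)
  key <- function(s, rows) {
    a <- s$atoms[rows, ]
    paste(a$chain, a$resnum, a$icode, a$name)
  }
  ka <- key(structure, rows_a)
  kb <- key(reference, rows_b)
  common <- intersect(ka, kb)
  list(a = rows_a[match(common, ka)], b = rows_b[match(common, kb)])
}

#' Per-frame RMSD of an ensemble against a reference structure
#'
#' Each frame is superposed onto the reference over the atom selection
#' before the deviation is measured, so rigid-body motion does not
#' contribute.
#'
#' @param ensemble a `structure_ensemble`
#' @param reference a `structure_model`; defaults to the ensemble topology
#' @param selection `"calpha"` (default), `"backbone"`, or atom names
#' @return data frame of class `rmsd_series`: `frame`, `rmsd` (Angstrom);
#'   attributes `reference_tag` and `selection`
#' @export
per_frame_rmsd <- function(ensemble, reference = NULL, selection = "calpha") {
  ref_tag <- if (is.null(reference)) "topology" else "supplied"
  if (is.null(reference)) reference <- ensemble$topology
  sel <- match_selection(ensemble$topology, reference, selection)
  if (length(sel$a) < 3) {
    stop("selection resolves to fewer than 3 matched atoms")
  }
  ref_xyz <- atom_coords(reference)[sel$b, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    kabsch_superpose(frame_coords(ensemble, f)[sel$a, , drop = FALSE],
                     ref_xyz)$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_len(n_frames(ensemble)), rmsd = vals)
  attr(out, "reference_tag") <- ref_tag
  attr(out, "selection") <- selection
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Average conformation over a frame window
#'
#' Frames in the window are superposed (over the C-alpha selection) onto the
#' first window frame and averaged atom-wise.
#'
#' @param ensemble a `structure_ensemble`
#' @param window frame indices; default all frames
#' @return a `structure_model` carrying the mean coordinates
#' @export
average_structure <- function(ensemble, window = NULL) {
  if (is.null(window)) window <- seq_len(n_frames(ensemble))
  if (length(window) == 0) stop("empty frame window")
  aligned <- aligned_window_coords(ensemble, window,
                                   target = frame_coords(ensemble, window[1]))
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  out <- set_coords(ensemble$topology, mean_xyz)
  out$metadata$averaged_frames <- window
  out
}

# Superpose every window frame onto `target` coordinates over C-alpha;
# returns list of full-atom coordinate matrices.
aligned_window_coords <- function(ensemble, window, target) {
  ca <- selection_rows(ensemble$topology, "calpha")
  if (length(ca) < 3) stop("topology has fewer than 3 C-alpha atoms")
  target_ca <- target[ca, , drop = FALSE]
  lapply(window, function(f) {
    xyz <- frame_coords(ensemble, f)
    sp <- kabsch_superpose(xyz[ca, , drop = FALSE], target_ca)
    apply_superposition(xyz, sp)
  })
}

#' Frame closest to the average conformation
#'
#' Returns the index of the window frame with the lowest C-alpha RMSD to the
#' window-average structure (ties broken by the lowest frame index).  This
#' is the "representative frame" used as the single-conformation stand-in
#' for a trajectory segment.
#'
#' @inheritParams average_structure
#' @return integer frame index (into the full ensemble)
#' @export
representative_frame <- function(ensemble, window = NULL) {
  if (is.null(window)) window <- seq_len(n_frames(ensemble))
  if (length(window) == 0) stop("empty frame window")
  avg <- average_structure(ensemble, window)
  ca <- selection_rows(ensemble$topology, "calpha")
  avg_ca <- atom_coords(avg)[ca, , drop = FALSE]
  rmsds <- vapply(window, function(f) {
    kabsch_superpose(frame_coords(ensemble, f)[ca, , drop = FALSE], avg_ca)$rmsd
  }, numeric(1))
  window[which.min(rmsds)]
}

#' Per-residue RMSF over a frame window
#'
#' Root-mean-square fluctuation of each residue's C-alpha position about its
#' mean, after removing rigid-body motion.  Alignment target is the average
#' structure with one re-averaging pass: frames are aligned to the first
#' window frame, averaged, re-aligned to that average and re-averaged; the
#' fluctuation is measured about the final mean positions.
#'
#' @param ensemble a `structure_ensemble`
#' @param window frame indices; defaults to [default_window()] (last 75%)
#' @return data frame of class `flexibility_profile`: `chain`, `resnum`,
#'   `icode`, `resname`, `rmsf` (Angstrom); attributes `temperature` and
#'   `window`
#' @export
per_residue_rmsf <- function(ensemble, window = NULL) {
  if (is.null(window)) window <- default_window(n_frames(ensemble))
  if (length(window) < 2) stop("RMSF needs at least 2 frames in the window")

  pass1 <- aligned_window_coords(ensemble, window,
                                 target = frame_coords(ensemble, window[1]))
  avg1 <- Reduce(`+`, pass1) / length(pass1)
  pass2 <- aligned_window_coords(ensemble, window, target = avg1)
  avg2 <- Reduce(`+`, pass2) / length(pass2)

  ca <- selection_rows(ensemble$topology, "calpha")
  sq <- matrix(0, nrow = length(ca), ncol = 1)
  for (xyz in pass2) {
    sq <- sq + rowSums((xyz[ca, , drop = FALSE] - avg2[ca, , drop = FALSE])^2)
  }
  rmsf <- sqrt(as.vector(sq) / length(pass2))

  res <- ensemble$topology$residues
  ridx <- ensemble$topology$atoms$ridx[ca]
  out <- data.frame(
    chain = res$chain[ridx], resnum = res$resnum[ridx],
    icode = res$icode[ridx], resname = res$resname[ridx],
    rmsf = rmsf, stringsAsFactors = FALSE
  )
  attr(out, "temperature") <- ensemble$temperature
  attr(out, "window") <- range(window)
  class(out) <- c("flexibility_profile", "data.frame")
  out
}

#' Per-residue displacement between two ensembles' average structures
#'
#' Both ensembles (identical topologies required) are averaged; the second
#' average is globally superposed onto the first over all C-alpha atoms, and
#' the per-residue C-alpha distance between the two averages is reported.
#' Used to locate regions whose mean conformation shifts between simulated
#' temperatures.
#'
#' @param ensemble_a,ensemble_b `structure_ensemble` objects sharing one
#'   topology
#' @param window_a,window_b frame windows; default all frames
#' @return data frame: `chain`, `resnum`, `icode`, `resname`, `rmsd`
#'   (Angstrom)
#' @export
per_residue_rmsd <- function(ensemble_a, ensemble_b,
                             window_a = NULL, window_b = NULL) {
  ta <- ensemble_a$topology
  tb <- ensemble_b$topology
  same <- identical(ta$atoms$name, tb$atoms$name) &&
    identical(ta$atoms$resnum, tb$atoms$resnum) &&
    identical(ta$atoms$chain, tb$atoms$chain)
  if (!same) stop("ensemble topologies do not match")

  avg_a <- average_structure(ensemble_a, window_a)
  avg_b <- average_structure(ensemble_b, window_b)
  ca <- selection_rows(ta, "calpha")
  xa <- atom_coords(avg_a)
  xb <- atom_coords(avg_b)
  sp <- kabsch_superpose(xb[ca, , drop = FALSE], xa[ca, , drop = FALSE])
  xb_fit <- apply_superposition(xb, sp)

  d <- sqrt(rowSums((xb_fit[ca, , drop = FALSE] - xa[ca, , drop = FALSE])^2))
  res <- ta$residues
  ridx <- ta$atoms$ridx[ca]
  data.frame(
    chain = res$chain[ridx], resnum = res$resnum[ridx],
    icode = res$icode[ridx], resname = res$resname[ridx],
    rmsd = d, stringsAsFactors = FALSE
  )
}

#' Hydrogen-bond count time series over an ensemble
#'
#' Runs [detect_hbonds()] on every frame and reports the per-frame count and
#' its arithmetic mean.
#'
#' @param ensemble a `structure_ensemble`
#' @param criteria an [hbond_criteria()]
#' @return data frame of class `hbond_series`: `frame`, `count`; attribute
#'   `mean`
#' @export
hbond_series <- function(ensemble, criteria = hbond_criteria()) {
  counts <- vapply(seq_len(n_frames(ensemble)), function(f) {
    nrow(detect_hbonds(frame_structure(ensemble, f), criteria))
  }, integer(1))
  out <- data.frame(frame = seq_len(n_frames(ensemble)), count = counts)
  attr(out, "mean") <- mean(counts)
  class(out) <- c("hbond_series", "data.frame")
  out
}

#' Write / read a flexibility profile as TSV
#'
#' Profiles round-trip through a plain TSV (columns `chain`, `resnum`,
#' `icode`, `resname`, `rmsf`) with the temperature label in a `#` header
#' line, so screening can run without re-reading the ensemble.
#'
#' @param profile a `flexibility_profile`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  temp <- attr(profile, "temperature")
  writeLines(sprintf("# temperature_K=%s",
                     ifelse(is.null(temp) || is.na(temp), "NA", temp)), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @return `read_profile`: a `flexibility_profile`
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  temp <- NA_real_
  if (grepl("^# temperature_K=", header)) {
    val <- sub("^# temperature_K=", "", header)
    temp <- suppressWarnings(as.numeric(val))
  }
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = c(icode = "character"))
  out$icode[is.na(out$icode)] <- ""
  attr(out, "temperature") <- temp
  class(out) <- c("flexibility_profile", "data.frame")
  out
}
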