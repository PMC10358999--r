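#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimize the least-squares
#' deviation of `mobile` onto `reference`.  Reflections are excluded: the
#' returned rotation always has determinant +1.  The transform maps mobile
#' coordinates (as rows) onto the reference frame via
#' `aligned = mobile %*% rotation + translation` (row-vector convention).
#'
#' @param mobile n x 3 coordinate matrix (Angstrom)
#' @param reference n x 3 coordinate matrix, same n
#' @return list of class `superposition` with elements `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length 3, Angstrom) and `rmsd`
#'   (Angstrom, the minimized value)
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    stop("mobile and reference must have identical dimensions")
  }
  if (ncol(mobile) != 3) stop("coordinates must be n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points, got ", n)

  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  m <- sweep(mobile, 2, cm)
  r <- sweep(reference, 2, cr)

  # degenerate (collinear or coincident) point sets have no unique rotation
  for (pts in list(m, r)) {
    sv <- svd(pts, nu = 0, nv = 0)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12)) {
      stop("degenerate (collinear) point set: superposition is not unique")
    }
  }

  h <- crossprod(m, r)          # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  diag_d <- diag(c(1, 1, d))
  rot <- s$u %*% diag_d %*% t(s$v)   # row-vector convention: m %*% rot
  aligned <- m %*% rot
  rmsd <- sqrt(sum((aligned - r)^2) / n)
  translation <- as.vector(cr - cm %*% rot)

  structure(
    list(rotation = rot, translation = translation, rmsd = rmsd),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix
#' @param sp a `superposition` from [kabsch_superpose()]
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, a clockwise rotation of
#' the far bond relative to the near bond is positive.  A planar trans
#' arrangement gives 180 degrees, cis gives 0.  The result lies in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom)
#' @return angle in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  tol <- 1e-10
  if (sqrt(sum(b1^2)) < tol || sqrt(sum(b2^2)) < tol || sqrt(sum(b3^2)) < tol) {
    stop("coincident consecutive points: dihedral undefined")
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < tol || sqrt(sum(n2^2)) < tol) {
    stop("collinear point triple: dihedral undefined")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- cross3(n1, b2u)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi dihedral of a residue
#'
#' The phi torsion C(i-1)-N(i)-CA(i)-C(i).  Glycines with phi below zero are
#' the ones that tolerate substitution by bulkier residues (the
#' rigidification rule used in the candidate screen); glycines with positive
#' phi occupy a left-handed backbone conformation that larger side chains
#' cannot adopt.
#'
#' @param structure a `structure_model`
#' @param resnum author residue number
#' @param chain chain id; defaults to the residue's chain when unambiguous
#' @param icode insertion code
#' @return phi in degrees, in (-180, 180]
#' @export
phi_of_residue <- function(structure, resnum, chain = NULL, icode = "") {
  ridx <- residue_index(structure, resnum, chain, icode)
  res <- structure$residues
  if (ridx == 1 || res$chain[ridx - 1] != res$chain[ridx]) {
    stop("no phi: residue ", residue_key_string(res$chain[ridx], resnum, icode),
         " is the first residue of its chain")
  }
  get_atom <- function(i, name) {
    row <- atom_row(structure, i, name)
    if (is.na(row)) {
      stop("missing backbone atom ", name, " in residue ",
           residue_key_string(res$chain[i], res$resnum[i], res$icode[i]))
    }
    c(structure$atoms$x[row], structure$atoms$y[row], structure$atoms$z[row])
  }
  dihedral_angle(
    get_atom(ridx - 1, "C"),
    get_atom(ridx, "N"),
    get_atom(ridx, "CA"),
    get_atom(ridx, "C")
  )
}

#' Residue-contact rule
#'
#' Two residues are in contact when the Euclidean distance between their
#' representative atoms — the beta carbon, or the alpha carbon for residues
#' without one (glycine) — is strictly below `threshold`.  The packaged
#' default threshold is the literal 3 used by the screening protocol; it is
#' carried in every report because a 3 Angstrom CB-CB contact criterion is
#' unusually tight and deliberately surfaced rather than hidden.
#'
#' @param threshold contact distance threshold (Angstrom); comparison is
#'   strict less-than
#' @return list of class `contact_rule`
#' @export
contact_rule <- function(threshold = 3) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  structure(list(threshold = threshold), class = "contact_rule")
}

# Representative-atom coordinates (CB, else CA) for every residue.
# Returns a list(coords = n_res x 3, ok = logical) — ok FALSE where neither
# CB nor CA exists.
rep_atom_coords <- function(structure) {
  a <- structure$atoms
  nres <- nrow(structure$residues)
  coords <- matrix(NA_real_, nres, 3)
  cb <- a$name == "CB"
  ca <- a$name == "CA"
  cb_rows <- match(seq_len(nres), a$ridx[cb])
  ca_rows <- match(seq_len(nres), a$ridx[ca])
  use_cb <- !is.na(cb_rows)
  rows <- ifelse(use_cb, which(cb)[cb_rows], which(ca)[ca_rows])
  ok <- !is.na(rows)
  coords[ok, ] <- cbind(a$x[rows[ok]], a$y[rows[ok]], a$z[rows[ok]])
  list(coords = coords, ok = ok)
}

#' Contact partners of a residue
#'
#' All other residues whose representative atom (CB; CA for glycine) lies
#' strictly closer than the rule's threshold.  The relation is symmetric and
#' never includes the residue itself.
#'
#' @param structure a `structure_model`
#' @param resnum author residue number
#' @param chain chain id (default: first chain)
#' @param icode insertion code
#' @param rule a [contact_rule()]
#' @return data frame of partners: `chain`, `resnum`, `icode`, `resname`,
#'   `distance` (Angstrom)
#' @export
contact_partners <- function(structure, resnum, chain = NULL, icode = "",
                             rule = contact_rule()) {
  ridx <- residue_index(structure, resnum, chain, icode)
  rep <- rep_atom_coords(structure)
  if (!rep$ok[ridx]) {
    stop("residue ", residue_key_string(structure$residues$chain[ridx],
                                        resnum, icode),
         " has neither CB nor CA atom")
  }
  self <- rep$coords[ridx, ]
  d <- sqrt(rowSums(sweep(rep$coords, 2, self)^2))
  hit <- which(rep$ok & d < rule$threshold & seq_along(d) != ridx)
  res <- structure$residues[hit, c("chain", "resnum", "icode", "resname")]
  res$distance <- d[hit]
  rownames(res) <- NULL
  res
}

#' Per-residue contact counts
#'
#' Number of contact partners of every residue under a [contact_rule()],
#' computed from the all-pairs representative-atom distance matrix.
#' Residues lacking both CB and CA (e.g. incomplete models) get `NA`.
#'
#' @param structure a `structure_model`
#' @param rule a [contact_rule()]
#' @return data frame: `chain`, `resnum`, `icode`, `resname`, `contacts`
#' @export
contact_counts <- function(structure, rule = contact_rule()) {
  rep <- rep_atom_coords(structure)
  n <- nrow(rep$coords)
  counts <- rep(NA_integer_, n)
  ok <- which(rep$ok)
  if (length(ok) > 0) {
    d <- as.matrix(stats::dist(rep$coords[ok, , drop = FALSE]))
    counts[ok] <- as.integer(rowSums(d < rule$threshold) - 1L)  # minus self
  }
  out <- structure$residues[, c("chain", "resnum", "icode", "resname")]
  out$contacts <- counts
  rownames(out) <- NULL
  out
}

#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair is counted as hydrogen bonded when the heavy-atom
#' donor-acceptor distance is at most `max_dist` and the donor-H-acceptor
#' angle is at least `min_angle`.  Defaults follow common trajectory-analysis
#' convention.
#'
#' @param max_dist maximum donor-acceptor distance (Angstrom)
#' @param min_angle minimum D-H-A angle (degrees)
#' @return list of class `hbond_criteria`
#' @export
hbond_criteria <- function(max_dist = 3.5, min_angle = 150) {
  if (max_dist <= 0) stop("max_dist must be > 0")
  if (min_angle <= 0 || min_angle > 180) stop("min_angle must be in (0, 180]")
  structure(list(max_dist = max_dist, min_angle = min_angle),
            class = "hbond_criteria")
}

# side-chain O/N acceptor atom names (heavy atoms only)
HB_ACCEPTOR_NAMES <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2",
                       "OG", "OG1", "OH", "ND1", "NE2")

#' Detect intra-protein hydrogen bonds in one conformation
#'
#' Donors are backbone amide nitrogens (proline excluded); the amide
#' hydrogen is taken from the structure when present (atom `H`/`HN`),
#' otherwise constructed in the peptide plane along the bisector of the
#' N-C(i-1) and N-CA directions at an N-H length of 1.01 Angstrom.
#' Acceptors are backbone carbonyl oxygens and side-chain O/N heavy atoms.
#' Pairs within the same residue or between sequence neighbours are not
#' counted, and each donor-acceptor residue pair is reported once.
#'
#' @param structure a `structure_model` (one conformation)
#' @param criteria an [hbond_criteria()]
#' @return data frame: donor `d_chain`, `d_resnum`, acceptor `a_chain`,
#'   `a_resnum`, `distance` (Angstrom), `angle` (degrees)
#' @export
detect_hbonds <- function(structure, criteria = hbond_criteria()) {
  a <- structure$atoms
  res <- structure$residues
  nres <- nrow(res)
  coords <- atom_coords(structure)

  get <- function(ridx, name) {
    row <- atom_row(structure, ridx, name)
    if (is.na(row)) NULL else coords[row, ]
  }

  # donor table: N position + (explicit or constructed) H position
  donors <- list()
  for (i in seq_len(nres)) {
    if (res$resname[i] == "PRO") next
    n_pos <- get(i, "N")
    if (is.null(n_pos)) next
    h_pos <- get(i, "H")
    if (is.null(h_pos)) h_pos <- get(i, "HN")
    if (is.null(h_pos)) {
      if (i == 1 || res$chain[i - 1] != res$chain[i]) next
      c_prev <- get(i - 1, "C")
      ca <- get(i, "CA")
      if (is.null(c_prev) || is.null(ca)) next
      u1 <- (n_pos - c_prev); u1 <- u1 / sqrt(sum(u1^2))
      u2 <- (n_pos - ca); u2 <- u2 / sqrt(sum(u2^2))
      hdir <- u1 + u2
      nh <- sqrt(sum(hdir^2))
      if (nh < 1e-8) next
      h_pos <- n_pos + 1.01 * hdir / nh
    }
    donors[[length(donors) + 1]] <- list(ridx = i, n = n_pos, h = h_pos)
  }

  acc_rows <- which(a$name %in% HB_ACCEPTOR_NAMES)
  out <- data.frame(d_chain = character(), d_resnum = integer(),
                    a_chain = character(), a_resnum = integer(),
                    distance = numeric(), angle = numeric(),
                    stringsAsFactors = FALSE)
  if (length(donors) == 0 || length(acc_rows) == 0) return(out)

  acc_coords <- coords[acc_rows, , drop = FALSE]
  acc_ridx <- a$ridx[acc_rows]

  hits <- list()
  for (d in donors) {
    dvec <- sweep(acc_coords, 2, d$n)
    dist <- sqrt(rowSums(dvec^2))
    sep <- abs(res$resnum[acc_ridx] - res$resnum[d$ridx])
    same_chain <- res$chain[acc_ridx] == res$chain[d$ridx]
    cand <- which(dist <= criteria$max_dist & (!same_chain | sep >= 2))
    for (j in cand) {
      # D-H-A angle at the hydrogen
      v1 <- d$n - d$h
      v2 <- acc_coords[j, ] - d$h
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= criteria$min_angle) {
        hits[[length(hits) + 1]] <- data.frame(
          d_chain = res$chain[d$ridx], d_resnum = res$resnum[d$ridx],
          a_chain = res$chain[acc_ridx[j]], a_resnum = res$resnum[acc_ridx[j]],
          distance = dist[j], angle = ang, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0) return(out)
  out <- do.call(rbind, hits)
  # one count per donor-acceptor residue pair
  key <- paste(out$d_chain, out$d_resnum, out$a_chain, out$a_resnum)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
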