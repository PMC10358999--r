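# Run code with a locally seeded RNG, restoring the caller's RNG state, so
# generators are pure functions of their arguments including the seed.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Place atom D given A, B, C by internal coordinates: |C-D| = bond,
# angle B-C-D, torsion A-B-C-D (degrees).  Standard chain-extension step.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal backbone geometry (Angstrom / degrees)
GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.4,
  t_omega = 180, t_n_ca_cb = -122.6   # torsion C(i)-N(i)-CA(i)-CB
)

#' Build an ideal poly-alanine helix
#'
#' Constructs a poly-alanine backbone (N, CA, C, O, CB per residue) with the
#' requested phi/psi dihedrals by internal-coordinate chain extension using
#' fixed ideal bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329
#' Angstrom; omega fixed at 180).  The default dihedrals give a canonical
#' right-handed alpha helix; positive phi builds the left-handed mirror
#' conformation the glycine rule is concerned with.
#'
#' @param n_residues number of residues (at least 4)
#' @param phi,psi backbone dihedrals, degrees
#' @param chain chain id
#' @return a `structure_model`
#' @export
make_helix <- function(n_residues, phi = -57, psi = -47, chain = "A") {
  if (n_residues < 4) stop("need at least 4 residues, got ", n_residues)
  g <- GEOM
  n_pos <- ca_pos <- c_pos <- vector("list", n_residues)
  # residue 1: N at origin, CA on x, C in the xy-plane
  n_pos[[1]] <- c(0, 0, 0)
  ca_pos[[1]] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  c_pos[[1]] <- ca_pos[[1]] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues - 1)) {
    n_pos[[i + 1]] <- place_atom(n_pos[[i]], ca_pos[[i]], c_pos[[i]],
                                 g$b_c_n, g$a_ca_c_n, psi)
    ca_pos[[i + 1]] <- place_atom(ca_pos[[i]], c_pos[[i]], n_pos[[i + 1]],
                                  g$b_n_ca, g$a_c_n_ca, g$t_omega)
    c_pos[[i + 1]] <- place_atom(c_pos[[i]], n_pos[[i + 1]], ca_pos[[i + 1]],
                                 g$b_ca_c, g$a_n_ca_c, phi)
  }
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    o_pos <- place_atom(n_pos[[i]], ca_pos[[i]], c_pos[[i]],
                        g$b_c_o, g$a_ca_c_o, psi - 180)
    cb_pos <- place_atom(c_pos[[i]], n_pos[[i]], ca_pos[[i]],
                         g$b_ca_cb, g$a_n_ca_cb, g$t_n_ca_cb)
    for (at in list(list("N", n_pos[[i]], "N"), list("CA", ca_pos[[i]], "C"),
                    list("C", c_pos[[i]], "C"), list("O", o_pos, "O"),
                    list("CB", cb_pos, "C"))) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = at[[1]], resname = "ALA", chain = chain,
        resnum = i, icode = "", x = at[[2]][1], y = at[[2]][2],
        z = at[[2]][3], occupancy = 1, bfactor = 0, element = at[[3]],
        stringsAsFactors = FALSE
      )
    }
  }
  structure_model(do.call(rbind, rows),
                  metadata = list(generator = "make_helix",
                                  phi = phi, psi = psi))
}

#' Generate a noise-perturbed synthetic ensemble
#'
#' Frames are the base structure plus iid Gaussian noise on every atom
#' coordinate, with a per-residue standard deviation.  The noise is
#' uncorrelated across atoms and frames — enough to give each residue a
#' known expected RMSF (`sigma * sqrt(3)` in the many-frame limit), with no
#' attempt to mimic real trajectory covariance.  Deterministic given
#' `seed`; the caller's RNG state is untouched.
#'
#' @param structure base `structure_model`
#' @param n_frames number of frames (>= 1)
#' @param sigma per-coordinate noise SD (Angstrom): a scalar, or a vector
#'   with one value per residue, or a named vector keyed by residue number
#' @param seed integer RNG seed
#' @param temperature temperature label (K) carried on the ensemble
#' @return a `structure_ensemble`
#' @export
make_ensemble <- function(structure, n_frames, sigma = 0.2, seed = 1,
                          temperature = NA_real_) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  nres <- n_residues(structure)
  if (!is.null(names(sigma))) {
    res_sigma <- rep(0, nres)
    idx <- match(as.integer(names(sigma)), structure$residues$resnum)
    if (anyNA(idx)) stop("sigma names include unknown residue numbers")
    res_sigma[idx] <- sigma
  } else if (length(sigma) == 1) {
    res_sigma <- rep(sigma, nres)
  } else {
    if (length(sigma) != nres) stop("sigma must be scalar or one per residue")
    res_sigma <- sigma
  }
  if (any(res_sigma < 0)) stop("sigma must be >= 0")

  base <- as.vector(t(atom_coords(structure)))      # x1 y1 z1 x2 ...
  atom_sigma <- res_sigma[structure$atoms$ridx]
  sd_vec <- rep(atom_sigma, each = 3)
  xyz <- with_local_seed(seed, {
    noise <- matrix(stats::rnorm(n_frames * length(base), sd = sd_vec),
                    nrow = n_frames, byrow = TRUE)
    sweep(noise, 2, base, `+`)
  })
  new_ensemble(structure, xyz,
               frame_times = 50 * seq_len(n_frames),
               temperature = temperature)
}

#' Generate a synthetic mutation-energy table with planted signals
#'
#' Background substitutions draw uniformly from the neutral band
#' \[-0.4, +0.4\] kcal/mol, so under default [stability_bands()] the
#' background produces no screening hits; planted entries are inserted
#' verbatim and are the only recoverable signal.  Deterministic given
#' `seed`.
#'
#' @param seed integer RNG seed
#' @param sites integer residue numbers covered by the table
#' @param kind `"saturation"` (19 non-self substitutions plus a zero
#'   self-row per site) or `"alanine_scan"` (one ALA row per site)
#' @param from_aa wild-type code(s), recycled over `sites` (default GLY)
#' @param planted `NULL` or data frame `site`, `to_aa`, `energy` of entries
#'   to insert verbatim; duplicated planted entries are an error
#' @param engine engine tag
#' @return a `mutation_energy_table`
#' @export
make_energy_table <- function(seed, sites, kind = c("saturation",
                                                    "alanine_scan"),
                              from_aa = "GLY", planted = NULL,
                              engine = "synthetic") {
  kind <- match.arg(kind)
  from_aa <- rep(aa_canon(from_aa), length.out = length(sites))
  rows <- list()
  for (i in seq_along(sites)) {
    targets <- if (kind == "alanine_scan") "ALA" else unname(AA3)
    for (to in targets) {
      rows[[length(rows) + 1]] <- data.frame(
        site = sites[i], from_aa = from_aa[i], to_aa = to,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  df$energy <- with_local_seed(seed, stats::runif(nrow(df), -0.4, 0.4))
  df$energy[df$from_aa == df$to_aa] <- 0

  if (!is.null(planted) && nrow(planted) > 0) {
    planted$to_aa <- aa_canon(planted$to_aa)
    if (anyDuplicated(planted[, c("site", "to_aa")])) {
      stop("planted site collision: duplicate (site, to_aa) entry")
    }
    for (i in seq_len(nrow(planted))) {
      hit <- which(df$site == planted$site[i] & df$to_aa == planted$to_aa[i])
      if (length(hit) == 0) {
        stop("planted entry targets a site absent from the table: ",
             planted$site[i])
      }
      df$energy[hit] <- planted$energy[i]
    }
  }
  mutation_energy_table(df$site, df$from_aa, df$to_aa, df$energy,
                        kind = kind, engine = engine)
}
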