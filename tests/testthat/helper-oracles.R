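# Independent oracles used to cross-check the package's geometry, kept
# deliberately on different algorithms than the implementation.

xcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Horn's quaternion method for the optimal-superposition RMSD (eigenvalue
# route, no SVD): independent of the Kabsch implementation under test.
quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  m <- sweep(mobile, 2, colMeans(mobile))
  r <- sweep(reference, 2, colMeans(reference))
  s <- crossprod(m, r)
  nm <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(nm, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(m^2) + sum(r^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# Dihedral by projection onto the plane perpendicular to the central bond
# (signed via the triple product) — a different route than the
# cross-product-normal formula in the package.
projection_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2u <- b2 / sqrt(sum(b2^2))
  u <- (p1 - p2) - sum((p1 - p2) * b2u) * b2u
  v <- (p4 - p3) - sum((p4 - p3) * b2u) * b2u
  atan2(sum(xcross(u, v) * b2u), sum(u * v)) * 180 / pi
}

# Build a minimal structure_model from a list of residues; each element is
# list(resnum=, resname=, atoms=named list of length-3 coordinate vectors).
toy_structure <- function(residues, chain = "A") {
  rows <- list()
  serial <- 0L
  for (r in residues) {
    for (nm in names(r$atoms)) {
      serial <- serial + 1L
      p <- r$atoms[[nm]]
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, resname = r$resname %||% "ALA",
        chain = chain, resnum = r$resnum, icode = "",
        x = p[1], y = p[2], z = p[3],
        occupancy = 1, bfactor = 0, element = substr(nm, 1, 1),
        stringsAsFactors = FALSE
      )
    }
  }
  structure_model(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random proper rotation matrix (QR route)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply one rigid transform to every frame of an ensemble
transform_ensemble <- function(ens, rot, shift) {
  xyz <- t(apply(ens$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% rot, 2, shift, `+`)))
  }))
  ens$xyz <- xyz
  ens
}

extdata <- function(name) {
  system.file("extdata", name, package = "thermoscreen", mustWork = TRUE)
}
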