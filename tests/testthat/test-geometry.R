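test_that("superposition handles identity, pure rotation and random clouds", {
  set.seed(101)
  ref <- matrix(rnorm(18), 6, 3)

  sp <- kabsch_superpose(ref, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  # mobile = reference rotated 90 degrees about z: recovered rotation is
  # the inverse and the residual is zero
  th <- pi / 2
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  mob <- ref %*% rz
  sp <- kabsch_superpose(mob, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, solve(rz), tolerance = 1e-8)
  expect_equal(apply_superposition(mob, sp), ref, tolerance = 1e-8)

  # random clouds match the quaternion-method oracle
  for (i in 1:25) {
    a <- matrix(rnorm(18), 6, 3)
    b <- matrix(rnorm(18), 6, 3)
    sp <- kabsch_superpose(a, b)
    expect_equal(sp$rmsd, quaternion_rmsd(a, b), tolerance = 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("superposition rmsd is invariant under a common rigid transform", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  base <- kabsch_superpose(a, b)$rmsd
  for (i in 1:10) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 5)
    a2 <- sweep(a %*% rot, 2, shift, `+`)
    b2 <- sweep(b %*% rot, 2, shift, `+`)
    expect_equal(kabsch_superpose(a2, b2)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("degenerate superposition inputs error", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, matrix(rnorm(15), 5, 3)), "collinear")
})

test_that("dihedral follows the IUPAC convention and matches two oracles", {
  # planar cis -> 0; planar trans -> 180
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               0, tolerance = 1e-10)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, projection_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    expect_equal(mine, as.numeric(bio3d::torsion.xyz(as.vector(t(p)))),
                 tolerance = 1e-6)
    # the signed torsion is symmetric under full reversal of the path
    rev <- dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(rev, mine, tolerance = 1e-9)
    expect_equal(rev, as.numeric(bio3d::torsion.xyz(as.vector(t(p[4:1, ])))),
                 tolerance = 1e-6)
  }

  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincident")
  expect_error(dihedral_angle(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
})

test_that("phi is the C(i-1)-N-CA-C torsion with chain-start handling", {
  h <- make_helix(10, phi = -57, psi = -47)
  expect_error(phi_of_residue(h, 1), "no phi")
  for (i in 2:9) {
    expect_equal(phi_of_residue(h, i), -57, tolerance = 1e-3)
  }
  # missing backbone atom is named
  broken <- h$atoms[!(h$atoms$name == "N" & h$atoms$resnum == 5), ]
  broken <- structure_model(broken[, setdiff(names(broken), "ridx")])
  expect_error(phi_of_residue(broken, 5), "missing backbone atom N")
})

test_that("contact rule uses representative atoms with strict less-than", {
  two <- function(d) {
    toy_structure(list(
      list(resnum = 1, atoms = list(CA = c(0, 0, 0), CB = c(0, 0, 1))),
      list(resnum = 5, atoms = list(CA = c(5, 0, 0), CB = c(0, 0, 1 + d)))
    ))
  }
  expect_equal(nrow(contact_partners(two(2.5), 1)), 1)
  expect_equal(nrow(contact_partners(two(2.5), 5)), 1)
  # boundary: exactly at the threshold is NOT a contact
  expect_equal(nrow(contact_partners(two(3.0), 1)), 0)

  # glycine falls back to CA
  s <- toy_structure(list(
    list(resnum = 1, resname = "GLY", atoms = list(CA = c(0, 0, 0))),
    list(resnum = 3, atoms = list(CA = c(9, 9, 9), CB = c(0, 2, 0)))
  ))
  p <- contact_partners(s, 1)
  expect_equal(p$resnum, 3)
  expect_equal(p$distance, 2)

  s2 <- toy_structure(list(
    list(resnum = 1, atoms = list(N = c(0, 0, 0))),
    list(resnum = 2, atoms = list(CA = c(1, 0, 0)))
  ))
  expect_error(contact_partners(s2, 1), "neither CB nor CA")
})

test_that("contact relation matches brute force and is symmetric/irreflexive", {
  set.seed(55)
  pts <- matrix(rnorm(30, sd = 2), 10, 3)
  s <- toy_structure(lapply(1:10, function(i) {
    list(resnum = i, atoms = list(CA = pts[i, ] + c(5, 5, 5), CB = pts[i, ]))
  }))
  rule <- contact_rule(3)
  d <- as.matrix(dist(pts))
  for (i in 1:10) {
    partners <- contact_partners(s, i, rule = rule)$resnum
    brute <- unname(which(d[i, ] < 3 & seq_len(10) != i))
    expect_equal(sort(partners), sort(brute))
    expect_false(i %in% partners)
    for (j in partners) {
      expect_true(i %in% contact_partners(s, j, rule = rule)$resnum)
    }
  }
  counts <- contact_counts(s, rule)
  expect_equal(counts$contacts, as.integer(rowSums(d < 3) - 1))
})

test_that("hydrogen bonds need both distance and angle", {
  ideal <- function(no_dist) {
    # N-H...O with D-H-A angle 175 degrees at the requested N...O distance
    n <- c(0, 0, 0)
    h <- c(1.01, 0, 0)
    u <- c(cos(5 * pi / 180), sin(5 * pi / 180), 0)
    # solve |n - (h + t u)| = no_dist for t > 0
    f <- function(t) sqrt(sum((h + t * u)^2)) - no_dist
    t <- uniroot(f, c(0.1, 10))$root
    o <- h + t * u
    toy_structure(list(
      list(resnum = 1, atoms = list(C = o + c(0, 1.23, 0), O = o)),
      list(resnum = 5, atoms = list(N = n, CA = c(-0.7, -1.2, 0), H = h))
    ))
  }
  hb <- detect_hbonds(ideal(2.9))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_resnum, 5)
  expect_equal(hb$a_resnum, 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  # stretched beyond the cutoff
  expect_equal(nrow(detect_hbonds(ideal(4.5))), 0)
  # angle criterion: bend the hydrogen far off the N-O axis
  s <- toy_structure(list(
    list(resnum = 1, atoms = list(O = c(2.9, 0, 0))),
    list(resnum = 5, atoms = list(N = c(0, 0, 0), H = c(0, 1.01, 0)))
  ))
  expect_equal(nrow(detect_hbonds(s)), 0)
})

test_that("an ideal capped helix shows the i -> i-4 backbone pattern", {
  n <- 12
  h <- make_helix(n)
  hb <- detect_hbonds(h)
  expect_equal(nrow(hb), n - 4)
  expect_equal(sort(hb$d_resnum), 5:n)
  expect_equal(hb$d_resnum - hb$a_resnum, rep(4, n - 4))

  # exhaustive donor/acceptor pair check with the same criteria
  crit <- hbond_criteria()
  brute <- 0
  for (i in 2:n) {
    np <- residue_atom(h, i, "N")
    cprev <- residue_atom(h, i - 1, "C")
    ca <- residue_atom(h, i, "CA")
    u1 <- (np - cprev) / sqrt(sum((np - cprev)^2))
    u2 <- (np - ca) / sqrt(sum((np - ca)^2))
    hp <- np + 1.01 * (u1 + u2) / sqrt(sum((u1 + u2)^2))
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      op <- residue_atom(h, j, "O")
      dd <- sqrt(sum((np - op)^2))
      v1 <- np - hp
      v2 <- op - hp
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (dd <= crit$max_dist && ang >= crit$min_angle) brute <- brute + 1
    }
  }
  expect_equal(nrow(hb), brute)
})

test_that("hydrogen-bond count is invariant under a global rigid transform", {
  set.seed(77)
  h <- make_helix(10)
  base <- nrow(detect_hbonds(h))
  for (i in 1:5) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 10)
    moved <- thermoscreen:::set_coords(
      h, sweep(atom_coords(h) %*% rot, 2, shift, `+`)
    )
    expect_equal(nrow(detect_hbonds(moved)), base)
  }
})
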