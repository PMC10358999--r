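test_that("CSV dialect parses with kind inference and strict validation", {
  ala <- parse_energy_table(extdata("tyr_ala_scan.csv"))
  expect_s3_class(ala, "mutation_energy_table")
  expect_equal(nrow(ala), 12)
  expect_equal(attr(ala, "kind"), "alanine_scan")
  expect_equal(attr(ala, "engine"), "ds-cme")

  sat <- parse_energy_table(extdata("tyr_saturation.csv"))
  expect_equal(nrow(sat), 38)
  expect_equal(attr(sat, "kind"), "saturation")
  expect_equal(sort(unique(sat$site)), c(124, 137))
  # self-rows retained with zero energy
  self <- sat[sat$to_aa == "GLY", ]
  expect_equal(self$energy, c(0, 0))

  dbl <- parse_energy_table(extdata("tyr_double_mutants.csv"))
  expect_equal(nrow(dbl), 15)
  expect_equal(attr(dbl, "kind"), "combinatorial")
  expect_equal(dbl$label[1], "G124W/G137W")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,from_aa,to_aa,energy", "124,G,X,-1.0"), bad)
  expect_error(parse_energy_table(bad), "unknown amino-acid code: X")

  nonnum <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,from_aa,to_aa,energy", "124,G,W,abc"), nonnum)
  expect_error(parse_energy_table(nonnum), "non-numeric")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,from_aa,to_aa,energy", "124,G,W,-1.0", "124,GLY,TRP,-2.0"),
             dup)
  expect_error(parse_energy_table(dup), "duplicate mutation entry: G124W")
})

test_that("FoldX PositionScan dialect parses into a tagged table", {
  fx <- parse_energy_table(extdata("tyr_foldx_singles.txt"),
                           dialect = "foldx_positionscan")
  expect_equal(attr(fx, "engine"), "foldx")
  expect_equal(fx$site, c(124, 137))
  expect_equal(fx$from_aa, c("GLY", "GLY"))
  expect_equal(fx$to_aa, c("TRP", "TRP"))
  expect_equal(fx$energy, c(-0.996959, -0.984701))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("not a positionscan line", bad)
  expect_error(parse_energy_table(bad, dialect = "foldx_positionscan"),
               "PositionScan")
})

test_that("stability classification partitions the energy line", {
  bands <- stability_bands()
  expect_equal(classify_stability(-0.84, bands), "stabilizing")
  expect_equal(classify_stability(0, bands), "neutral")
  expect_equal(classify_stability(5.28, bands), "destabilizing")
  # boundaries are inclusive to neutral
  expect_equal(classify_stability(c(-0.5, 0.5), bands),
               c("neutral", "neutral"))

  set.seed(3)
  e <- c(runif(200, -5, 5), -0.5, 0.5, -1.5)
  labels <- classify_stability(e, bands)
  expect_true(all(labels %in% c("stabilizing", "neutral", "destabilizing")))
  expect_equal(length(labels), length(e))

  expect_error(stability_bands(neutral_low = 0.5, neutral_high = -0.5),
               "below neutral_high")
  expect_error(stability_bands(candidate_cutoff = 0), "candidate_cutoff")
})

test_that("alanine-scan screen matches the published worked example", {
  ala <- parse_energy_table(extdata("tyr_ala_scan.csv"))
  all_hits <- alanine_scan_filter(ala)
  expect_equal(length(all_hits), 12)
  after <- alanine_scan_filter(ala, exclusions = c(38, 191, 195, 216, 217))
  expect_equal(after, c(20, 102, 124, 135, 137, 205, 240))

  empty <- mutation_energy_table(integer(), character(), character(),
                                 numeric(), kind = "alanine_scan")
  expect_equal(alanine_scan_filter(empty), integer(0))
  sat <- parse_energy_table(extdata("tyr_saturation.csv"))
  expect_error(alanine_scan_filter(sat), "alanine_scan")
})

test_that("screen output shrinks monotonically as the cutoff tightens", {
  ala <- parse_energy_table(extdata("tyr_ala_scan.csv"))
  prev <- alanine_scan_filter(
    ala, stability_bands(neutral_low = -0.4, candidate_cutoff = -1.5)
  )
  for (cut in c(-0.6, -0.9, -1.5, -2.2, -3)) {
    cur <- alanine_scan_filter(
      ala, stability_bands(neutral_low = cut, candidate_cutoff = cut - 1)
    )
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("saturation column minima, ties and destabilizing counts", {
  sat <- parse_energy_table(extdata("tyr_saturation.csv"))
  b124 <- saturation_best(sat, 124)
  expect_equal(b124$to_aa, "TRP")
  expect_equal(b124$energy, -3.82)
  b137 <- saturation_best(sat, 137)
  expect_equal(b137$to_aa, "TRP")
  expect_equal(b137$energy, -3.58)

  expect_equal(count_destabilizing(sat, 124), 1)  # the proline row
  expect_equal(count_destabilizing(sat, 137), 0)  # self-row excluded

  expect_error(saturation_best(sat, 999), "not present")

  tie <- mutation_energy_table(
    site = c(10, 10, 10), from_aa = "GLY",
    to_aa = c("TRP", "CYS", "SER"), energy = c(-1.0, -1.0, 0.2)
  )
  expect_equal(saturation_best(tie, 10)$to_aa, "CYS")

  allneg <- mutation_energy_table(
    site = 7, from_aa = "GLY", to_aa = c("ALA", "SER", "TRP"),
    energy = c(-0.1, -0.2, -0.3)
  )
  expect_equal(count_destabilizing(allneg, 7), 0)

  # exhaustive-scan oracle over synthetic tables
  for (seed in 1:5) {
    tab <- make_energy_table(seed, sites = c(3, 8),
                             planted = data.frame(site = 8, to_aa = "TRP",
                                                  energy = -2.5))
    for (s in c(3, 8)) {
      rows <- tab[tab$site == s & tab$from_aa != tab$to_aa, ]
      rows <- rows[order(rows$energy, rows$to_aa), ]
      got <- saturation_best(tab, s)
      expect_equal(got$to_aa, rows$to_aa[1])
      expect_equal(got$energy, rows$energy[1])
    }
  }
})

test_that("candidate substitutions respect the saturation cutoff", {
  sat <- parse_energy_table(extdata("tyr_saturation.csv"))
  cands <- candidate_sites(sat)
  expect_equal(sum(cands$site == 124), 15)
  expect_true(all(cands$energy < -1.5))

  none <- candidate_sites(sat, stability_bands(candidate_cutoff = -10))
  expect_equal(nrow(none), 0)

  loose <- candidate_sites(sat, stability_bands(neutral_low = -0.001,
                                                neutral_high = 0.001,
                                                candidate_cutoff = -0.001))
  # every negative non-self substitution of site 137 qualifies near cutoff 0
  expect_equal(sum(loose$site == 137), 18)

  ala <- parse_energy_table(extdata("tyr_ala_scan.csv"))
  expect_error(candidate_sites(ala), "saturation")
})

test_that("mutant ranking is an order-independent ascending permutation", {
  dbl <- parse_energy_table(extdata("tyr_double_mutants.csv"))
  rk <- rank_mutants(dbl)
  expect_equal(rk$label[1], "G124W/G137W")
  expect_equal(rk$energy[1], -7.42)
  expect_equal(attr(rk, "selected"), "G124W/G137W")
  expect_true(all(diff(rk$energy) >= 0))
  expect_setequal(rk$label, dbl$label)

  set.seed(8)
  shuffled <- dbl[sample(nrow(dbl)), ]
  attr(shuffled, "kind") <- "combinatorial"
  expect_equal(rank_mutants(shuffled)$label, rk$label)

  single <- combinatorial_energy_table("G124W", -1)
  expect_equal(rank_mutants(single)$label, "G124W")
  expect_error(rank_mutants(dbl[0, ]), "empty")
})

test_that("additive ddG sums distinct-site singles", {
  fx <- parse_energy_table(extdata("tyr_foldx_singles.txt"),
                           dialect = "foldx_positionscan")
  expect_equal(additive_ddg(fx), -1.98166, tolerance = 1e-9)
  expect_equal(additive_ddg(fx[1, ]), -0.996959)
  expect_equal(additive_ddg(data.frame(site = c(1, 2), energy = c(2, -2))), 0)
  expect_error(additive_ddg(data.frame(site = c(5, 5), energy = c(-1, -2))),
               "duplicated site 5")
  expect_error(additive_ddg(fx[0, ]), "at least one")
})

test_that("additive combinatorial synthesis mirrors the direct table", {
  sat <- parse_energy_table(extdata("tyr_saturation.csv"))
  sets <- list(data.frame(site = c(124, 137), to_aa = c("TRP", "TRP")))
  add <- additive_table(sat, sets)
  expect_equal(add$label, "G124W/G137W")
  expect_equal(add$energy, -3.82 - 3.58)
  expect_equal(attr(add, "engine"), "ds-cme+additive")
  expect_error(
    additive_table(sat, list(data.frame(site = 1, to_aa = "TRP"))),
    "absent"
  )
})

test_that("amino-acid codes normalize and labels round-trip", {
  t1 <- mutation_energy_table(124, "G", "W", -3.82)
  expect_equal(t1$from_aa, "GLY")
  expect_equal(t1$label, "G124W")
  parsed <- parse_mutation_label("G124W/G137W")
  expect_equal(parsed$site, c(124, 137))
  expect_equal(parsed$to_aa, c("TRP", "TRP"))
  expect_error(parse_mutation_label("G124"), "cannot parse")
  expect_error(mutation_energy_table(1, "XYZ", "ALA", 0), "unknown amino-acid")
})
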