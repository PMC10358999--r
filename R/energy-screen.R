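AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA1 <- stats::setNames(names(AA3), AA3)

# Normalize a 1- or 3-letter amino-acid code to canonical 3-letter; error on
# anything else.
aa_canon <- function(code) {
  code <- toupper(trimws(code))
  out <- ifelse(code %in% AA3, code,
                ifelse(code %in% names(AA3), AA3[code], NA))
  if (anyNA(out)) {
    stop("unknown amino-acid code: ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Mutation-energy table
#'
#' Holds externally computed per-mutation stability energies
#' (kcal/mol; negative = stabilizing): alanine-scan rows, in-silico
#' saturation-mutagenesis columns, or combinatorial multi-site mutants.
#' Engines are never mixed silently — each table carries an `engine` tag
#' because different calculators use different energy scales.
#' Self-substitutions (`from == to`, conventionally printed with energy 0)
#' are retained but excluded from minima and destabilizing counts.
#'
#' @param site integer residue numbers (for combinatorial rows use
#'   [combinatorial_energy_table()])
#' @param from_aa,to_aa amino-acid codes (1- or 3-letter, normalized to
#'   3-letter)
#' @param energy energies in kcal/mol
#' @param kind `"alanine_scan"`, `"saturation"` or `"combinatorial"`
#' @param engine free-text engine tag (e.g. `"ds-cme"`, `"foldx"`)
#' @return data frame of class `mutation_energy_table` with columns `site`,
#'   `from_aa`, `to_aa`, `energy`, `label`; attributes `kind`, `engine`
#' @export
mutation_energy_table <- function(site, from_aa, to_aa, energy,
                                  kind = c("saturation", "alanine_scan",
                                           "combinatorial"),
                                  engine = "unknown") {
  kind <- match.arg(kind)
  from_aa <- aa_canon(from_aa)
  to_aa <- aa_canon(to_aa)
  if (any(!is.finite(energy))) stop("non-numeric or non-finite energy value")
  out <- data.frame(site = as.integer(site), from_aa = from_aa, to_aa = to_aa,
                    energy = as.numeric(energy), stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("site", "from_aa", "to_aa")])
  if (any(dup)) {
    stop("duplicate mutation entry: ",
         mutation_label(out$site[dup][1], out$from_aa[dup][1],
                        out$to_aa[dup][1]))
  }
  out$label <- mutation_label(out$site, out$from_aa, out$to_aa)
  attr(out, "kind") <- kind
  attr(out, "engine") <- engine
  class(out) <- c("mutation_energy_table", "data.frame")
  out
}

#' @rdname mutation_energy_table
#' @param label mutation labels like `"G124W/G137W"` (slash-joined single
#'   mutations, 1-letter codes)
#' @export
combinatorial_energy_table <- function(label, energy, engine = "unknown") {
  if (any(!is.finite(energy))) stop("non-numeric or non-finite energy value")
  if (anyDuplicated(label)) {
    stop("duplicate mutation entry: ", label[duplicated(label)][1])
  }
  # validate labels parse
  lapply(label, parse_mutation_label)
  out <- data.frame(site = NA_integer_, from_aa = NA_character_,
                    to_aa = NA_character_, energy = as.numeric(energy),
                    label = as.character(label), stringsAsFactors = FALSE)
  attr(out, "kind") <- "combinatorial"
  attr(out, "engine") <- engine
  class(out) <- c("mutation_energy_table", "data.frame")
  out
}

#' Mutation labels
#'
#' Single mutations print as `"G124W"` (1-letter from, site, 1-letter to);
#' multi-site mutants join single labels with `/`, e.g. `"G124W/G137W"`.
#'
#' @param site residue number(s)
#' @param from_aa,to_aa amino-acid codes
#' @return character label(s)
#' @export
mutation_label <- function(site, from_aa, to_aa) {
  paste0(AA1[aa_canon(from_aa)], site, AA1[aa_canon(to_aa)])
}

#' @rdname mutation_label
#' @param label a slash-joined label to parse
#' @return `parse_mutation_label`: data frame `site`, `from_aa`, `to_aa`
#' @export
parse_mutation_label <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", parts))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("cannot parse mutation label: ", label)
  data.frame(
    site = as.integer(vapply(m, `[`, character(1), 3)),
    from_aa = aa_canon(vapply(m, `[`, character(1), 2)),
    to_aa = aa_canon(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

table_kind <- function(table) attr(table, "kind")

#' Parse a mutation-energy file
#'
#' Two dialects:
#' * `"csv"` — comma- or tab-delimited with either columns
#'   `site, from_aa, to_aa, energy[, engine]` (kind inferred: all-alanine
#'   targets with one row per site parse as an alanine scan, otherwise
#'   saturation), or columns `mutations, energy[, engine]` for combinatorial
#'   tables with slash-joined labels.
#' * `"foldx_positionscan"` — PositionScan-style lines
#'   `<fromAA><chain><site><toAA> <energy>`, e.g. `GA124W -0.996959`
#'   (engine tag `foldx`, kind saturation).
#'
#' @param path input file
#' @param dialect `"csv"` or `"foldx_positionscan"`
#' @param engine override for the engine tag
#' @return a `mutation_energy_table`
#' @export
parse_energy_table <- function(path, dialect = c("csv", "foldx_positionscan"),
                               engine = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "foldx_positionscan") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    m <- regmatches(lines,
                    regexec("^([A-Za-z]{1,3})([A-Za-z])([0-9]+)([A-Za-z])\\s+(-?[0-9.eE+]+)$",
                            lines))
    bad <- vapply(m, length, integer(1)) != 6
    if (any(bad)) stop("cannot parse PositionScan line: ", lines[bad][1])
    from <- vapply(m, `[`, character(1), 2)
    site <- as.integer(vapply(m, `[`, character(1), 4))
    to <- vapply(m, `[`, character(1), 5)
    energy <- as.numeric(vapply(m, `[`, character(1), 6))
    if (anyNA(energy)) stop("non-numeric energy in ", path)
    return(mutation_energy_table(site, from, to, energy, kind = "saturation",
                                 engine = engine %||% "foldx"))
  }

  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  eng <- engine %||% (if ("engine" %in% names(df)) df$engine[1] else "unknown")
  if ("mutations" %in% names(df)) {
    if (!"energy" %in% names(df)) stop("missing energy column in ", path)
    if (!is.numeric(df$energy)) stop("non-numeric energy in ", path)
    return(combinatorial_energy_table(df$mutations, df$energy, engine = eng))
  }
  needed <- c("site", "from_aa", "to_aa", "energy")
  if (!all(needed %in% names(df))) {
    stop("expected columns ", paste(needed, collapse = ", "), " in ", path)
  }
  if (!is.numeric(df$energy)) stop("non-numeric energy in ", path)
  to3 <- aa_canon(df$to_aa)
  one_per_site <- !anyDuplicated(df$site)
  kind <- if (all(to3 == "ALA") && one_per_site) "alanine_scan" else "saturation"
  mutation_energy_table(df$site, df$from_aa, df$to_aa, df$energy,
                        kind = kind, engine = eng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stability classification bands
#'
#' Energy bands (kcal/mol) used throughout the screen: mutations with
#' energy in `[neutral_low, neutral_high]` are neutral, below `neutral_low`
#' stabilizing, above `neutral_high` destabilizing.  `candidate_cutoff` is
#' the stricter threshold a saturation substitution must beat to become a
#' candidate design.
#'
#' @param neutral_low,neutral_high bounds of the no-effect band (defaults
#'   -0.5 / +0.5 kcal/mol)
#' @param candidate_cutoff candidate threshold (default -1.5 kcal/mol)
#' @return list of class `stability_bands`
#' @export
stability_bands <- function(neutral_low = -0.5, neutral_high = 0.5,
                            candidate_cutoff = -1.5) {
  if (!(neutral_low < neutral_high)) {
    stop("neutral_low must be below neutral_high")
  }
  if (!(candidate_cutoff <= neutral_low)) {
    stop("candidate_cutoff must not exceed neutral_low")
  }
  structure(list(neutral_low = neutral_low, neutral_high = neutral_high,
                 candidate_cutoff = candidate_cutoff),
            class = "stability_bands")
}

#' Classify mutation energies
#'
#' Band boundaries are inclusive to neutral: an energy exactly at
#' `neutral_low` or `neutral_high` classifies as neutral, since only
#' energies strictly below the lower bound count as stabilizing.
#'
#' @param energy numeric vector (kcal/mol)
#' @param bands a [stability_bands()]
#' @return character vector: `"stabilizing"`, `"neutral"` or
#'   `"destabilizing"`
#' @export
classify_stability <- function(energy, bands = stability_bands()) {
  ifelse(energy < bands$neutral_low, "stabilizing",
         ifelse(energy > bands$neutral_high, "destabilizing", "neutral"))
}

#' Alanine-scan stability screen
#'
#' Sites whose alanine substitution energy falls strictly below the
#' stabilizing threshold, minus excluded sites (e.g. catalytic metal-binding
#' residues), ascending.
#'
#' @param table a `mutation_energy_table` of kind `alanine_scan`
#' @param bands a [stability_bands()]
#' @param exclusions integer sites to drop
#' @return sorted integer vector of sites
#' @export
alanine_scan_filter <- function(table, bands = stability_bands(),
                                exclusions = integer()) {
  if (!identical(table_kind(table), "alanine_scan")) {
    stop("expected an alanine_scan table, got kind ", table_kind(table))
  }
  hits <- unique(table$site[table$energy < bands$neutral_low])
  sort(setdiff(hits, exclusions))
}

non_self <- function(table) table[table$from_aa != table$to_aa, , drop = FALSE]

site_rows <- function(table, site) {
  rows <- table[table$site == site, , drop = FALSE]
  if (nrow(rows) == 0) stop("site ", site, " not present in table")
  rows
}

#' Best saturation substitution at a site
#'
#' The minimum-energy non-self substitution; ties broken by the
#' alphabetically first 3-letter code.
#'
#' @param table a saturation `mutation_energy_table`
#' @param site residue number
#' @return list with `to_aa` (3-letter code) and `energy` (kcal/mol)
#' @export
saturation_best <- function(table, site) {
  rows <- non_self(site_rows(table, site))
  if (nrow(rows) == 0) stop("site ", site, " has no non-self substitutions")
  rows <- rows[order(rows$energy, rows$to_aa), , drop = FALSE]
  list(to_aa = rows$to_aa[1], energy = rows$energy[1])
}

#' Count destabilizing substitutions at a site
#'
#' Non-self substitutions with energy strictly above zero.
#'
#' @inheritParams saturation_best
#' @return integer count
#' @export
count_destabilizing <- function(table, site) {
  rows <- non_self(site_rows(table, site))
  sum(rows$energy > 0)
}

#' Candidate substitutions under the saturation cutoff
#'
#' All (site, substitution) pairs with energy strictly below the bands'
#' `candidate_cutoff`.
#'
#' @param table a saturation `mutation_energy_table`
#' @param bands a [stability_bands()]
#' @return data frame: `site`, `to_aa`, `energy`, `label`, ascending by
#'   energy
#' @export
candidate_sites <- function(table, bands = stability_bands()) {
  if (!identical(table_kind(table), "saturation")) {
    stop("expected a saturation table, got kind ", table_kind(table))
  }
  rows <- non_self(table)
  rows <- rows[rows$energy < bands$candidate_cutoff, , drop = FALSE]
  rows <- rows[order(rows$energy, rows$label), , drop = FALSE]
  rownames(rows) <- NULL
  rows[, c("site", "to_aa", "energy", "label")]
}

#' Rank mutants by energy
#'
#' Ascending by energy (most stabilizing first), ties broken by the
#' lexicographic mutation label.  The top element is the selected design.
#'
#' @param table a `mutation_energy_table` (any kind)
#' @return data frame of class `mutant_ranking`: `label`, `energy`;
#'   attribute `selected` = top label
#' @export
rank_mutants <- function(table) {
  if (nrow(table) == 0) stop("cannot rank an empty table")
  rows <- table[order(table$energy, table$label), c("label", "energy")]
  rownames(rows) <- NULL
  attr(rows, "selected") <- rows$label[1]
  attr(rows, "engine") <- attr(table, "engine")
  class(rows) <- c("mutant_ranking", "data.frame")
  rows
}

#' Additive folding free-energy change of a multi-mutant
#'
#' Under the additivity approximation the ddG of a multi-site mutant is the
#' arithmetic sum of its single-mutant ddG values; duplicated sites violate
#' the assumption and raise an error.
#'
#' @param singles data frame with columns `site` and `energy` (kcal/mol),
#'   e.g. rows of a `mutation_energy_table`
#' @return summed ddG (kcal/mol)
#' @export
additive_ddg <- function(singles) {
  if (is.null(singles) || nrow(singles) == 0) {
    stop("need at least one single mutant")
  }
  if (anyDuplicated(singles$site)) {
    stop("duplicated site ", singles$site[duplicated(singles$site)][1],
         ": additivity assumes pairwise-distinct sites")
  }
  sum(singles$energy)
}

#' Build a combinatorial table by additivity from singles
#'
#' For each requested mutation set, sums the single-substitution energies
#' from `singles`; the resulting table is tagged with the source engine plus
#' `"+additive"` so reports can state which path produced a ranking.
#'
#' @param singles a saturation (or alanine-scan) `mutation_energy_table`
#' @param sets list of mutation sets, each a data frame `site`, `to_aa`
#' @return a combinatorial `mutation_energy_table`
#' @export
additive_table <- function(singles, sets) {
  labels <- character(0)
  energies <- numeric(0)
  for (set in sets) {
    rows <- merge(set, singles, by.x = c("site", "to_aa"),
                  by.y = c("site", "to_aa"), sort = FALSE)
    if (nrow(rows) != nrow(set)) {
      stop("mutation set contains substitutions absent from singles table")
    }
    ord <- order(rows$site)
    labels <- c(labels, paste(rows$label[ord], collapse = "/"))
    energies <- c(energies, additive_ddg(rows))
  }
  combinatorial_energy_table(labels, energies,
                             engine = paste0(attr(singles, "engine"),
                                             "+additive"))
}
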