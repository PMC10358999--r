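CONFIG_KEYS <- c("structure", "ensembles", "profiles", "rmsd_regions",
                 "rmsf_regions", "low_contact_regions",
                 "glycine_phi_table", "energy_tables",
                 "contact_rule", "hbond_criteria", "stability_bands",
                 "rmsd", "rmsf", "low_contact", "exclusions",
                 "output_dir", "seed")

config_defaults <- function() {
  list(
    structure = NULL,
    ensembles = list(),
    profiles = list(),
    rmsd_regions = NULL,
    rmsf_regions = NULL,
    low_contact_regions = NULL,
    glycine_phi_table = NULL,
    energy_tables = list(),
    contact_rule = list(threshold = 3),
    hbond_criteria = list(max_dist = 3.5, min_angle = 150),
    stability_bands = list(neutral_low = -0.5, neutral_high = 0.5,
                           candidate_cutoff = -1.5),
    rmsd = list(delta_min = 0.5, min_len = 3),
    rmsf = list(delta_min = 0.5, min_len = 3),
    low_contact = list(max_contacts = 2, min_len = 3),
    exclusions = list(),
    output_dir = NULL,
    seed = 1
  )
}

check_subkeys <- function(value, allowed, where) {
  unknown <- setdiff(names(value), allowed)
  if (length(unknown) > 0) {
    stop("unknown key in ", where, ": ", paste(unknown, collapse = ", "))
  }
}

resolve_path <- function(path, base_dir) {
  if (is.null(path)) return(NULL)
  if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base_dir, path)
  if (!file.exists(path)) stop("referenced path does not exist: ", path)
  path
}

#' Validate and normalize a screening configuration
#'
#' Reads a JSON config, fills documented defaults, rejects unknown keys (so
#' typos never silently disable a threshold), range-checks every threshold
#' group, and verifies that every referenced input path exists.  Relative
#' paths are resolved against the config file's directory.  At least one
#' screening factor must have inputs.
#'
#' @param path path to a JSON config file
#' @return object of class `screen_config`: the defaulted, checked
#'   configuration as a named list
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  }
  cfg <- config_defaults()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  base_dir <- dirname(normalizePath(path))

  check_subkeys(cfg$contact_rule, "threshold", "contact_rule")
  check_subkeys(cfg$hbond_criteria, c("max_dist", "min_angle"),
                "hbond_criteria")
  check_subkeys(cfg$stability_bands,
                c("neutral_low", "neutral_high", "candidate_cutoff"),
                "stability_bands")
  check_subkeys(cfg$rmsd, c("delta_min", "min_len"), "rmsd")
  check_subkeys(cfg$rmsf, c("delta_min", "min_len"), "rmsf")
  check_subkeys(cfg$low_contact, c("max_contacts", "min_len"), "low_contact")

  # constructors enforce the numeric invariants (band inversion etc.)
  defaults <- config_defaults()
  cfg$stability_bands <- utils::modifyList(defaults$stability_bands,
                                           cfg$stability_bands)
  do.call(stability_bands, cfg$stability_bands)
  cfg$contact_rule <- utils::modifyList(defaults$contact_rule,
                                        cfg$contact_rule)
  do.call(contact_rule, cfg$contact_rule)
  cfg$hbond_criteria <- utils::modifyList(defaults$hbond_criteria,
                                          cfg$hbond_criteria)
  do.call(hbond_criteria, cfg$hbond_criteria)
  cfg$rmsd <- utils::modifyList(defaults$rmsd, cfg$rmsd)
  cfg$rmsf <- utils::modifyList(defaults$rmsf, cfg$rmsf)
  cfg$low_contact <- utils::modifyList(defaults$low_contact, cfg$low_contact)

  cfg$structure <- resolve_path(cfg$structure, base_dir)
  cfg$glycine_phi_table <- resolve_path(cfg$glycine_phi_table, base_dir)
  cfg$ensembles <- lapply(cfg$ensembles, function(e) {
    check_subkeys(e, c("path", "temperature"), "ensembles")
    e$path <- resolve_path(e$path, base_dir)
    e$temperature <- e$temperature %||% NA_real_
    e
  })
  cfg$profiles <- lapply(cfg$profiles, function(p) {
    check_subkeys(p, c("path", "temperature"), "profiles")
    p$path <- resolve_path(p$path, base_dir)
    p
  })
  cfg$energy_tables <- lapply(cfg$energy_tables, function(t) {
    check_subkeys(t, c("path", "dialect", "engine"), "energy_tables")
    t$path <- resolve_path(t$path, base_dir)
    t$dialect <- t$dialect %||% "csv"
    t
  })
  cfg$exclusions <- lapply(cfg$exclusions, function(x) {
    check_subkeys(x, c("site", "reason"), "exclusions")
    x$reason <- x$reason %||% "unspecified"
    x
  })
  if (!is.null(cfg$rmsd_regions)) {
    cfg$rmsd_regions <- unlist(cfg$rmsd_regions)
    parse_ranges(cfg$rmsd_regions)
  }
  if (!is.null(cfg$rmsf_regions)) {
    cfg$rmsf_regions <- unlist(cfg$rmsf_regions)
    parse_ranges(cfg$rmsf_regions)
  }
  if (!is.null(cfg$low_contact_regions)) {
    cfg$low_contact_regions <- unlist(cfg$low_contact_regions)
    parse_ranges(cfg$low_contact_regions)
  }

  has_factor <- !is.null(cfg$structure) ||
    length(cfg$ensembles) >= 2 || length(cfg$profiles) >= 2 ||
    !is.null(cfg$rmsd_regions) || !is.null(cfg$rmsf_regions) ||
    !is.null(cfg$low_contact_regions) ||
    !is.null(cfg$glycine_phi_table) || length(cfg$energy_tables) > 0
  if (!has_factor) stop("config enables no screening factor")

  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "screen_config"
  cfg
}

exclusion_df <- function(cfg) {
  if (length(cfg$exclusions) == 0) {
    return(data.frame(site = integer(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    site = vapply(cfg$exclusions, function(x) as.integer(x$site), integer(1)),
    reason = vapply(cfg$exclusions, function(x) as.character(x$reason),
                    character(1)),
    stringsAsFactors = FALSE
  )
}

#' Run the full candidate-site and mutant screen
#'
#' Executes the screening factors in a fixed order — temperature-shift
#' (RMSD) regions, RMSF-increase regions, low-contact regions, glycine phi
#' rule, alanine scan — aggregates the nominated sites with per-factor
#' provenance and the configured exclusions, then runs the energy stage:
#' per-site saturation screening under the candidate cutoff and ranking of
#' combinatorial mutants (supplied directly, or synthesized by additive
#' combination of the per-site best substitutions when no combinatorial
#' table is given).  Factors whose inputs are missing are skipped and
#' listed in the report.  Deterministic given config and seed.
#'
#' @param config a `screen_config` from [validate_config()]
#' @return object of class `screen_report` (a named list); see
#'   [write_report()] for serialization
#' @export
run_screen <- function(config) {
  if (!inherits(config, "screen_config")) stop("config must be a screen_config")
  bands <- do.call(stability_bands, config$stability_bands)
  rule <- do.call(contact_rule, config$contact_rule)

  structure <- if (!is.null(config$structure)) read_pdb(config$structure)
  ensembles <- lapply(config$ensembles, function(e) {
    read_ensemble(e$path, temperature = as.numeric(e$temperature))
  })
  profiles <- lapply(config$profiles, function(p) read_profile(p$path))
  tables <- lapply(config$energy_tables, function(t) {
    parse_energy_table(t$path, dialect = t$dialect, engine = t$engine)
  })

  skipped <- character()
  factors <- list()

  # -- factor 1: RMSD-shift regions ------------------------------------
  if (!is.null(config$rmsd_regions)) {
    factors$rmsd_region <- parse_ranges(config$rmsd_regions)
  } else if (length(ensembles) >= 2) {
    temps <- vapply(ensembles, function(e) e$temperature, numeric(1))
    lo <- ensembles[[which.min(temps)]]
    hi <- ensembles[[which.max(temps)]]
    prd <- per_residue_rmsd(lo, hi,
                            window_a = default_window(n_frames(lo)),
                            window_b = default_window(n_frames(hi)))
    factors$rmsd_region <- mask_to_ranges(
      prd$chain, prd$resnum, prd$rmsd >= config$rmsd$delta_min,
      config$rmsd$min_len
    )
  } else {
    skipped <- c(skipped, "rmsd_region")
  }

  # -- factor 2: RMSF-increase regions ---------------------------------
  rmsf_profiles <- NULL
  if (!is.null(config$rmsf_regions)) {
    factors$rmsf_region <- parse_ranges(config$rmsf_regions)
  } else {
    if (length(profiles) >= 2) {
      temps <- vapply(profiles, function(p) {
        t <- attr(p, "temperature")
        if (is.null(t)) NA_real_ else t
      }, numeric(1))
      rmsf_profiles <- list(low = profiles[[which.min(temps)]],
                            high = profiles[[which.max(temps)]])
    } else if (length(ensembles) >= 2) {
      temps <- vapply(ensembles, function(e) e$temperature, numeric(1))
      rmsf_profiles <- list(
        low = per_residue_rmsf(ensembles[[which.min(temps)]]),
        high = per_residue_rmsf(ensembles[[which.max(temps)]])
      )
    }
    if (!is.null(rmsf_profiles)) {
      factors$rmsf_region <- rmsf_increase_regions(
        rmsf_profiles$low, rmsf_profiles$high,
        delta_min = config$rmsf$delta_min, min_len = config$rmsf$min_len
      )
    } else {
      skipped <- c(skipped, "rmsf_region")
    }
  }

  # -- factor 3: low-contact regions -----------------------------------
  if (!is.null(config$low_contact_regions)) {
    factors$low_contact <- parse_ranges(config$low_contact_regions)
  } else if (!is.null(structure)) {
    factors$low_contact <- low_contact_regions(
      structure, rule,
      max_contacts = config$low_contact$max_contacts,
      min_len = config$low_contact$min_len
    )
  } else {
    skipped <- c(skipped, "low_contact")
  }

  # -- factor 4: glycine phi rule --------------------------------------
  gly_table <- NULL
  if (!is.null(config$glycine_phi_table)) {
    gly_table <- read_glycine_phi(config$glycine_phi_table)
  } else if (!is.null(structure)) {
    gly_table <- glycine_phi_table(structure)
  }
  if (!is.null(gly_table) && nrow(gly_table) > 0) {
    factors$gly_phi <- glycine_phi_candidates(gly_table)
  } else {
    skipped <- c(skipped, "gly_phi")
  }

  # -- factor 5: alanine scan ------------------------------------------
  kinds <- vapply(tables, table_kind, character(1))
  ala <- which(kinds == "alanine_scan")
  if (length(ala) > 0) {
    factors$ala_scan <- alanine_scan_filter(tables[[ala[1]]], bands)
  } else {
    skipped <- c(skipped, "ala_scan")
  }

  if (length(factors) == 0) stop("no screening factor could be run")
  candidates <- aggregate_candidates(factors, exclusion_df(config))

  # -- energy stage ----------------------------------------------------
  saturation <- NULL
  sat_idx <- which(kinds == "saturation")
  if (length(sat_idx) > 0) {
    sat <- tables[[sat_idx[1]]]
    sites <- sort(unique(sat$site))
    best <- lapply(sites, function(s) {
      b <- saturation_best(sat, s)
      data.frame(site = s, to_aa = b$to_aa, energy = b$energy,
                 destabilizing = count_destabilizing(sat, s),
                 stringsAsFactors = FALSE)
    })
    saturation <- list(
      best = do.call(rbind, best),
      candidates = candidate_sites(sat, bands)
    )
  }

  ranking <- NULL
  ranking_path <- NULL
  comb_idx <- which(kinds == "combinatorial")
  if (length(comb_idx) > 0) {
    ranking <- rank_mutants(tables[[comb_idx[1]]])
    ranking_path <- "supplied"
  } else if (!is.null(saturation) && nrow(saturation$best) >= 2) {
    b <- saturation$best
    pairs <- utils::combn(seq_len(nrow(b)), 2, simplify = FALSE)
    sets <- lapply(pairs, function(p) {
      data.frame(site = b$site[p], to_aa = b$to_aa[p],
                 stringsAsFactors = FALSE)
    })
    ranking <- rank_mutants(additive_table(tables[[sat_idx[1]]], sets))
    ranking_path <- "additive"
  }

  report <- list(
    version = as.character(utils::packageVersion("thermoscreen")),
    config = config_echo(config, bands, rule),
    factors = factors,
    skipped_factors = skipped,
    candidate_set = candidates,
    saturation = saturation,
    ranking = ranking,
    ranking_path = ranking_path,
    selected_design = if (!is.null(ranking)) attr(ranking, "selected")
  )
  class(report) <- "screen_report"
  report
}

# every threshold used, echoed explicitly in the report
config_echo <- function(config, bands, rule) {
  list(
    contact_rule = list(threshold = rule$threshold,
                        comparison = "strict-less-than"),
    hbond_criteria = config$hbond_criteria,
    stability_bands = unclass(bands),
    rmsd = config$rmsd,
    rmsf = config$rmsf,
    low_contact = config$low_contact,
    seed = config$seed,
    inputs = list(
      structure = config$structure,
      ensembles = vapply(config$ensembles, `[[`, character(1), "path"),
      profiles = vapply(config$profiles, `[[`, character(1), "path"),
      glycine_phi_table = config$glycine_phi_table,
      energy_tables = vapply(config$energy_tables, `[[`, character(1),
                             "path")
    )
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat("  factors run:     ", paste(names(x$factors), collapse = ", "), "\n")
  if (length(x$skipped_factors) > 0) {
    cat("  factors skipped: ", paste(x$skipped_factors, collapse = ", "), "\n")
  }
  cat("  candidate sites: ", nrow(x$candidate_set$sites), "\n")
  if (!is.null(x$selected_design)) {
    cat("  selected design: ", x$selected_design,
        sprintf(" (%.2f kcal/mol, %s)", x$ranking$energy[1], x$ranking_path),
        "\n")
  }
  invisible(x)
}

report_to_list <- function(report) {
  f <- lapply(report$factors, function(x) {
    if (is.data.frame(x)) as.list(format_ranges(x)) else as.integer(x)
  })
  out <- list(
    version = report$version,
    config = report$config,
    factors = f,
    skipped_factors = as.list(report$skipped_factors),
    candidate_sites = report$candidate_set$sites,
    exclusions_applied = report$candidate_set$exclusions_applied,
    selected_design = report$selected_design,
    ranking_path = report$ranking_path
  )
  if (!is.null(report$saturation)) {
    out$saturation_best <- report$saturation$best
    out$saturation_candidates <- report$saturation$candidates
  }
  if (!is.null(report$ranking)) out$ranking <- as.data.frame(report$ranking)
  out
}

#' Write a screen report to disk
#'
#' Emits `report.json` (canonical machine-readable form; content is a pure
#' function of config + inputs, so identical runs produce byte-identical
#' files), `candidates.tsv` (site, nominating factors), and
#' `narrative.txt`, a plain-text account that mirrors the screen's decision
#' order with every threshold echoed.
#'
#' @param report a `screen_report`
#' @param dir output directory (created if needed)
#' @return invisibly, the report paths
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  tsv_path <- file.path(dir, "candidates.tsv")
  sites <- report$candidate_set$sites
  excl <- report$candidate_set$exclusions_applied
  tsv <- rbind(
    data.frame(site = sites$site, factors = sites$factors,
               excluded_reason = "", stringsAsFactors = FALSE),
    if (nrow(excl) > 0) {
      data.frame(site = excl$site, factors = "",
                 excluded_reason = excl$reason, stringsAsFactors = FALSE)
    }
  )
  utils::write.table(tsv[order(tsv$site), ], tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  txt_path <- file.path(dir, "narrative.txt")
  con <- file(txt_path, "w")
  writeLines(screen_narrative(report), con)
  writeLines(paste("written:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
             con)
  close(con)
  invisible(c(json = json_path, tsv = tsv_path, narrative = txt_path))
}

screen_narrative <- function(report) {
  e <- report$config
  lines <- c(
    "Candidate-site screen, decision order",
    "=====================================",
    sprintf("contact rule: distance < %g A (strict)",
            e$contact_rule$threshold),
    sprintf("stability bands: neutral [%g, %g] kcal/mol, candidate cutoff %g",
            e$stability_bands$neutral_low, e$stability_bands$neutral_high,
            e$stability_bands$candidate_cutoff),
    sprintf("RMSF increase rule: delta >= %g A over >= %d residues",
            e$rmsf$delta_min, e$rmsf$min_len),
    sprintf("low-contact rule: <= %d partners over >= %d residues",
            e$low_contact$max_contacts, e$low_contact$min_len),
    ""
  )
  for (f in names(report$factors)) {
    x <- report$factors[[f]]
    desc <- if (is.data.frame(x)) {
      if (nrow(x) == 0) "none" else paste(format_ranges(x), collapse = ", ")
    } else {
      if (length(x) == 0) "none" else paste(x, collapse = ", ")
    }
    lines <- c(lines, sprintf("factor %-12s -> %s", f, desc))
  }
  if (length(report$skipped_factors) > 0) {
    lines <- c(lines, sprintf("skipped (missing inputs): %s",
                              paste(report$skipped_factors, collapse = ", ")))
  }
  lines <- c(lines, "",
             sprintf("aggregated candidate sites (%d): %s",
                     nrow(report$candidate_set$sites),
                     paste(report$candidate_set$sites$site, collapse = ", ")))
  excl <- report$candidate_set$exclusions_applied
  if (nrow(excl) > 0) {
    lines <- c(lines, sprintf("excluded: %s",
                              paste(sprintf("%d (%s)", excl$site, excl$reason),
                                    collapse = "; ")))
  }
  if (!is.null(report$saturation)) {
    b <- report$saturation$best
    lines <- c(lines, "", "saturation screen, per-site best substitution:",
               sprintf("  site %d -> %s (%.2f kcal/mol, %d destabilizing)",
                       b$site, b$to_aa, b$energy, b$destabilizing))
  }
  if (!is.null(report$ranking)) {
    lines <- c(lines, "",
               sprintf("mutant ranking (%s): top = %s (%.2f kcal/mol)",
                       report$ranking_path, report$selected_design,
                       report$ranking$energy[1]))
  }
  lines
}
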