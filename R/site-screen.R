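#' Residue ranges
#'
#' Inclusive residue-number ranges on one chain, written `"A:90-96"` in
#' configs and reports.  A single residue is `"A:100"` or `"A:100-100"`.
#'
#' @param chain chain id (single character)
#' @param start,end first and last residue number (inclusive, `start <= end`)
#' @return data frame with columns `chain`, `start`, `end`
#' @export
residue_range <- function(chain, start, end = start) {
  if (any(end < start)) stop("range end must be >= start")
  data.frame(chain = chain, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' @rdname residue_range
#' @param x character vector of range strings like `"A:90-96"`; a bare
#'   `"90-96"` defaults to chain A
#' @export
parse_ranges <- function(x) {
  out <- lapply(x, function(s) {
    s <- trimws(s)
    chain <- "A"
    if (grepl(":", s, fixed = TRUE)) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1]]
      chain <- parts[1]
      s <- parts[2]
    }
    nums <- suppressWarnings(as.integer(strsplit(s, "-", fixed = TRUE)[[1]]))
    if (anyNA(nums) || length(nums) < 1 || length(nums) > 2) {
      stop("cannot parse residue range: ", s)
    }
    residue_range(chain, nums[1], nums[length(nums)])
  })
  do.call(rbind, out)
}

#' @rdname residue_range
#' @param ranges a range data frame
#' @export
format_ranges <- function(ranges) {
  ifelse(ranges$start == ranges$end,
         sprintf("%s:%d", ranges$chain, ranges$start),
         sprintf("%s:%d-%d", ranges$chain, ranges$start, ranges$end))
}

# Expand ranges to the residue numbers they cover (per chain).
expand_ranges <- function(ranges) {
  if (is.null(ranges) || nrow(ranges) == 0) return(integer())
  unlist(lapply(seq_len(nrow(ranges)), function(i) {
    seq.int(ranges$start[i], ranges$end[i])
  }))
}

# Collapse a logical mask over an ordered residue table into maximal runs of
# TRUE with length >= min_len, expressed as ranges.  Runs never span chain
# breaks or residue-numbering gaps.
mask_to_ranges <- function(chain, resnum, mask, min_len = 1) {
  n <- length(mask)
  if (n == 0) return(residue_range(character(), integer())[0, ])
  new_block <- c(TRUE, chain[-1] != chain[-n] | diff(resnum) != 1L)
  block <- cumsum(new_block)
  grp <- paste(block, cumsum(c(TRUE, diff(as.integer(mask)) != 0L)))
  out <- list()
  for (g in unique(grp[mask])) {
    idx <- which(grp == g & mask)
    if (length(idx) >= min_len) {
      out[[length(out) + 1]] <- residue_range(chain[idx[1]],
                                              resnum[idx[1]],
                                              resnum[idx[length(idx)]])
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Regions whose flexibility increases with temperature
#'
#' Maximal runs of at least `min_len` consecutive residues whose RMSF
#' increase (`high - low`) is at least `delta_min`.  These are the flexible
#' loops that loosen on heating and are nominated for rigidification.
#' The defaults (0.5 Angstrom over at least 3 residues) define what the
#' screen treats as a significant increase and are echoed in every report.
#'
#' @param low,high `flexibility_profile` objects at the lower and higher
#'   simulated temperature, covering the same residues
#' @param delta_min minimum RMSF increase (Angstrom)
#' @param min_len minimum run length (residues)
#' @return range data frame (`chain`, `start`, `end`)
#' @export
rmsf_increase_regions <- function(low, high, delta_min = 0.5, min_len = 3) {
  key_l <- residue_key_string(low$chain, low$resnum, low$icode)
  key_h <- residue_key_string(high$chain, high$resnum, high$icode)
  if (!identical(key_l, key_h)) {
    stop("profiles cover different residue sets")
  }
  delta <- high$rmsf - low$rmsf
  mask_to_ranges(low$chain, low$resnum, delta >= delta_min, min_len)
}

#' Regions of sparse residue contacts
#'
#' Maximal runs of at least `min_len` consecutive residues whose contact
#' count under `rule` is at most `max_contacts`.  Poorly packed stretches
#' respond more strongly to temperature and are screened as candidate
#' regions.
#'
#' @param structure a `structure_model`
#' @param rule a [contact_rule()]
#' @param max_contacts maximum partner count for a residue to be "sparse"
#' @param min_len minimum run length
#' @return range data frame (`chain`, `start`, `end`)
#' @export
low_contact_regions <- function(structure, rule = contact_rule(),
                                max_contacts = 2, min_len = 3) {
  cc <- contact_counts(structure, rule)
  mask <- !is.na(cc$contacts) & cc$contacts <= max_contacts
  mask_to_ranges(cc$chain, cc$resnum, mask, min_len)
}

#' Glycine backbone-dihedral table
#'
#' Computes phi for every glycine in a structure (chain-start glycines,
#' which have no phi, are omitted).  Used by the glycine rigidification
#' rule: only glycines with phi below zero can be replaced by bulkier
#' residues without forcing a disallowed backbone conformation.
#'
#' @param structure a `structure_model`
#' @return data frame of class `glycine_phi_table`: `resnum`, `phi`
#'   (degrees)
#' @export
glycine_phi_table <- function(structure) {
  res <- structure$residues
  gly <- which(res$resname == "GLY")
  rows <- list()
  for (i in gly) {
    phi <- tryCatch(
      phi_of_residue(structure, res$resnum[i], res$chain[i], res$icode[i]),
      error = function(e) NA_real_
    )
    if (!is.na(phi)) {
      rows[[length(rows) + 1]] <- data.frame(resnum = res$resnum[i], phi = phi)
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(resnum = integer(), phi = numeric())
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("glycine_phi_table", "data.frame")
  out
}

#' @rdname glycine_phi_table
#' @param path CSV with columns `residue` (or `resnum`) and `phi`
#' @export
read_glycine_phi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(out)[names(out) == "residue"] <- "resnum"
  if (!all(c("resnum", "phi") %in% names(out))) {
    stop("glycine phi table needs columns residue/resnum and phi")
  }
  out <- out[, c("resnum", "phi")]
  if (any(out$phi <= -180 | out$phi > 180)) {
    stop("phi angles must lie in (-180, 180]")
  }
  class(out) <- c("glycine_phi_table", "data.frame")
  out
}

#' Glycine sites eligible for rigidifying substitution
#'
#' Sites with phi strictly below zero, minus the supplied exclusions
#' (typically glycines adjacent to the active site), in ascending order.
#'
#' @param table a `glycine_phi_table`
#' @param exclusions integer vector of sites to drop; a site absent from the
#'   table triggers a warning, not an error
#' @return sorted integer vector of residue numbers
#' @export
glycine_phi_candidates <- function(table, exclusions = integer()) {
  if (nrow(table) == 0) stop("glycine phi table is empty")
  hits <- table$resnum[table$phi < 0]
  missing <- setdiff(exclusions, table$resnum)
  if (length(missing) > 0) {
    warning("exclusion site(s) not in table: ", paste(missing, collapse = ", "))
  }
  sort(setdiff(hits, exclusions))
}

#' Total residue count covered by ranges
#'
#' @param ranges range data frame (`chain`, `start`, `end`)
#' @param merge_overlaps merge overlapping ranges (per chain) before
#'   counting, so shared residues are counted once
#' @return integer residue count
#' @export
region_total <- function(ranges, merge_overlaps = TRUE) {
  if (is.null(ranges) || nrow(ranges) == 0) return(0L)
  if (any(ranges$end < ranges$start)) stop("invalid range: end < start")
  if (!merge_overlaps) {
    return(sum(ranges$end - ranges$start + 1L))
  }
  total <- 0L
  for (ch in unique(ranges$chain)) {
    r <- ranges[ranges$chain == ch, , drop = FALSE]
    total <- total + length(unique(expand_ranges(r)))
  }
  total
}

#' Aggregate per-factor candidate sites with provenance
#'
#' Union of the sites nominated by each screening factor, recording for each
#' site every factor that nominated it; exclusions are removed from the set
#' and logged with their reason.
#'
#' @param factors named list; each element is either an integer vector of
#'   sites or a range data frame (`chain`, `start`, `end`)
#' @param exclusions `NULL`, or a data frame with columns `site` and
#'   `reason`
#' @return object of class `candidate_set`: list with `sites` (data frame
#'   `site`, `factors`), and `exclusions_applied` (data frame `site`,
#'   `reason`)
#' @export
aggregate_candidates <- function(factors, exclusions = NULL) {
  if (length(factors) == 0) stop("at least one factor is required")
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("factors must be a named list")
  }
  site_map <- list()
  for (fname in names(factors)) {
    f <- factors[[fname]]
    sites <- if (is.data.frame(f)) expand_ranges(f) else as.integer(f)
    for (s in unique(sites)) {
      key <- as.character(s)
      site_map[[key]] <- union(site_map[[key]], fname)
    }
  }
  all_sites <- sort(as.integer(names(site_map)))

  excl_applied <- data.frame(site = integer(), reason = character(),
                             stringsAsFactors = FALSE)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    hit <- exclusions$site %in% all_sites
    excl_applied <- data.frame(site = as.integer(exclusions$site[hit]),
                               reason = as.character(exclusions$reason[hit]),
                               stringsAsFactors = FALSE)
    all_sites <- setdiff(all_sites, exclusions$site)
  }

  sites_df <- data.frame(
    site = all_sites,
    factors = vapply(as.character(all_sites), function(k) {
      paste(sort(site_map[[k]]), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(sites_df) <- NULL
  structure(list(sites = sites_df, exclusions_applied = excl_applied),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d site(s), %d exclusion(s) applied\n",
              nrow(x$sites), nrow(x$exclusions_applied)))
  invisible(x)
}

# round half away from zero (printed-table convention); base round() is
# half-to-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Secondary-structure content summary
#'
#' Per-class residue counts and percentages from user-supplied region
#' assignments (the package performs no secondary-structure assignment of
#' its own).  Percentages are `100 * count / total`, rounded half-up to two
#' decimals, matching common printed-table precision.
#'
#' @param regions named list mapping class (e.g. `helix`, `turn`, `coil`) to
#'   a range data frame
#' @param total_residues total residue count of the protein
#' @return data frame: `class`, `count`, `percentage`
#' @export
secstruct_summary <- function(regions, total_residues) {
  if (total_residues <= 0) stop("total_residues must be > 0")
  rows <- lapply(names(regions), function(cls) {
    r <- regions[[cls]]
    if (!is.null(r) && nrow(r) > 0 && any(r$end > total_residues)) {
      stop("class ", cls, " has a range beyond residue ", total_residues)
    }
    count <- region_total(r, merge_overlaps = FALSE)
    data.frame(class = cls, count = count,
               percentage = round_half_up(100 * count / total_residues, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read secondary-structure region assignments from CSV
#'
#' Expects columns `class` and `range` (range strings like `"A:12-28"`),
#' one row per region, as produced by external secondary-structure
#' assignment or visual inspection.
#'
#' @param path CSV path
#' @return named list mapping class to a range data frame, ready for
#'   [secstruct_summary()]
#' @export
read_secstruct_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "range") %in% names(df))) {
    stop("expected columns class and range in ", path)
  }
  out <- lapply(split(df$range, df$class), parse_ranges)
  out[unique(df$class)]
}
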