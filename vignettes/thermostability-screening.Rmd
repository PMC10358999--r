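---
title: "Screening rigidifying mutations for enzyme thermostability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening rigidifying mutations for enzyme thermostability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscreen)
```

## The screening model

`thermoscreen` implements a multi-factor rational-design screen for enzyme
thermostability.  The premise is that a protein loses activity at elevated
temperature through its most flexible, most weakly packed parts, and that
stability is gained by *rigidifying* those parts — substituting small,
conformationally permissive residues (above all glycine) with bulkier ones
at positions where the backbone can accommodate them.  The screen never
computes physics itself: molecular-dynamics ensembles and mutation energies
are produced by external engines (an MD code; Discovery Studio's mutation
energy or FoldX ΔΔG), and the package consumes their outputs and applies
the decision rules.

Six factors nominate candidate sites, executed in a fixed order so that
provenance tags are comparable across runs:

1. **Temperature-shift (RMSD) regions.**  Per-residue Cα displacement
   between the average conformations of a low- and a high-temperature
   ensemble, after global Cα superposition.  Runs of at least `min_len`
   residues shifting by at least `delta_min` (defaults 0.5 Å over 3
   residues) are nominated; regions identified by visual conformational
   comparison can be supplied directly as `"A:238-245"` strings instead.
2. **RMSF-increase regions.**  Per-residue root-mean-square fluctuation at
   each temperature; runs where the high-temperature RMSF exceeds the
   low-temperature RMSF by at least `delta_min` over at least `min_len`
   residues.  The source protocol calls such increases "significant"
   without quantifying them; the 0.5 Å / 3-residue defaults are this
   package's operational definition, are mandatory in the config, and are
   echoed in every report.
3. **Low-contact regions.**  Two residues are in contact when their
   β-carbons (α-carbon for glycine) lie strictly closer than a threshold.
   The packaged default threshold is the literal `3` used by the protocol
   this package reproduces.  That value carries no unit in its source; read
   as Ångström it is a very tight criterion, which is why the threshold is
   a mandatory, always-echoed configuration value rather than a hidden
   constant.  Residues with at most `max_contacts` partners (default 2)
   over runs of `min_len` form sparse, weakly packed stretches.
4. **Glycine φ rule.**  The backbone torsion φ = C(i−1)–N–CA–C.  A glycine
   with φ > 0 sits in a left-handed conformation no other residue tolerates
   — mutating it would distort the backbone.  A glycine with φ < 0 can be
   replaced by a larger residue, trading conformational entropy for
   rigidity.  Only φ < 0 glycines pass.
5. **Alanine scan.**  Externally computed alanine-substitution energies;
   sites with energy strictly below the stabilizing threshold (−0.5
   kcal/mol) pass.
6. **Exclusions.**  Catalytically required sites (metal-binding residues,
   substrate-pocket neighbours) are user-supplied with a reason and removed
   during aggregation — the package deliberately has no active-site
   detector, so no exclusion is ever silently inferred.

Aggregation takes the set union and records, per site, every factor that
nominated it.  The energy stage then screens saturation-mutagenesis tables
(all 19 substitutions per site) with the stricter candidate cutoff (−1.5
kcal/mol) and ranks combinatorial mutants ascending by energy; the top
element is the selected design.

## Energy conventions

Stability bands follow the convention of the mutation-energy engines:
energies in `[-0.5, +0.5]` kcal/mol are neutral, below −0.5 stabilizing,
above +0.5 destabilizing.  Boundary values classify as neutral, because
only energies *strictly below* the bound count as stabilizing.  Tables
carry an `engine` tag and are never mixed across engines in one screen:
the same substitution can score, e.g., −3.82 kcal/mol in one engine and
−0.997 in another, so cross-engine comparisons are meaningless.
Self-substitution rows (GLY→GLY, printed as 0 by saturation engines) are
retained on parsing but excluded from column minima and destabilizing
counts.  Ties in a column minimum resolve to the alphabetically first
3-letter code, and ranking ties resolve by the lexicographic mutation
label, so rankings are total and reproducible.

For multi-site mutants two paths exist: a directly supplied combinatorial
table, or additive synthesis, where the ΔΔG of a multi-mutant is
approximated as the sum of its single-mutant values.  Additivity assumes
the sites do not interact — duplicated sites are an error — and each
report states which path produced its ranking (`supplied` or `additive`).

## Ensemble analytics

Ensembles are multi-model PDB files, one frame per MODEL block, sharing
one topology; binary trajectory formats are out of scope, so users export
frames beforehand.  All analytics remove rigid-body motion with a proper
(determinant +1) Kabsch superposition before measuring anything:

* **Per-frame RMSD** against a reference, over Cα by default.
* **Average structure**: window frames superposed to the first window
  frame, then averaged atom-wise.
* **Representative frame**: the window frame with the lowest Cα RMSD to
  the average — the single-conformation stand-in for a trajectory segment;
  ties break to the lowest index.
* **Per-residue RMSF** about the mean position.  The alignment target is
  the average structure with one re-averaging pass (align to first frame →
  average → re-align to that average → re-average): the source protocol
  does not specify a scheme, and a single extra pass is a standard,
  inexpensive stabilizer of the alignment target.
* **Hydrogen-bond series**: geometric detection per frame.  Donors are
  backbone amide nitrogens (proline excluded); the amide hydrogen is taken
  from the file when present and otherwise constructed in the peptide
  plane along the bisector of the N–C(i−1) and N–CA directions at 1.01 Å.
  Acceptors are backbone carbonyl oxygens plus side-chain O/N heavy atoms.
  Side-chain *donors* are not counted: their hydrogen positions cannot be
  reconstructed reliably from heavy atoms alone, and counting them without
  an angle test would inflate counts.  A pair bonds when the
  donor–acceptor distance is ≤ 3.5 Å and the D–H–A angle ≥ 150°
  (configurable); each donor–acceptor residue pair counts once, and
  sequence neighbours (separation < 2) never count.  Only intra-protein
  bonds are counted — solvent is invisible to this package.

Analysis windows are frame-index based (frame times are metadata only);
the default window keeps the trailing 75% of frames, the same proportion
as analysing the 5–20 ns segment of a 20 ns production run, expressed as a
fraction so it generalizes to any frame count.

## Numerical choices

* Coordinates are Å everywhere; residue numbering is the author numbering
  of the input file, 1-based, with inclusive ranges (`"A:90-96"`).  The
  package never hard-codes a protein length — published descriptions of
  the worked example disagree internally about its residue count (274
  vs. 276), which is exactly why lengths always come from inputs.
* Contact comparison is strict `<`; hydrogen-bond distance is `≤`.  Each
  matches its source convention and both appear in report metadata.
* The torsion sign follows IUPAC (cis = 0°, trans = 180°, range
  (−180°, 180°]); the first residue of a chain has no φ and says so.
* Superposition of fewer than 3 points, or of collinear point sets, is
  refused rather than silently regularized.
* Secondary-structure percentages round half-up to two decimals, matching
  printed-table precision; classes come from user-supplied region
  assignments — no DSSP reimplementation.
* Alternate locations: altloc `A`/blank kept, others dropped with a
  warning.  HETATM records are retained as metadata, never as residues.

## The worked example

The packaged `tyr_*` fixtures transcribe the published screen of a
bacterial tyrosinase: the glycine φ table (22 glycines), the alanine-scan
table (12 stabilizing sites), the two-site saturation table (19 × 2), the
double-mutant table (15 rows), the FoldX single-mutant ΔΔG file, and the
secondary-structure region list.  Running `run_screen()` on
`tyr_screen_config.json` reproduces the published decision sequence: five
factors aggregate to 56 candidate sites after exclusions, the saturation
minima at sites 124 and 137 are both tryptophan, and the ranking selects
G124W/G137W.  One bookkeeping note: the union of the five published factor
sets is exactly 56 *because* four glycine sites and six alanine-scan sites
are shared with other factors; the per-site provenance tags in the
candidate set make those overlaps explicit.  The published β-turn ranges
enumerate 7 residues while the printed count is 6 (one range overlaps a
coil range); the package counts what ranges enumerate and leaves such
reconciliation to the user's region input.

## What the synthetic generators emulate

`make_helix()` builds poly-alanine backbones with exact requested φ/ψ by
internal-coordinate chain extension (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å, ω = 180°), giving structures whose dihedrals are known to the
construction tolerance.  `make_ensemble()` adds iid Gaussian noise per
coordinate with per-residue σ, so each residue's expected RMSF is the
analytic σ√3 in the many-frame limit.  `make_energy_table()` draws
background energies uniformly inside the neutral band [−0.4, +0.4]
kcal/mol and inserts planted entries verbatim, so planted signals are the
only screening hits.  All generators are pure functions of their arguments
including the seed.

These fixtures validate the *decision logic*, not the physics: real
trajectories have correlated, anisotropic fluctuations, drifting means and
solvent effects, and real mutation-energy tables have correlated errors.
Passing the planted-recovery suites shows the screen's thresholds, run
detection and bookkeeping are correct — not that the defaults are optimal
for any particular protein.

Validation problem sizes were chosen to keep the analytic limits sharp at
desk scale: 40-residue helices, 2000-frame ensembles for the σ√3 recovery
(sampling error ≈ 1.6%, alignment absorption ≈ 3%, comfortably inside the
5% acceptance band), 80–100-frame ensembles for the 20-seed end-to-end
planted-recovery runs.

## Limitations

* Trajectory-dependent published quantities (hydrogen-bond means at each
  temperature, RMSD/RMSF curves of the real protein) require the original
  trajectories and are context, not reproducible targets.
* The contact threshold's missing unit is resolved by fiat (literal 3,
  surfaced in config and reports), not by re-deriving the original
  analysis.
* No structure preparation: missing atoms, protonation and model quality
  are upstream concerns.
* The screen treats factors as independent evidence; it does not model
  epistasis beyond the explicit additivity approximation, and it performs
  no docking or activity prediction — catalytic-site protection is purely
  the user's exclusion list.
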