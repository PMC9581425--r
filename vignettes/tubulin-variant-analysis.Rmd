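---
title: "Structural and predictor-based analysis of tubulin missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and predictor-based analysis of tubulin missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulinvep)
```

## The problem

Human tubulins — the α-, β- and γ-tubulin paralogues the field calls
*isotypes* — carry a large number of reported dominant pathogenic missense
mutations, associated with neurodevelopmental disorders but also with
bleeding disorders, female infertility and neurodegeneration. Because
dominant-negative and gain-of-function mechanisms are thought to dominate
tubulin disease, two standard computational lenses — structural context and
variant effect predictors (VEPs) — behave unusually on this family, and
quantifying *how* they behave requires a reproducible pipeline rather than
one-off scripts. `tubulinvep` implements that pipeline: variant curation,
structural-location classification, location-enrichment statistics,
stability (ΔΔG) group comparisons, ROC/AUC benchmarking of VEP score
tables, and a rank-based ensemble score (MCD) that identifies the
pathogenic mutations the predictors handle worst.

## Variant catalog

Variants are parsed from compact protein-change tokens (`"V353I"`:
wild-type residue, 1-based position, mutant residue) and validated against
an isotype registry: the isotype must exist and the token's wild-type
letter must match the registry sequence at that position; failing rows are
rejected with a per-row reason. Substitutions reported as pathogenic *and*
observed in gnomAD are removed from both sets, since they carry no signal
for benchmarking. Putatively benign gnomAD variants serve as negatives
throughout.

The packaged registry metadata (family, phenotype classification,
gnomAD missense-constraint Z-scores, reported variant counts for the 19
isotypes surveyed) is real; the packaged *sequences* are deterministic
synthetic stand-ins (`make_synthetic_registry_fasta()`), which keeps every
position-validated workflow runnable self-contained. The loader is
sequence-agnostic: pass a real FASTA to `isotype_registry()` for real
analyses. Gene symbols are normalised to HGNC style, and the Greek
notations common in the literature (TUBα1A, TUBß8) are accepted.

## Structural-location classification

Each variant position is mapped onto three-dimensional structures and
assigned exactly one class through a fixed hierarchy:

1. **GTP_BINDING** — any heavy atom of the mapped residue within the
   contact cutoff of GTP or an analogue (component codes GTP, GDP, GNP,
   GSP, GCP, G2P by default), unioned over *all* retained structures;
2. **INTRADIMER** — contact with the partner subunit within the tubulin
   heterodimer, read from the configured intradimer model structure;
3. **MAP_INTERFACE** — contact with a microtubule-associated protein in
   the configured MAP model;
4. **INTERDIMER** — lateral/longitudinal microtubule-lattice contact in
   the configured lattice model;
5. **SURFACE** / **INTERIOR** — otherwise, by relative solvent-accessible
   surface area (rSASA), strictly greater than 0.25 meaning surface, taken
   from the highest-resolution structure in which the position maps;
6. **OUTSIDE_STRUCTURE** — the position maps into no retained structure.

Key parameters, with defaults and rationale:

* **Contact cutoff, 5.0 Å** heavy-atom-to-heavy-atom. No single value is
  canonical; 5 Å is a conventional interface-contact distance, and the
  cutoff is configurable everywhere it is used.
* **Chain retention: ≥ 70 % identity over ≥ 50 aligned residues**, from a
  global Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5),
  identity computed over aligned (non-gap) columns. This admits related
  (non-human, non-identical-isotype) tubulin chains while excluding
  unrelated proteins.
* **Triplet mapping rule**: a position is used only when it *and both
  sequence neighbours* align to consecutive structure residues with
  identical amino acids — the structure must literally display the
  isotype's local sequence. Terminal positions (no two neighbours) are
  therefore unmappable, and positions where the deposited structures show
  a different residue (a common situation for diverged isotypes) fall to
  OUTSIDE_STRUCTURE. We require the variant residue itself, not merely any
  residue of the triplet, to make interface contact.
* **rSASA: Shrake–Rupley sampling**, 960 points per atom, probe 1.4 Å,
  element van-der-Waals radii (C 1.70, N 1.55, O 1.52, S/P 1.80; unknown
  elements fall back to 1.70 with a warning), normalised by the Tien et
  al. (2013) theoretical maxima per residue type. 960 points keeps the
  per-residue numerical error well under the distance to the 0.25
  decision boundary for anything not already borderline.
* **Resolution ties** are broken toward the lexicographically smallest
  structure id, making annotation fully deterministic. Structures without
  a recorded resolution sort last. Residues with missing atoms still
  count for contacts using the atoms present.

PDB inputs with REMARK 350 records have biological assembly 1 expanded
(extra transform copies get chain ids suffixed `.k`). mmCIF files are read
via bio3d but without assembly expansion — a known limitation; the package
never downloads structures.

## Enrichment, stability and benchmarking statistics

Location enrichment compares, per structural class, in-class versus
not-in-class counts between pathogenic and gnomAD variants with a
two-sided Fisher's exact test, per family and per isotype. Tests are
per-class 2×2 (matching per-class significance stars at
0.05/0.01/0.001/0.0001) and deliberately uncorrected for multiple testing;
the enriched label is read off the conditional odds ratio. An omnibus
single-table alternative would answer a different question (any
distributional difference at all) and is not what per-class stars report.

ΔΔG tables (FoldX layout: `ddg_fold` for the monomer, `ddg_full` for the
biological assembly, kcal/mol, positive = destabilising) are consumed as
data — FoldX is never executed. Group comparisons use the unpaired
two-sided rank-sum test under four metrics (`fold`, `full`, and their
absolute values); records missing the requested metric are dropped per
comparison with a logged count.

Rank tests take the exact enumeration path for small samples (pooled
n ≤ 20 for the rank-sum, ≤ 15 nonzero differences for the signed-rank,
both tie-free), otherwise the normal approximation with tie and continuity
corrections. The limits are configurable; they are chosen so that
desk-scale analyses are exact while isotype-scale comparisons stay fast.

VEP benchmarking treats pathogenic variants as positives. Predictors on
inverse scales (lower = more damaging: PROVEAN, DeepSequence, SIFT4G,
BLOSUM by default) are negated once before any ROC work. The AUC is the
rank statistic (ties counted half), identical to the trapezoidal area
under the unique-threshold ROC curve; missing scores are dropped per
predictor (complete-case per column, no imputation). Stratified AUC
matrices use only the stratum's own gnomAD variants as negatives — pooling
negatives across isotypes is a config-level alternative we did not adopt,
since it mixes sequence contexts. Per-phenotype-group performance is
compared by pairing each predictor's two group AUCs in a paired
signed-rank test. Optimal thresholds minimise the Euclidean distance to
the ROC top-left corner over midpoints of adjacent distinct scores (plus
±∞), break ties toward higher specificity, and are reported on the
predictor's *native* scale with an explicit direction ("below" for inverse
predictors).

## The MCD score

For each predictor, oriented scores of the *pooled* pathogenic + gnomAD
dataset are converted to cumulative-distribution ranks — the proportion of
scores less than or equal to each score, giving values in (0, 1] — and
each mutation's **mean cumulative distribution (MCD)** is the mean of its
available ranks. Low MCD on a pathogenic mutation means the predictor
ensemble collectively scored it benign-like, so sorting pathogenic
mutations by ascending MCD (ties broken lexicographically) surfaces the
worst-predicted ones. Orientation *before* ranking is what makes ranks
comparable across predictors. Averaging over available predictors only
(rather than requiring complete cases across all predictors) avoids
discarding most of the data under realistic missingness; the number of
predictors used is reported per mutation. The original description of
this score mentions, in one place, normalisation within a window
partition of the combined dataset; the procedural definition is a single
global cumulative distribution per predictor, which is what we implement.

## Synthetic data and what passing tests mean

The generators produce every input the pipeline consumes, with planted
truth:

* `make_toy_structure()` builds a rigid toy assembly: two extended
  pseudo-chains touching over a planted interface patch, a 4-atom GTP
  ligand 3.6 Å from a pocket residue, and an occluding atom cage that
  buries a three-residue core. The seed applies only a rigid rotation and
  translation, so every planted contact and burial margin is identical
  across seeds. Positions adjacent to the cage are deliberately excluded
  from the truth set (their accessibility is genuinely borderline).
* `make_score_matrix()` draws benign scores from N(0,1) and pathogenic
  from N(d,1), so the expected AUC has the closed form Φ(d/√2) — the
  recovery target used in tests.
* `make_variant_catalog()` samples distinct substitutions (pathogenic and
  benign disjoint by construction), optionally with per-class sampling
  odds to plant a location enrichment; without enrichment its counts
  default to the published per-isotype totals, so the packaged catalog
  fixture reproduces those counts exactly while its membership is
  synthetic.
* `make_ddg_table()` plants a mean ΔΔG shift (gnomAD N(0.5, 1.2²) in
  kcal/mol) with correlated monomer/assembly noise.

These emulate the *shape* of the real inputs — not real tubulin geometry,
empirical score distributions, or the correlation structure between
predictors (real VEPs are strongly correlated; synthetic columns are
independent). Passing tests therefore demonstrate that the machinery is
correct and calibrated, not that real tubulin variants are well
predicted. Test problem sizes: toy chains of 60 residues, catalogs of
60–200 variants per label, score matrices up to 1000 + 1000 rows, and
2000-replicate null calibrations — sizes at which the full suite runs in
well under a minute per stage on one CPU.

## Degenerate inputs and tie-breaks, in one place

Identity substitutions (`"A5A"`) are parse errors; single-class strata are
errors naming the stratum; all-missing score vectors and all-zero paired
differences are errors; empty ligand or interface sets return empty
tables, not errors. Deduplication is idempotent. Classification is total:
every variant receives exactly one class, with OUTSIDE_STRUCTURE the
fallback (with a warning when an isotype retains no structure at all).
Ties: resolution → smallest structure id; optimal threshold → lower false
positive rate; MCD ranking → (isotype, protein_change) lexicographic.

## Known limitations

* Real structures and real supplementary score tables are not bundled;
  real-data runs are config-driven and the user must supply files plus a
  `model_roles` configuration naming which structures define the
  intradimer, MAP and lattice interfaces.
* mmCIF biological assemblies are not expanded.
* The registry ships synthetic sequences; real-sequence validation
  requires a user-supplied FASTA.
* MCD is a ranking device, not a calibrated probability.
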