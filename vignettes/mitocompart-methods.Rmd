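---
title: "Methods: sequence-derived prediction of sub-mitochondrial localization"
author: "mitocompart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-derived prediction of sub-mitochondrial localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Mitochondria contain four protein-bearing compartments — the inner and
outer membranes, the intermembrane space, and the matrix — and a
protein's compartment is strongly constrained by global properties of
its sequence: membrane proteins are enriched in hydrophobic stretches,
matrix proteins in charged and polar residues, and so on. `mitocompart`
casts compartment assignment as four-class supervised classification: a
fixed 239-dimensional encoding of the sequence, information-gain feature
ranking, and a radial-basis-function support vector machine (libsvm via
e1071, one-vs-one multi-class), evaluated by stratified k-fold
cross-validation with per-class one-vs-rest sensitivity, specificity,
Matthews correlation and ROC/AUC.

This choice of machinery embodies two assumptions worth keeping in
view: (i) the localization signal is carried by *global, coarse-grained*
sequence statistics, not by a specific targeting peptide — the encoder
deliberately contains no cleavage-site or PSSM/profile features; and
(ii) compartments are mutually exclusive — multi-location proteins are
removed during curation rather than modelled.

## The feature encoding

The vector has four named blocks, concatenated in a fixed order
(`featureLayout()` returns `c(ccd = 60, saac = 60, fg_sse = 88,
physchem = 31)`). Amino acids are always ordered alphabetically by
one-letter code (A, C, D, …, Y).

**Composition / centroid / distribution (60).** For each amino acid
`a`: its frequency `n_a / L`; its centroid, the mean of its 1-based
positions divided by `L` (0 when absent); and its distribution, the
standard deviation of its normalized positions. Three simple statistics
per residue type — how much, where on average, and how spread out. We
use the population (1/n) standard deviation so that a single occurrence
gives exactly 0 rather than an undefined value; with ≥2 occurrences the
difference from the sample convention is a bounded factor
√((n−1)/n) and irrelevant to ranking or classification.

**Split amino-acid composition (60).** The sequence is cut at
`floor(L/3)` and `floor(2L/3)` — parts of sizes `floor(L/3)`,
`floor(2L/3) − floor(L/3)`, `L − floor(2L/3)` — and the 20-residue
composition of each third is reported separately. This restores the
crude positional information (N-terminal vs C-terminal bias) that the
global composition discards.

**Functional groups, short peptides, secondary structure (88).** The
sub-block structure is 17 + 5 + 3 + 51 + 12:

* 17 whole-sequence group frequencies: 10 functional groups defined by
  side-chain chemistry (aliphatic AVLIG, hydroxyl ST, sulfur CM,
  aromatic FWY, basic KRH, acidic DE, amide NQ, imino P, tiny AG,
  charged DEKRH) and 7 physico-chemical groups (hydrophobic CFILMVW,
  hydrophilic DEKNQR, neutral AGHPSTY, polar DEHKNQRSTY, non-polar
  ACFGILMPVW, small ACDGNPSTV, aromatic FHWY). Groups may overlap;
  each frequency is member residues over `L`. All memberships live in
  TSV resources under `inst/extdata/` and can be overridden.
* 5 short-peptide class frequencies: a 10-residue window slides along
  the sequence and is assigned to a peptide class when a strict
  majority (> w/2) of its residues belong to that class. The five
  residue classes (hydrophobic FILMVW, hydrophilic DEKR, polar NQSTY,
  non-polar AGP, neutral CH) are a *disjoint partition* of the
  alphabet, so at most one class can hold a strict majority and no
  tie-breaking order is needed; windows without a majority count toward
  nothing, which is why these five frequencies lie in [0,1] without
  summing to 1.
* 3 secondary-structure content fractions (helix, sheet, coil).
* 51 per-state group frequencies: the 17 group frequencies recomputed
  within helix, sheet and coil residues separately (denominator =
  residues in that state; 0 when a state is absent).
* 12 per-state short-peptide frequencies: the four non-neutral peptide
  classes per state, a window belonging to the state of its central
  residue (position ⌈w/2⌉ of the window), normalized by the number of
  windows centred in that state (0 when none are).

The decomposition of this block, the group memberships, and the
per-state window conventions are package conventions, fixed once and
documented here; the field uses several near-equivalent variants and
none is canonical.

**Physicochemical properties (31).** Each feature is the mean over the
sequence of one per-residue AAindex scale. The default set of 31 scales
(hydropathy KYTJ820101, hydrophilicity HOPT810101, bulkiness
ZIMJ680102, Grantham polarity and volume, flexibility BHAR880101,
accessible surface areas CHOC760101/2, van der Waals volume, … — the
full accession list is in `defaultPhyschemScales()`) is loaded at run
time from the AAindex copy bundled with **seqinr**; it is a curated
convention covering hydrophobicity, size, polarity, flexibility and
exposure, and any 31 complete accessions — or an external TSV via
`readPhyschemScales()` — can be substituted.

## Secondary-structure assignment

The per-state features need an H/E/C string per sequence.
`assignSSE()` provides a self-contained propensity assigner: classical
Chou–Fasman helix and sheet propensities (shipped as
`inst/extdata/chou_fasman.tsv`) are smoothed with a centred moving
average (window 5, truncated at the termini — terminal residues are
averaged over their available neighbours rather than over invented
padding), and each position is called H when the smoothed helix
propensity is ≥ 1.03 and exceeds the sheet value, E when the sheet
propensity is ≥ 1.05 and exceeds the helix value, and C otherwise. The
1.03/1.05 cutoffs are the classical former/breaker boundaries of the
two scales; window and cutoffs are arguments. This is intentionally a
fast approximation, not a modern predictor: the features consume only
coarse state fractions and state-conditioned compositions, which are
robust to per-residue errors. A pre-computed assignment from any
external predictor can be passed to `encodeSequence(sse = …)`.

## Feature selection

`informationGain()` discretizes a feature into 10 equal-width bins over
its observed range (a constant column collapses to one bin) and returns
H(Y) − H(Y|X) in bits. Equal-width binning is the simplest
deterministic choice and matches common machine-learning toolkit
behaviour; the bin count is an argument. `rankFeatures()` orders
features by descending gain with ties broken by ascending feature
index, so rankings are total and reproducible, and `topFeatures(k)`
subsets are nested by construction. In cross-validation the ranking is
recomputed from each training fold and the frozen index set applied to
the held-out fold — selection never sees test labels.

## Classifier and tuning

Features are min–max scaled to [0,1] using training statistics stored
in the model and re-applied at prediction; RBF kernels are not
scale-invariant and unscaled blocks (e.g. molecular weight vs a
frequency) would otherwise dominate the distance. The SVM is libsvm's
one-vs-one multi-class machine; for ROC analysis, per-class one-vs-rest
scores are formed as the signed sum of the pairwise decision values
involving the class. `gridSearch()` evaluates mean stratified k-fold CV
accuracy over a (C, γ) grid — default the libsvm practitioner's grid,
C ∈ 2^{−5..15}, γ ∈ 2^{−15..3} in steps of 2² — with ties broken
toward smaller C then smaller γ (preferring the smoother model).
Class weighting is off by default and available as
`classWeighting = "balanced"` for imbalanced data. Fold assignment
depends only on (labels, folds, seed): per class, a seeded shuffle is
dealt round-robin, so fold sizes differ by at most one per class and
every sample is tested exactly once.

The pipeline runner `runPipelineCV()` tunes once on the full encoded
matrix with a reduced 3×3 grid (`pipelineGrid()`: C ∈ 2^{0,3,6},
γ ∈ 2^{−7,−5,−3}) and then cross-validates with per-fold selection.
Running the full grid inside every fold would multiply cost ~25-fold
for no benefit on the well-conditioned problems the runner targets; the
full grid remains the default of `gridSearch()` itself.

## Evaluation

All metrics are exact ratios of one-vs-rest confusion counts;
`ConfusionCounts` stores the 4×4 matrix and derives TP/FP/TN/FN per
class. A metric whose denominator is zero (e.g. specificity of a class
absent from a small fold) is reported as `NA`, never silently as 0 —
with realistic class imbalance (intermembrane-space proteins are rare)
degenerate folds are a real possibility and must be visible. Overall
accuracy is the trace of the confusion matrix over its total. AUC uses
the rank-based Mann–Whitney formulation, identical to trapezoidal
integration of the tie-grouped ROC curve, with ties counted as
half-concordant; the macro AUC is the unweighted mean of the per-class
one-vs-rest AUCs.

## The synthetic-data generator

`generateProteins()` emits i.i.d. residues from per-class emission
profiles: a uniform base in which each compartment's five signature
residues (inner membrane FILVW, intermembrane space CGHST, matrix
DEKNQ, outer membrane AMPRY) are boosted by `1 + effectSize` and the
row renormalized. The defaults — 100 sequences per class, lengths
uniform on [80, 200] (above the curation minimum, around the scale of
small globular proteins), `effectSize = 4` (signature residues emitted
five-fold above background, a strong compositional effect),
`effectSize = 0` as the permutation null — are the package's reference
conditions, chosen once. Signature sets are disjoint across classes so
the null is exactly uniform and the strong condition is learnable from
composition alone. An optional `blockStructure` mode confines the class
signal to the N-terminal third, exercising the split-composition and
centroid features specifically.

The generator emulates compositional class structure only. Real
proteins have positional grammar, domains, phylogenetic correlation
between training and test sequences, and severe class imbalance; a
pipeline that is perfect on the strong synthetic condition is therefore
*validated as software* — encoding, selection, tuning and evaluation
wired correctly, no leakage — not certified to reach any particular
accuracy on curated SWISS-PROT data.

## Dataset curation

`curate()` applies, in order: ambiguous-annotation removal
(case-insensitive substring match on "possible", "probable",
"by similarity", "potential"), multi-location removal (two or more
distinct compartment phrases co-occurring in the annotation), a minimum
length of 80 residues, and the standard 20-letter alphabet. Each record
counts against the first filter it fails, so the report's counts
conserve the input exactly. The order of filters, and the
keyword-co-occurrence reading of "multiple location", are package
conventions; annotation formats differ between databases and no
machine-readable rule is universal. Taxonomic filtering (e.g.
eukaryote, non-plant) is the caller's responsibility — plain FASTA
carries no taxonomy. `reduceRedundancy()` is a self-contained
CD-HIT-style greedy clustering: longest sequence first (ties by id), a
sequence joins the first representative it exceeds 70% identity with,
where identity is matches over alignment columns of a global alignment
scored match 1 / mismatch 0 / linear gap −1 (Biostrings). Keeping this
in-package avoids an external binary dependency at the cost of the
quadratic runtime that is irrelevant at curated-dataset sizes.

## Numerical and degenerate-input conventions

* Empty sequences, sequences shorter than 3 (split composition) or than
  the 10-residue peptide window, and nonstandard residues raise errors
  naming the offence; filtering is the curation layer's job, encoding
  refuses silently wrong answers.
* Grid-search ties prefer smaller C, then smaller γ; ranking ties
  prefer the lower feature index; both make results independent of hash
  or sort instability.
* All randomness (generation, fold shuffling) runs under local seeds
  that restore the caller's RNG state.
* Information gain clips the tiny negative rounding residue of
  H(Y) − H(Y|X) at 0.

## Problem sizes

The shipped tests and the acceptance script use 400 synthetic sequences
(100 per class, lengths 80–200) for end-to-end runs, ≤ 20 sequences for
alignment-oracle checks, and ≤ 10⁴ samples for statistical sanity
checks of the information-gain estimator — sizes chosen so the full
suite documents the method's behaviour in about a minute on a single
core while still exercising every code path at realistic dimensionality
(the feature space is always the full 239).

## Known limitations

* The Chou–Fasman assigner is a 1970s-era approximation; the per-state
  feature block inherits its biases. The override hook exists precisely
  so profile-based assignments can be substituted.
* The 88-feature block decomposition, the group memberships, and the
  identity of the 31 physicochemical scales are fixed conventions among
  several defensible variants; results depend on them only through
  smooth group/scale averages, but byte-level comparability with other
  implementations of the same feature counts is not claimed.
* The encoder ignores homology: redundancy reduction at 70% identity
  limits, but does not eliminate, train/test relatedness in real data.
* No probability calibration; decision scores are suitable for ranking
  (ROC) but are not posterior probabilities.
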