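---
title: "Methods and design of the glycoPSC pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the glycoPSC pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoPSC)
```

# The analysis model

`glycoPSC` analyses site-level N-glycosylation across a panel of cell
lines — by default five hiPSC lines (Gra1, Gra2, Gra7, CBF46, CBF50), two
hESC lines (H9, NTU1) and the two parental somatic lines (HGra, HF), each
profiled in three replicate runs. The pipeline's statistical object is an
intensity matrix of glycosites by runs; everything downstream is built from
replicate means, coefficients of variation and fold-change ratios of those
intensities, so the core assumptions are the usual ones of label-free
quantitation: intensities are positive, multiplicative in their error
structure (hence all correlation and clustering work on log2 values, and
replicate noise is modelled as normal in log space), and run-level
systematic differences are removable by a single multiplicative factor per
run (mean normalization).

## Identification gates

A glycosite row survives identification iff

* it is not a contaminant or reverse-database (decoy) identification —
  matched either by flag columns or by the `REV__`/`CON__` identifier
  prefixes of the MaxQuant dialect;
* its site localization score is ≥ 50 **and** its localization probability
  is ≥ 0.8 in at least 2 replicate runs of at least one cell line;
* its reported asparagine position is a true N‑X≠P‑[S/T/C] sequon of its
  protein in the supplied FASTA.

Both thresholds are inclusive, following their "≥" statement. The
probability rule is evaluated *within* a cell line's replicates (a site
passing in any one line is retained globally); whether the original rule
meant per-line or across all 27 runs is not decidable from its wording, and
the per-line reading is both the stricter-per-line and the one consistent
with reporting per-line identification counts. `min_prob_replicates` makes
it configurable. Sequon scanning is positional and overlapping (the string
`NNSS` has sequons at positions 1 and 2); positions within two residues of
the sequence end can never match, and letters outside the 20-residue
alphabet never match.

## Quantitation

After mean normalization (each run scaled so its mean over non-missing
features equals the grand mean of run means), a site is *comparable* in a
pairwise comparison iff it has ≥ 2 non-missing replicates in both lines,
its CV — sample (n−1) standard deviation over mean, on the **linear**
scale, the conventional definition — is ≤ 0.20 in **both** lines, and its
peptide carries no variable-modification (oxidation/acetylation) flag.
Fold change is the ratio of normalized replicate means, not the mean of
ratios; calls use the inclusive 2-fold gate in either direction. Design
choices worth stating:

* *CV gate in both lines.* "CV ≤ 20 %" does not say one line or both; both
  is the stricter, reproducibility-oriented reading, and it is what the
  `cv_threshold` gate implements.
* *Missing-in-one-line sites are non-comparable*, not infinitely
  regulated: the method's own reporting of a "comparable" universe per
  comparison implies such sites are set aside.
* *Voting consistency.* A site is a general hiPSC alteration when it is
  called in one direction in ≥ 5 of the 10 hiPSC-vs-hESC comparisons *and
  never in the opposite direction*. Without the consistency clause a site
  could qualify as both a general up- and down-alteration;
  `require_consistency = FALSE` restores the permissive reading.
* Fold changes are computed from all non-missing replicates; the CV gate
  decides comparability but does not drop replicates from the mean.

## Calibration

Glyco fold changes are divided by the parent protein's fold change for the
same line pair (equivalently log2 subtraction) — the minimal operation
consistent with "adjusting a PTM change by the protein change". Proteins
with several glycosites are calibrated per site and rolled up afterwards.
The status rule keeps three regimes: |log2 FC<sub>cal</sub>| ≥ 1 is
retained; [log2 1.75, 1) is retained with a `near_threshold` flag (the
analysis this package implements explicitly kept two such proteins); below
log2 1.75 the glyco change is explained by the protein change. Non-positive
or missing protein folds are flagged as record-level errors and excluded
from classification rather than silently dropped.

## Network significance

The candidate–PluriNet subnetwork keeps edges with confidence ≥ 0.7 and
candidates with at least one direct PluriNet edge. Two topology statistics
are tested — the average local clustering coefficient (degree < 2
contributes 0) and the mean shortest path over unordered pairs of the
largest connected component — against `n_random = 1000` nulls generated by
degree-preserving double-edge swaps (10 × |E| attempted swaps per draw, the
standard mixing heuristic; every draw's degree sequence is asserted equal
to the observed one). Empirical p-values use add-one smoothing,
p = (b + 1)/(n + 1), so p is never 0 and never below 1/(n+1); clustering
counts `random ≥ observed` as extreme, mean shortest path counts
`random ≤ observed`. The Fisher's exact construction classifies every
non-PluriNet gene of the universe by candidate membership × "has ≥ 1
high-confidence PluriNet interaction"; the universe defaults to all nodes
of the interaction database (plus any isolated query genes) and is
configurable, since the original test's margins are one defensible reading
among several. Gene-set enrichment is the hypergeometric upper tail with
Benjamini–Hochberg correction across sets.

## Reprogramming states

Probe filtering removes a probe only when it lies strictly below the
per-sample bottom-quantile cut (default 20 %) in *every* sample — the
reading of "lowest 20 % of the range of intensities in all samples" that
matches a flag-based expression filter's intent; with `quantile = 0`
nothing is removed. Redundancy is collapsed by keeping the probe with the
highest total intensity per gene (ties: lexicographically smaller probe
id). Differential testing is a two-sided Welch t-test on log2 expression,
pooling both lines of each cell type (2 lines × 2 replicates = 4 vs 4 by
default); the original description says only "t-test", and Welch is the
safe unequal-variance default. A significant gene (default α = 0.05,
matching the lower end of the reported p-value tiers) is classified by the
strict sign pattern of its hiPSC and SC means around the hESC mean:

| state | hiPSC vs hESC | SC vs hESC | interpretation |
|---|---|---|---|
| incomplete_silencing | > | > | somatic memory |
| over_silencing | < | > | silenced past the hESC level |
| incomplete_reactivation | < | < | never reached the hESC level |
| over_reactivation | > | < | reactivated past the hESC level |

Equality in either governing comparison, or non-significance, yields
`unchanged`; the four significant states partition the strict-sign space
exactly (tested over all nine sign combinations).

# The synthetic-data generator

The generator is first-class, tested code: it is the study's stand-in for
deposited MS data and produces every input with planted, recoverable truth.
Its defaults are the study conditions: 9 cell lines (5 hiPSC / 2 hESC /
2 SC) × 3 replicates; planted hiPSC-vs-hESC alterations of ±1.5 log2 units
on 15 % of clean sites; replicate CV 0.15 (which makes roughly three
quarters of sites pass the 20 % CV gate at n = 3, the reported range);
run-level missingness 5 % (reproducing the ~82–87 % / 7–11 % / 4–8 %
three/two/one-replicate detection profile); decoy, variable-modification
and localization-failure rows at 5 % / 5 % / 10 % so each filter has real
prey; and a somatic-cell divergence (40 % of sites shifted by ~2 log2
units) that reproduces the PSC-versus-SC separation seen in clustering and
in the much larger altered fraction of PSC-vs-SC comparisons. Intensities
are generated in log2 space (normal noise, sd = CV/ln 2 — exact in the
small-CV limit) and exported linear, matching search-engine output;
missingness is missing-at-random at the run level, the simplest testable
contract. Expression simulation plants each state's inequality pattern
with a 1-log2-unit margin and 0.2 sd replicate noise on two replicates per
line; planted (regulated) genes draw their baselines from the upper half of
the intensity range — regulated glycosylation-pathway genes are expressed
genes — leaving the dedicated low-intensity probe stratum as the filter's
target. The network generator plants an exact number of high-confidence
candidate–PluriNet links (background candidate–PluriNet pairs are capped
below the 0.7 threshold so the count is exact) and a dense PluriNet module.

What the generator does **not** emulate: correlated (abundance-dependent)
missingness, between-line baseline drift beyond the planted shifts, glycan
compositions or spectra, the empirically observed excess of threonine over
serine at the sequon's third position, and — importantly for the network
stage — nulls that are *less* structured than the observed subnetwork
under degree preservation: degree-preserving swaps retain much of the
planted module's structure, so small empirical topology p-values are not
guaranteed on synthetic data even though the planted Fisher-overlap
enrichment is recovered (p ≈ 10⁻³). Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted truths, not that
real data would show the same effect sizes.

# Numerical and determinism choices

* Thresholds are inclusive throughout (≥ 50, ≥ 0.8, ≤ 0.20, ≥ 2-fold,
  ≥ 0.7), with a 1e-12 slack only inside the randomization test's
  extremity counts to keep ties stable under floating-point noise.
* Correlation pairs sharing < 3 features, CVs with < 2 replicates, runs
  with no observations, and empty matched sets are reported as flagged
  `NA`s or errors naming the offender — never fabricated values.
* Clustering of cell lines sorts line names lexicographically before
  building the tree, making the dendrogram independent of input order.
* Every generator takes an explicit seed (via `withr::with_seed`, so the
  caller's RNG state is untouched) and identical calls are byte-identical.
  `run_all()` derives per-stage seeds from one master seed
  (`(seed mod 10^6) × 1009 + stage`), keeping every derived seed well
  below 2³¹ and letting a stage be re-run alone with its in-pipeline seed.
* Degenerate inputs have defined behaviour: a comparison with a constant
  gene in both groups gives t = 0, p = 1 (equal means) or the smallest
  positive p (unequal means); a graph admitting no swap reports p = 1 with
  a warning; an empty candidate set after the confidence gate returns an
  empty network with a warning, not an exception.

# Problem sizes used by the shipped tests

The test-suite simulations are deliberately compact so the whole suite
runs in about a minute: 40–150 proteins per simulated experiment
(~80–300 glycosites), 20 seeds for the quantitation recovery study, 1,000
null networks for the randomization checks, exhaustive enumeration of all
labeled graphs on up to 6 nodes (32,768 six-node graphs) for the topology
oracles, 10,000 random sequences for the sequon oracle, and 120-gene
expression matrices with 40 planted states. These sizes were chosen as the
smallest at which the Monte-Carlo intervals in the tests are meaningful.

# Known limitations

* The pipeline starts from search-engine output; peptide-spectrum
  matching, FDR control of the search, and raw-array preprocessing are out
  of scope, as are match-between-runs, imputation and occupancy
  (stoichiometry) estimation.
* The Fisher-test margins and the probability-gate scope are single
  defensible readings of under-specified procedures; both are exposed as
  configuration rather than hidden constants.
* Multiple-testing correction across genes is offered (BH in
  `enrich_pathways`) but state calling follows the per-gene significance
  convention of the original analysis; genome-scale use should adjust
  `alpha` accordingly.
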