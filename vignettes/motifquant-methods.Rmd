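---
title: "Quantitative immunopeptidome analysis and motif discovery with motifquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative immunopeptidome analysis and motif discovery with motifquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifquant)
```

## The problem

MHC class II molecules such as the HLA-DQ allotypes DQ2.5, DQ2.2 and DQ7.5
present peptides of variable length (roughly 8–25 residues, typically around
14) whose 9-residue *binding core* sits in the peptide-binding groove at an
unknown register. Label-free LC-MS/MS of acid-eluted ligands yields, per
peptide and sample, an *ion peak volume* — a relative abundance estimate.
`motifquant` implements the computational arc from such peptide
quantification tables to (i) normalized, comparable repertoires, (ii)
clustering and differential-abundance statistics between allotypes, and
(iii) quantitative motif discovery: an ensemble of small neural networks
that simultaneously aligns each peptide's binding core and regresses its
abundance, summarized as position-specific frequency matrices and Shannon
logos.

## Normalization and repertoire summaries

Raw ion peak volumes are made comparable across samples by the scale-ratio
transform: each peptide's volume is divided by the summed volume of all
peptides identified in the same sample, so every sample column sums to 1 and
all values live on a 0–1 scale. Zero and missing intensities both mean "not
detected" and stay 0. Group-level abundances are unweighted means over all
technical and biological replicate columns of a group.

Summaries built on this matrix:

* **Abundance shares** — the summed group-mean abundance of a peptide
  selection (top-N, an explicit list, or a predicate such as a CLIP flag),
  reported in percent. Shares are stored full precision and printed to one
  decimal in summaries.
* **Length distributions** — unique detected sequences per length; the mode
  breaks ties toward the smaller length.
* **Nested sets** — the transitive closure of the relation "one sequence
  contains the other as a contiguous substring", computed by hashing all
  substrings whose lengths occur in the data and joining by union-find.
  Containment (not mere overlap) is the deliberate, oracle-checkable reading
  of "nested sets of sequences"; protein of origin is not required to match.
  A peptide "is part of a nested set" when its set has at least two members.
* **CLIP annotation** — a peptide is CLIP if it maps exactly inside the
  invariant chain (CD74) with at least `min_overlap` residues (default 9)
  inside the configured CLIP region, or contains a configured CLIP core
  (defaults: the canonical CLIP1 register core `MRMATPLLM` and an
  alternative-register core `ATPLLMQAL`). Both rules are active by default
  and fully configurable, because published CLIP core definitions vary
  between registers and studies.

## Clustering

The normalized matrix is transformed by `ln(x + 1e-5)`; the floor offset
puts absent peptides at a finite baseline so they still inform similarity,
which is intentional — an absence pattern is a repertoire feature. Natural
logs are used throughout; the base only rescales distances and changes
neither correlation nor Ward orderings.

Samples (columns) are clustered by average linkage on correlation distance
`d = 1 − Pearson`; zero-variance columns get distance 1 with a warning.
Peptides (rows) are clustered by Ward's minimum-variance criterion on
Euclidean distances (`hclust` method `ward.D2`, which applies Ward's
criterion correctly to unsquared distances). Agglomeration and leaf ordering
follow `stats::hclust`'s deterministic conventions; merge heights for
average linkage equal the mean pairwise inter-cluster distance, which the
test suite verifies against a literal brute-force agglomerator.

## Differential abundance

For an allotype pair, each peptide gets a moderated mean-difference
statistic `d = (mean_A − mean_B)/(s + s0)` on log-transformed values, with
`s` the pooled standard error and the fudge factor `s0 = median(s)` over
peptides. The median-`s0` choice is a documented simplification of the
original percentile search; it stabilizes variance without tuning. `d` is
calibrated by group-label permutation (exhaustive whenever at most 10,000
distinct splits exist, otherwise a seeded random sample): `Z` is the
permutation-standardized `d`, and the two-sided p-value counts permuted
`|d|` at least as large as observed — per peptide, with the observed split
included when enumeration is exhaustive, so the smallest achievable p-value
is set by the permutation granularity. Statistics are computed on
log-transformed values by default, consistent with the clustering input;
peptides absent from every sample of both groups are excluded.

The proportion of truly differential peptides is `1 − pi0`, where `pi0` is
the fitted non-increasing (Grenander-type, pool-adjacent-violators) density
of the p-value histogram evaluated at `p = 1`, clipped to [0, 1] — a
transparent approximation to convex density estimation, cross-checked in the
tests against `limma::convest` on mixture data. Twenty equal-width bins
balance bias and variance for the 10³–10⁴ p-values typical here.

The overall repertoire difference is tested with `Q = Σ (mean_A −
mean_B)²` over log values under the same permutation scheme. A permutation
null was chosen over the original score-test asymptotics deliberately: it is
assumption-light, but its p-values are bounded below by `1/(B + 1)`, so
astronomically small analytic p-values are reported here as "at the
permutation floor" rather than as point values.

## Motif discovery

Training data for one allotype are the peptides detected in that group,
minus CLIP peptides (their register is fixed by the invariant chain, not by
groove preference) and peptides shorter than the 9-mer core. Group-mean
abundances `X` become regression targets by `ln(X + 1e-5)` followed by
linear min–max rescaling to [0, 1]; if all abundances are equal the targets
are defined as 0.5.

Each network encodes a candidate 9-mer window as the concatenation of
BLOSUM50 substitution-score rows divided by 5 (20 values per residue, 180
inputs), feeds 3 hidden sigmoid units and one sigmoid output. Training
presents every peptide once per epoch in shuffled order, scores all its
windows with the *current* network, picks the best-scoring window (ties to
the smallest offset), and takes one stochastic gradient step on squared
error for that window only — alignment and regression are learned
simultaneously. Weights start uniform in [−0.1, 0.1]; training runs a fixed
300 epochs without early stopping, with the learning rate decaying linearly
from 0.05 to 0.005. The schedule is a package choice (the architecture is
fixed by convention, the schedule is not); it converges stably across the
simulation scales below and every value is exposed in `nn_config()`.

Redundancy control and cross-validation: peptides sharing any identical
9-mer are forced into one cluster (union-find over hashed 9-mers), and
clusters are dealt — largest first, ties in seed-shuffled order — onto the
currently smallest of 5 folds. The ensemble is 5 network seeds × 5 held-out
folds = 25 networks. A training peptide's reported prediction is the mean
over the 5 networks that held it out (so no network ever predicts a peptide
whose 9-mer relative it trained on); novel peptides use all networks. The
reported binding core is the majority window offset across the *full*
ensemble, ties to the smallest offset: individual networks occasionally lock
onto an alignment register shifted by one position, and the register
consensus is a property of the whole ensemble — a 5-network held-out subset
can be dominated by shifted members, while the 25-network vote is stable. Insertions and deletions within the
core are not modeled: cores are contiguous 9-mers.

Logos can be built two ways, because elution-data motifs and
predictor-encoded motifs are distinct objects: `motif_from_cores()`
summarizes the aligned cores of the training peptides themselves, while
`motif_from_top_scores()` samples 200,000 random 15-mers from a background
composition, keeps the 2,000 highest-scoring, and summarizes *their*
predicted cores. Both paths are provided and default parameters mirror the
conventional logo pipeline: greedy sequence-weighting clusters at 63 %
identity (each cluster shares one unit of weight), substitution-derived
pseudocounts with effective weight `alpha = n_clusters − 1` and pseudocount
weight `beta = 200`, and Shannon heights `height(p, a) = f(p, a) · I_p` with
`I_p = log2(20) + Σ_a f log2 f`. The pseudocount target frequencies
`q(a|b)` are reconstructed from the BLOSUM62 half-bit log-odds scores via
`q(a,b) ∝ p(a) p(b) 2^{S(a,b)/2}` with the shipped proteome-average
background `p` — an analytic reconstruction of the substitution
probabilities rather than the historical count table, adequate because the
pseudocounts only smooth low-count columns.

## The synthetic-data generator

`generate_repertoire()` emulates the statistical structure the analysis
assumes, so every stage is testable without any external data:

* three allotypes with planted 9×20 frequency PWMs (`default_pwms()`): a
  "DQ2.5-like" motif (hydrophobic P1, acidic P4/P6, aromatic P7, no P9
  anchor), a "DQ2.2-like" motif adding a strong S/T anchor at P3 and a P9
  anchor, and an uncharged "DQ7.5-like" motif. These are qualitative test
  fixtures emulating reported motif differences, never claims about the true
  motifs;
* peptide lengths 8–25 with a clear mode at 14 (lengths below the 9-mer core
  are redrawn — a core cannot fit in an 8-mer, so simulated core-bearing
  ligands start at 9);
* nested sets: a ligand spawns end-trimmed variants (short geometric trims,
  never cutting into the core) with probability 0.35;
* log-normal true abundances with `ln A = mu + sigma·z + gamma·LLR(core)`,
  `gamma = 1` by default: the log-likelihood-ratio coupling encodes the
  premise that motif-matching peptides form stabler complexes and accumulate
  — without it the quantitative targets would carry no motif signal and a
  quantitative motif learner would have nothing to find;
* replicate structure 3 cell lines × 2 biological × 3 technical per
  allotype (54 samples), per-sample log-normal loading factors (sd 0.5,
  removed again by normalization), multiplicative replicate noise (CV 0.3),
  and 10 % detection dropout;
* CLIP spike-ins: ragged windows of the canonical CD74 CLIP-region sequence
  embedded in a toy CD74, scaled to configured shares of total signal
  (defaults 53 % / 5 % / 12 % for the three allotypes, mirroring CLIP
  dominance on DQ2.5-like molecules), with moderate log-normal spread
  (sd 0.7) across length variants.

What the generator does **not** emulate: identification error and FDR
structure, modified peptides (deamidation, pyro-Glu, oxidation collapse to
plain sequences upstream), intensity-dependent missingness, ionization
efficiency differences between peptides, shared peptides between allotypes
beyond CLIP, and any real binding chemistry. Passing tests therefore show
that the algorithms recover what they assume, at the noise levels modeled —
they do not certify recovery on real elution data.

## Numerical choices and conventions

* Scale-ratio columns sum to 1 within 1e-9; empty samples stay all-zero with
  a warning rather than an error.
* `d = 0/0` (constant peptide when `s0 = 0`) is 0 by convention; a genuine
  mean difference over a zero denominator keeps its sign at infinity and
  simply tops the ranking.
* Exhaustive permutation p-values include the observed labelling, so the
  identity and its mirror set the attainable minimum (e.g. 2/20 for 3 vs 3).
* Grenander fitting uses `stats::isoreg` on the reversed histogram; the
  estimate is clipped to [0, 1].
* Degenerate rescaling (all abundances equal) maps every target to 0.5.
* Sequence-weighting identity at 63 % of 9 residues means ≥ 6 matching
  positions; `cluster_threshold > 1` disables weighting.
* All randomness flows from explicit seeds; the C++ trainer uses its own
  seeded Mersenne Twister so ensembles are bit-reproducible; pipeline stages
  derive named substreams from one root seed.
* PSSM and peptide-table writers emit 17 significant digits so read–write
  round trips are exact.

## Problem sizes used in validation

The shipped validation uses desk-scale simulations chosen as the package's
own test design: repertoire summaries and clustering at 600 primary ligands
per allotype, differential calibration on 5,000 null peptides with the
exhaustive 924-split 6-vs-6 permutation set, pi0 recovery on 10,000 planted
p-values, and motif recovery at 2,000 primary ligands per allotype with the
full 25-network ensemble. The worked abundance-share example uses the three
shipped 20-row reference tables and reproduces their printed shares (52 %,
and two shares printing as 23 %) exactly.

## Known limitations

* The global permutation test cannot produce p-values below `1/(B + 1)`;
  truly enormous repertoire differences are reported at the floor.
* `pi0` from the histogram density at 1 is biased upward when alternatives
  have heavy tails near 1, and unstable below ~50 p-values (warned).
* Core alignment assumes a contiguous 9-mer register and no
  peptide-flanking-residue effects.
* The greedy identity clustering used for sequence weighting is
  order-dependent by construction (it follows the conventional logo
  pipeline); with thousands of cores the effect on frequencies is
  negligible.
* Reading publisher spreadsheets directly is out of scope: inputs are
  tab-separated text in a MaxQuant-like layout, plus FASTA and YAML.
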