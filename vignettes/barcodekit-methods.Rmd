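---
title: "Methods and design choices in barcodekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in barcodekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
```

barcodekit evaluates DNA-barcode reference libraries with the two method
families that dominate the field — distance-based (unsupervised)
identification and barcode-gap OTU picking, and character-based
(supervised) classification — on a common footing, so that markers and
methods can be compared on the same curated data. This vignette explains
the models, the semantic choices made where the published descriptions
are qualitative, the synthetic test bed, and the limits of what a green
test establishes.

## Curation

Barcode libraries are conventionally curated by (a) keeping only
standard-length barcodes — here, ungapped length strictly greater than
400 bp by default, counting neither gaps nor `N` — and (b) for
benchmarking, keeping only species with at least three individuals, and
restricting two-marker comparisons to the species present in both
markers. Headers carry a species label and an accession; since
repositories disagree on the layout, the parsing rule (`label_spec`) is
configurable, defaulting to `Species_name|ACCESSION`. Sequences are
uppercased on read and `U` is mapped to `T`.

## Genetic distances

All three models operate per pair under **pairwise deletion**: a site is
comparable only if both sequences carry a plain `A/C/G/T` there. Gaps,
`N` and IUPAC ambiguity codes are excluded entirely rather than
partially matched — the simplest defensible rule, and the convention of
the standard barcode tools. Complete deletion is deliberately not the
default because gapped *matK*-like alignments would lose most of their
sites.

* `simple` — p-distance, mismatches / comparable sites.
* `jc69` — d = −(3/4) ln(1 − 4p/3); domain p < 0.75, violations are
  *errors* ("saturation"), never silently stored.
* `k80` — d = −(1/2) ln(1 − 2P − Q) − (1/4) ln(1 − 2Q), with the
  transition proportion P (A↔G, C↔T) and transversion proportion Q
  estimated from the pair itself. A quoted "TS/TV = 2.0" setting in the
  tools this mirrors is a configuration echo; no assumed ratio enters
  the formula.

`distance_matrix()` is strict by default (an undefined pair aborts with
the pair named); lenient mode stores `NA` and excludes such pairs
downstream. Distance ties anywhere in the package use an absolute
epsilon of 1e-12 — float-safe, and well below one mismatch at any
realistic alignment length.

## Identification criteria

With a distance matrix and species labels, each record is treated as a
query against all others:

* **Best Match (BM).** All records tied (within epsilon) at the minimal
  distance decide: all conspecific → Correct; all allospecific →
  Incorrect; mixed → Ambiguous. A singleton species query is forced
  Incorrect.
* **Best Close Match (BCM).** BM plus a ceiling: if the nearest record
  lies beyond the threshold, the query is NoMatch. The threshold is
  either fixed (default 3 %, the field's customary screening value) or
  the 95th percentile of pooled intraspecific distances
  (`threshold = "percentile:95"`), computed with linear interpolation
  between order statistics (`stats::quantile` type 7).
* **All Species Barcodes (ASB).** Described only qualitatively in the
  literature ("utilizes information from all conspecifics", "requires at
  least two conspecific matches"), so the package pins the strictest
  consistent reading and documents it prominently: the query is
  **Correct** iff every conspecific ranks strictly ahead of every
  allospecific record *and* the farthest conspecific lies within the
  threshold; an allospecific tying the farthest conspecific (within
  epsilon) gives **Ambiguous**; an allospecific strictly inside the
  conspecific range gives **Incorrect**; no record within the threshold
  gives **NoMatch**. A query whose conspecifics respect the ordering but
  exceed the threshold is counted Incorrect (it fails the
  all-barcodes-within-threshold requirement). Queries with no
  conspecifics can never be Correct.

Species-level rollups are computed independently of each other: a
species is *Correct* if at least one of its sequences is Correct, and a
*TRUE SPECIES* if at least one sequence is Correct and none is Incorrect
or Ambiguous. NoMatch does **not** veto TRUE status by default (the
stricter reading is a flag), because the customary definition lists only
Incorrect/Ambiguous as vetoes.

## Barcode-gap partitioning

The partitioner scans a geometric series of prior maximal intraspecific
divergences (defaults P_min = 0.001 to P_max = 0.1 in 10 steps — the
usual web-tool settings). At each prior it sorts all pairwise distances,
scans successive gaps g_i = d_(i+1) − d_(i), and flags the first gap
that (a) reaches beyond the prior and (b) exceeds X times the local mean
gap, with X = 1.5 by default. Two details are the package's own, since
the original's windowing is not published:

* *Scan condition.* A gap counts once d_(i+1) ≥ prior — i.e. a gap
  straddling the prior is "beyond this limit". (The alternative,
  d_(i) ≥ prior, would skip the barcode gap whenever the prior lands
  inside it.)
* *Local scale w(i).* The mean gap over a sliding window of
  ⌈N/10⌉ ranked gaps on each side of i, capped at the data. Uniformly
  spaced distances therefore never contain a significant gap (every gap
  equals its local mean), and a pronounced jump dwarfs its
  neighbourhood. X is configurable for sensitivity analysis.

The detected threshold induces single-linkage groups (connected
components of the ≤-threshold graph); the procedure recurses within each
group on the restricted distances until nothing splits, stopping on
groups of fewer than 3 records, where gap detection is meaningless. The
per-prior histogram bin count (20) is diagnostic only and plays no role
in detection.

Across the prior series, the **initial partition** is selected as the
one whose group count equals the modal count, ties broken toward the
smaller prior. "The most relevant number of OTUs" is ambiguous in the
literature; modal-count selection is a stated interpretation: small
priors oversplit, large priors collapse everything, and the modal count
marks the stable plateau in between. Groups are tagged SINGLETON (one
record), TRUE (one species, found nowhere else), AMBIGUOUS (one species,
split across groups) or INCORRECT (multiple species).

## Featurization

* `encode_alignment()` — fixed per-column code A=1, C=2, G=3, T=4,
  gap/other = 0; constant columns are retained.
* `spectrum_features(k)` — counts of contiguous k-mers over
  `{A,C,G,T}`; gaps are stripped first, windows touching any other
  symbol are skipped.
* `gappy_features(k, g)` — counts of position tuples i₁ < … < i_k with
  span i_k − i₁ ≤ k−1+g spelling each word: a
  subsequence-with-bounded-span definition, pinned by brute-force
  enumeration oracles in the tests, chosen because it collapses exactly
  to the spectrum at g = 0.
* `mismatch_features(k, m)` — for each word, the number of contiguous
  k-mer instances within Hamming distance ≤ m, computed exactly via an
  inclusion–type position-operator expansion over the 4^k count array
  (cost grows with C(k, m), exponential in m as expected).

"Frequencies" are normalised per sequence by the number of counted
windows (relative frequencies; raw counts via `raw = TRUE`) — the
normalisation is not standardised in the tools this mirrors, so it is a
documented default. Feature order is lexicographic over `{A,C,G,T}^k`
and fixed across a dataset. Feature-space size is 4^k: k = 6 means 4096
columns, which is memory-hungry with gappy enumeration on large
libraries — the package imposes no limit but users should expect the
growth.

## Cross-validated classification

Folds are stratified: each class is shuffled (seeded) and dealt
round-robin starting at the least-loaded fold, so classes smaller than
the fold count spread evenly; every instance is tested exactly once per
repeat. Available families:

* *nearest-neighbor* — native exhaustive Euclidean search; prediction is
  the majority among nn neighbours (ties: smaller aggregate distance,
  then first-seen class); probabilities are neighbour class frequencies
  with no distance weighting, matching the customary default
  configuration.
* *tree-ensemble* — a native random forest (no tree package exists in
  the supported dependency stack): bootstrapped CART trees, Gini
  impurity, midpoint splits, `mtry = floor(sqrt(p))` random features per
  node, 100 trees by default, probabilities averaged over trees.
* *multinomial-logistic* — ridge-penalised multinomial logistic
  regression via glmnet (`alpha = 0`), default ridge 1e-8, mirroring the
  customary "Logistic with a ridge estimator" configuration.
* *margin-based* — a pluggable fit/predict-probability contract only.
  An SVM is deliberately not re-implemented: the published comparisons
  themselves could not run SMO at scale, and no SVM backend exists in
  the dependency stack.

Metrics: accuracy; the classification RMSE
√(Σᵢ Σ_c (p_ic − y_ic)² / NC) against one-hot truth (0 iff all mass on
the true class; 0.5 for uniform probabilities on a balanced binary
problem); per-class TPR = TP/(TP+FN) and FPR = FP/(TN+FP) (FPR is `NA`
on single-class input); and three species-level summaries, because the
customary "species %" row is never defined precisely: the percentage of
species with *any* correct prediction, with *all* predictions correct,
and with TPR exactly 1 (the "true positive species" statistic). All are
emitted; the mapping is an interpretation and flagged as such. A species
with a single sequence can never be predicted correctly under CV — its
class is absent from every training set it is tested against — so
singleton TPR is structurally 0.

## Classifier comparison

The corrected resampled paired t-test uses
t = d̄ / √((1/n + n₂/n₁) · var(d)) with df = n − 1 and the unbiased
sample variance; n₂/n₁ = 1/9 for 10-fold CV. The variance inflation is
the Nadeau–Bengio correction used by the standard experiment testers;
at ratio 0 the statistic reduces exactly to the classic paired t.
Degenerate inputs are explicit: var 0 with mean 0 gives t = 0 (not
significant); var 0 with nonzero mean is flagged infinite and reported
significant. `rank_classifiers()` reports mean ± SD and win/tie/loss
against a baseline at two-tailed 0.05, stably sorted by mean.

## The synthetic test bed

`generate_dataset()` emulates a curated library: one ancestor per
species mutated from a shared root, members mutated from their ancestor,
a fraction of species reduced to singletons, indels written as gap
columns (aligned output, no realignment — emulating markers whose
alignments carry scattered indels), missing data as `N`. Substitutions
are uniform (JC-like) so that distance-model tests have closed-form
expectations; a transition bias option (`tstv`, substitution is the
transition with probability R/(R+1)) supports K80-oriented checks.

One calibration deserves emphasis: `intra_divergence` and
`inter_divergence` are **expected pairwise p-distances** (within
species, and between species ancestors), not per-branch rates. Two
sequences mutated independently at per-site rate r from a common source
differ per site with probability 2r(1−r) + (2/3)r², so the generator
solves r = (3/4)(1 − √(1 − 4D/3)) for each target D. This makes the
stated world directly checkable ("mean intraspecific p-distance ≈
intra_divergence") and puts the default barcode gap where the defaults
say: intra 0.005 vs inter 0.08 with L = 600 yields a clean gap
(intraspecific distances ≲ 0.015, interspecific ≳ 0.05) in essentially
every seeded run. Defaults — 20 species × 4 members, 600 bp — are a
deliberately small but realistic curated-library shape: enough
conspecifics for every criterion to succeed, alignment length in the
range of a trimmed *rbcL*.

What the generator does **not** emulate: coalescent population
structure, rate variation among sites and lineages, codon structure,
paraphyly, misidentified reference labels, or alignment error. A green
planted-gap test therefore establishes the *correctness of the
machinery* (criteria, partitioning, featurization, CV bookkeeping), not
the field performance of any marker; the published benchmark numbers on
real libraries are inputs this package can reproduce only when given
those libraries.

## Numerical choices and degenerate inputs

* Distance ties and ASB/BM ranking: absolute epsilon 1e-12.
* Percentile thresholds: linear interpolation between order statistics.
* JC69/K80 domain violations: errors by default ("saturation"), `NA` in
  lenient mode.
* Sequences shorter than k after gap stripping: all-zero feature row
  plus a warning.
* Empty datasets: identification, partitioning and the workflow all
  error out before any stage runs.
* Seeds are explicit everywhere (fold assignment, bootstrap, generator);
  the full workflow is byte-identical across reruns with the same
  configuration.

## Known limitations

* The barcode-gap partitioner replicates the published *idea* (prior
  scan, relative gap width, recursive splitting), not the original C
  program's exact windowing and p-value machinery; group counts on real
  data can differ from the web tool's.
* The native random forest is compact and adequate for barcode-sized
  feature tables; it is not a tuned large-scale implementation.
* Multiple-sequence alignment is out of scope: aligned input is taken
  as given.
* The percentile-threshold BCM ties the threshold to the library at
  hand; comparing thresholds across libraries therefore compares
  different operating points.
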