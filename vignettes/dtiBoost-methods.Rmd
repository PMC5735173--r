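---
title: "dtiBoost: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dtiBoost: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why the
open design decisions were settled the way they were. The README shows a
worked example; here we document the model, the tunable parameters, the
synthetic-data generator, and the numerical conventions a maintainer (or a
reviewer of results produced with this package) needs to know.

## The prediction problem

A drug–target screen is modeled as a bipartite graph $G = (D \cup T, E)$
with disjoint id namespaces for drugs and protein targets. The complete
pair set $D \times T$ is labeled $+1$ on edges and $-1$ elsewhere — a
*closed-world* assumption: a non-edge is treated as a true negative even
though some non-edges are merely undiscovered interactions. The package
does not soften this at dataset level (silently dropping or down-weighting
non-edges would corrupt the imbalance statistics that drive balancing and
evaluation); instead the caveat is exploited *after* training, when
`rankNewInteractions()` surfaces the highest-scoring negative pairs as
candidate new interactions.

With $|D| \cdot |T|$ pairs and typically few known edges, the class
imbalance is severe: rebuilding the four classic benchmark geometries from
their published sizes gives majority:minority ratios of 14.6, 28.02, 32.36
and 99.98 (these are recomputed, not asserted, by both the test suite and
`scripts/acceptance.R`).

## Feature encoders

All target-side encoders map a variable-length protein (length $L$) to a
fixed-length vector, which is what makes pair-level classification
possible.

**Normalized PSSM.** The PSI-BLAST profile is an $L \times 20$ matrix of
integer log-odds scores in PSI-BLAST column order
`A R N D C Q E G H I L K M F P S T W Y V`. Two squashings into $[0,1]$ are
offered: element-wise logistic $1/(1+e^{-m})$ (default) and global min–max.
The source lineage for this normalization only states "similar to" earlier
work, so the choice is exposed as a parameter rather than hard-coded; the
logistic form is the default because it is the standard treatment of
log-odds scores and has no degenerate case (min–max fails on a constant
matrix, and the package makes that an error rather than returning NaNs).

**Bigrams.** For a profile matrix $M$ with $d$ columns,
$\mathrm{bigram}(k,l) = \frac{1}{L}\sum_{i=1}^{L-1} M_{i,k} M_{i+1,l}$,
giving $d^2$ values. Note the $1/L$ prefactor over an $(L-1)$-term sum:
that is the printed definition and it is implemented verbatim, so values
are reproducible against other implementations of the same formulas. The
same applies to the auto-covariances below ($1/L$ over $L-k$ terms).

**Torsion angles.** The four backbone angles (phi, psi, theta, tau — SPD
file column order, which the package uses everywhere; degrees in files)
are converted to radians and expanded to the $L \times 8$ matrix
$[\sin \mid \cos]$. The phrase "sign and cosine" in the literature this
follows is read as *sine* and cosine: taking the sign would collapse each
angle to $\pm 1$ and make the downstream compositions degenerate. Using
both sine and cosine makes every angle feature invariant under adding full
turns, which the tests assert exactly.

**Compositions.** Secondary-structure label frequencies over
$\{C, E, H\}$ (coil, strand, helix — fixed order, summing to 1), the mean
accessible surface area (Å$^2$), and the 8 column means of the torsion
matrix.

**Auto-covariances.**
$\mathrm{AC}(k,j) = \frac{1}{L}\sum_{i=1}^{L-k} M_{i,j} M_{i+k,j}$ for
lags $k = 1 \dots \mathrm{DF}$. The distance factor defaults to
$\mathrm{DF} = 10$; proteins must therefore be longer than 10 residues and
shorter inputs fail fast with an explicit error rather than zero-padding.

**Flatten orders** are frozen and named in every output header so feature
indices are bit-for-bit reproducible: bigrams row-major
(`pssm_bg_<k>_<l>`, k outer), auto-covariances column-outer/lag-inner
(`ta_ac_<k>_<j>` at position $(j-1)\mathrm{DF} + k$).

**Groups.** A = PSSM bigram (400); B = compositions (3 + 1 + 8);
C = auto-covariances (80 + 30); D = torsion/probability bigrams (64 + 9).
B, C, D are only ever added on top of A, so with the 881-bit drug
fingerprint the pair widths are 1281 / 1293 / 1403 / 1476. Fingerprints
are inputs, never computed: the optional `smilesToFingerprint()` adapter
(rcdk-backed) exists for convenience, but parity with any particular
fingerprinting toolchain is deliberately not promised, and the core
package builds and tests without it.

## Balancing

Both samplers operate on *training data only* — `crossValidate()` applies
them inside each fold, and an instrumented-sampler test asserts that no
test row is ever visible to the sampler.

* **RUS** keeps every minority row and draws
  $\min(n_{maj}, \lceil r \cdot n_{min}\rceil)$ majority rows uniformly
  without replacement ($r$ = `targetRatio`, default 1).
* **CUS** first partitions the majority rows with k-means (Euclidean,
  Hartigan–Wong with 10 random restarts, 300-iteration cap, seeded;
  these settings are unstated in the method's source and were fixed once
  at standard values), then draws
  $\min(n_{maj}, \lceil h \cdot r \cdot n_{min}\rceil)$ rows across
  clusters. Two semantics of the pseudo-code were genuinely open and both
  are implemented behind `allocation`: proportional-to-cluster-size with
  largest-remainder rounding (default — the literal reading of
  "represent the entire majority class"), or equal counts per cluster.
  Every non-empty cluster contributes at least one row whenever the draw
  is at least the cluster count. The under-sampling control $h$ is read
  as a multiplier on the *total* draw (the alternative per-cluster
  fraction reading is equivalent under proportional allocation).
  `k` defaults to 23, the best value reported from a 5–30 sweep in the
  method's source.

Minority rows are never touched, outputs are always row subsets of the
input (no synthesis), and a fixed seed gives byte-identical output.

## Boosting

Discrete AdaBoost exactly as classically defined: uniform $D_1$; per
round, fit the weak learner on $(X, y, D_t)$, compute
$\varepsilon_t = \sum_i D_t(i)\,[h_t(x_i) \ne y_i]$,
$\alpha_t = \tfrac12 \ln((1-\varepsilon_t)/\varepsilon_t)$, re-weight and
renormalize. Stopping rules: $\varepsilon_t = 0$ retains the stage with
$\alpha$ capped at $\tfrac12\ln((1-10^{-10})/10^{-10})$ and stops;
$\varepsilon_t \ge 0.5$ discards the stage and stops; an ensemble with no
retained stage is an error. The number of rounds $T$ is not stated in the
method's source; it is exposed (`nRounds`) with default 100 for
`adaBoost()` and 20 in the pipeline configuration.

The weak learner is a depth-limited decision tree with instance weights
and Gini splits, behind a two-function contract (`fit(X, y, w)`,
`predict(model, X)`). The default backend is the package's own vectorized
CART (`giniTreeLearner()`): an exhaustive per-feature scan over sorted
distinct-value boundaries scoring weighted Gini decrease, with
deterministic tie-breaking (lowest feature index, then lowest threshold).
An rpart-backed learner with identical semantics (`rpartLearner()`) is
provided and the tests check that the two agree on random stump problems;
the built-in tree is the default because refitting through a formula
interface on 1476-column matrices spends nearly all its time in
`model.frame` bookkeeping rather than splitting. Named presets
(`adaBoostPreset()`) carry the published per-network tree controls,
including a minimum-split of 1 in one row, stored as printed.

**Why the pipeline default is stumps (`maxDepth = 1`).** After
under-sampling, training sets are small and balanced; a tree of depth
$\ge 2$ routinely reaches zero weighted training error in round 1, and
the zero-error stopping rule then produces a single-stage ensemble whose
scores are two-valued — a correct classifier but a useless *ranker*, and
auROC/auPR are ranking metrics. Depth-1 stumps cannot separate such data
in one round, so boosting accumulates all $T$ stages and
`predictScore()` — the monotone map $(g/\sum\alpha + 1)/2$ of the margin
into $[0,1]$ — becomes fine-grained.

## Evaluation

Threshold metrics implement the standard confusion-matrix formulas;
degenerate denominators (no positive predictions, an MCC factor of zero)
return 0 with a warning so cross-validation averages stay finite. The ROC
curve groups tied scores into single threshold steps and integrates by
trapezoid, making the area identical to the Mann–Whitney U statistic
(asserted against an exhaustive pairwise oracle). The PR curve integrates
step-wise, $\sum_i (R_i - R_{i-1}) P_i$, with *no* interpolation — linear
PR interpolation is known to be optimistic — so an uninformative ranking
scores the positive prevalence.

Cross-validation is stratified (per-class round-robin after a shuffle, so
fold prevalences match the global one within one sample), repeated
(default 5 × 5), and derives every random decision — folds, sampler draws,
k-means, tree seeds — from one master seed. Single-point metrics use a
score cut-off of 0.5 by default, exposed as `threshold`.

## The synthetic-fixture generator

The generator emulates the *formats and distributional shape* of the four
input kinds — PSI-BLAST ASCII PSSMs (integer scores uniform on
$[-10, 10]$; the 40-column dialect, so parsers prove they keep only the
first 20 numeric columns), SPIDER2 SPD files (angles uniform on
$[-180, 180]$°, Dirichlet-like probability rows, secondary-structure
label = argmax of its row, ASA uniform on $[20, 200]$ Å$^2$), random
fingerprints (background bit density 0.1), and interaction lists at a
configurable edge density. Protein lengths start at 12 so the
auto-covariance precondition always holds. Generation is byte-identical
under a fixed seed.

Signal is planted at the *pair* level, because labels attach to pairs: an
"active" subset of drugs (a 30-bit fingerprint block at high density) and
of targets (up-shifted PSSM columns, helix-biased probabilities) is sized
so the active × active block covers about `density` of all pairs, and
edges are drawn without replacement with weight $e^{s}$ on active–active
pairs ($s$ = `signalStrength`). At $s = 0$ edges are uniform and no
feature shift is planted — the null pipeline. For the presets $s = 10$:
the weighted draw only becomes effectively deterministic on the planted
block once $e^{s}$ dwarfs the number of competing pairs (by the
exponential-race argument, the expected number of off-block edges is
$\approx n_{pairs} H_{|E|} e^{-s}$, about 0.03 at $s = 10$ for the tiny
preset versus ~2 at $s = 6$) — below that, planting noise caps even the
Bayes-optimal ranking and a "strong-signal" recovery check would not be
measuring the pipeline.

What the generator does *not* emulate: real PSSM column correlations,
secondary-structure prediction accuracy, chemical similarity structure
among fingerprints, or hub-like degree distributions of real interaction
networks. A passing recovery test therefore demonstrates that the
machinery — features, balancing, boosting, evaluation — recovers a planted
entity-level association through the full stack; it says nothing about
predictive accuracy on real screens, which the package makes no claim to
reproduce without the real inputs.

Problem sizes were chosen once for the desk-scale study conditions: the
`tiny` preset (20 × 12 pairs, density 0.1) for recovery and null
calibration under 5 × 5 cross-validation, `nuclear_receptor_like`
(54 × 26, 90 edges — ratio 14.6) and `enzyme_like` (ratio ≈ 100) for the
imbalance regimes.

## Numerical conventions, in one place

* Residues are 1-based in files and in R objects; fingerprint bits keep
  their 0-based PubChem indices in column names (`fp_0` … `fp_880`).
* Probability rows off by more than $10^{-2}$ from sum 1 are parse
  errors; smaller deviations are renormalized (object validity then
  enforces $10^{-3}$).
* Oracle-equivalence tests (bigrams, auto-covariances, curve areas vs.
  brute force) use tolerance $10^{-12}$; file round-trips compare at the
  written decimal precision ($10^{-4}$ for angles/probabilities).
* Ties: prediction margins of exactly 0 classify as $+1$; candidate
  ranking breaks score ties lexicographically by (drug id, target id);
  tree splits break Gini ties toward the lowest feature index and
  threshold.
* Duplicate interaction rows collapse with a warning; duplicate edges,
  mismatched PSSM/SPD sequences, unknown ids, single-class inputs and
  too-short proteins are errors, never silent fixes.

## Known limitations

* Closed-world negatives mislabel undiscovered interactions by
  construction; candidate ranking mitigates but does not remove this.
* Fingerprints are trusted as given; no SMILES standardization or
  fingerprint recomputation is attempted in core.
* The published benchmark performance figures require the original gold
  datasets plus PSI-BLAST and SPIDER2 runs per protein; nothing in this
  package reproduces those numbers, and the acceptance outputs are
  limited to quantities recomputable from published counts and from
  seeded synthetic data.
* rpart-backed trees clamp depths above 30 (the backend's hard limit);
  the built-in learner honors any depth but under-sampled training sets
  rarely support depth beyond a few levels.
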