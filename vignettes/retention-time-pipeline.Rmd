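---
title: "Fingerprint-based retention time prediction, projection and annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprint-based retention time prediction, projection and annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In untargeted LC–MS metabolomics, an observed ion's accurate mass rarely
identifies a molecule uniquely: many structures share a formula mass within
a few ppm. Chromatographic retention time (RT) is an orthogonal evidence
layer, but a measured RT is only meaningful for the chromatographic method
(CM) that produced it, and no laboratory can measure standards for every
candidate structure. A quantitative structure–retention relationship (QSRR)
model closes that gap: it predicts RT from molecular structure, and a
projection function transfers those predictions onto another laboratory's
method, where they can rank and filter mass-search candidates.

`chromrt` implements this pipeline end to end:

1. **Fingerprints** — circular (Morgan-type) binary fingerprints, the open
   equivalent of extended connectivity fingerprints (ECFP), from SDF or
   SMILES structures.
2. **Deep RT regression** — a fully connected network mapping fingerprints
   to RT in seconds.
3. **Naive k-NN baseline** — the heuristic "similar molecules elute
   together", used as a statistical control with a similarity-stratified
   comparison.
4. **Projection** — a degree-4 polynomial least-squares map from predicted
   RT onto an external CM's time scale, fitted on a few dozen identified
   anchor molecules.
5. **Annotation** — accurate-mass candidate search (10 ppm, \[M+H\]⁺ /
   \[M−H\]⁻), ranking by relative RT error, ROC-based error-threshold
   selection, filtering and top-k ranking reports.
6. **Synthetic data** — a seeded generator producing libraries and external
   methods with the statistical structure the analyses above assume, so the
   whole pipeline is exercised and validated without external data.

## The deep model

The regressor is a standard scalar-regression feed-forward network: four
fully connected hidden layers of 1000, 500, 200 and 100 relu units, a
single linear output unit, mean-squared-error loss with an L2 weight
penalty of $\lambda = 10^{-4}$, Adam with learning rate 0.01, 20 epochs at
batch size 35, and a 75/25 random train/validation split. These are the
`dlm_config()` defaults. Binary fingerprint inputs are used unscaled and
the target is trained in raw seconds; there is no early stopping — training
always runs the full epoch schedule.

Adam moment parameters beyond the learning rate use the customary defaults
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$). Weights are
He-initialised (variance $2/\text{fan-in}$), the right scaling for relu
layers on sparse binary inputs. Initialisation and per-epoch shuffling are
drawn from R's RNG under `config$seed` and the update loop is
single-threaded compiled code, so a fixed seed reproduces a fit bit for
bit.

Per-molecule errors are
$\mathrm{rel} = 100\,|\hat t - t|/t$ and $\mathrm{abs} = |\hat t - t|$,
with the *experimental* RT in the denominator — that makes errors
comparable across molecules of different RT. Non-retained molecules
(eluting before the void gap, below 300 s by default — a gradient held at
initial conditions for a few minutes puts the first retained peaks well
after that) can be excluded from summaries, which is the standard practice:
a model that misses the retained/non-retained gap inflates the mean far
more than the median. `detect_nonretained_cutoff()` offers a data-driven
largest-gap alternative when the gradient program is unknown.

## The naive baseline and its statistics

`knn_median_rt()` predicts a molecule's RT as the median RT of its $k = 3$
Tanimoto-nearest training molecules, on the same fingerprints the deep
model sees — so both approaches receive identical structural information.
Similarity ties at the $k$-th neighbour resolve by training `mol_id` order:
reproducibility over arbitrariness.

The comparison between the two is run within similarity strata: the set of
validation molecules having at least one training molecule at ≥ 95, 90,
80, 70 and 50 % Tanimoto similarity (nested by construction). Two test
flavours are used, matching how the groups are formed:

* **Paired arms** (same molecules, two predictors):
  `compare_paired_errors()` runs a paired Wilcoxon signed-rank test for
  location and an Ansari–Bradley test for scale. The Ansari–Bradley test is
  applied in its standard two-sample form to the two error samples; a
  "paired" variant of it has no standard definition.
* **Unequal groups** (different molecules, e.g. with versus without a
  similar training neighbour): `subsample_bonferroni_test()` repeatedly
  (1000×) subsamples the larger group to the smaller group's size, runs a
  two-sample Wilcoxon rank-sum test each time, multiplies each P value by
  the repetition count (Bonferroni), and reports the smallest level of
  {0.05, 0.01, 0.001, 0.0001} under which at least 95 % of corrected P
  values fall, else `ns`. With equal group sizes every repetition is the
  same full test; the construction is deliberately conservative, which the
  null-calibration test confirms.

IQRs are reported as Q3 − Q1 with R's default linear-interpolation
quantiles.

## Projection between methods

Reverse-phase methods broadly conserve elution order, so predicted RT on
the reference scale maps onto an external method through a smooth,
monotone-ish function. `fit_projection()` regresses the target method's
experimental RT on an orthogonal-polynomial basis (`stats::poly`) of the
predicted RT, degree 4 by default — least squares on a numerically stable
basis. The regression direction is experimental ~ poly(predicted): that is
the direction needed to carry predictions onto the target scale. An
optional iteratively reweighted (Tukey bisquare) mode damps aberrant
predictions among the anchors; it is off by default because plain least
squares is the baseline behaviour being characterised. No monotonicity
constraint is imposed; values outside the anchor range are evaluated but
flagged as extrapolations rather than clamped.

Anchors are drawn uniformly at random without replacement (50 by default)
and the seed is recorded in the fitted object, because different anchor
draws genuinely give different projections — the serialised JSON
(`write_projection_json()`) carries degree, power-basis coefficients,
anchor ids and seed so any fit can be audited and re-evaluated.

## Annotation, ROC and ranking

`candidate_search()` retrieves every library molecule whose \[M+H\]⁺ or
\[M−H\]⁻ theoretical m/z (proton mass 1.007276 Da, singly charged only)
matches the observed ion within 10 ppm, with the deviation taken against
the theoretical m/z — the database-search convention. Candidates are ranked
by ascending relative RT error (ties by `mol_id`).

The filtering threshold is chosen by a ROC sweep over relative RT error
from 0 to 100 % in 2.5 % steps. At threshold $t$, a candidate with error
$\le t$ is called positive; TP/FN count correct identities below/above the
threshold, FP/TN incorrect candidates below/above it, and
$\mathrm{TPR} = \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$,
$\mathrm{FPR} = \mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$. Boundary cases
count as "under" ($\le$), at both grid endpoints. The AUC is the
trapezoidal area under the (FPR, TPR) points — on grid-aligned data this
equals the tie-corrected rank statistic exactly, which the tests use as an
independent oracle. `select_threshold()` maximises Youden's
$J = \mathrm{TPR} - \mathrm{FPR}$, ties resolving to the smallest
threshold. Ranking reports condition on cases with more than 1, 2 or 3
candidates, as appropriate for a report about *distinguishing* candidates;
cases whose true identity fell outside the mass window count in the
denominators but can never hit a rank. Stereoisomer-like candidates that
collapse to one fingerprint are not deduplicated.

## What the generator emulates — and what it does not

`gen_library()` produces the structure the analyses above need, and
nothing hidden beyond it:

* **Similarity structure** — 60 cluster prototypes (bit density 0.1,
  1024 bits) with per-member bit flips at rate 0.012, plus near-duplicate
  "homologue" variants (rate 0.18, per-event flip rate uniform in
  0.001–0.008). The variants populate the 95 and 90 % similarity strata;
  cluster mates populate 70–85 %. Nearly every molecule has a ≥ 50 %
  neighbour, mirroring real libraries.
* **Latent RT map** — a sparse linear map of the bits (100 nonzero
  Gaussian weights), squashed through a probit onto 360–1260 s (a mild,
  monotone nonlinearity: learnable by the network, approximable by k-NN).
  A pure `linear` mode exists for exact noise-floor analyses.
* **Replicate noise** — sd 18 s, a typical median replicate variability
  for a long reverse-phase gradient, and the natural lower bound on
  achievable prediction error.
* **Family-shared idiosyncratic RT** — each family (a molecule and its
  near-duplicates) carries a shared offset with sd 90 s that fingerprints
  cannot explain, the scale of real isomer-family RT variability. This is
  what makes molecules with a near-twin in the training set *genuinely*
  easier to predict, the effect the similarity-impact analysis must
  detect; the offset is learnable only when a family member was seen in
  training.
* **Non-retained molecules** — the 8 % of molecules with the weakest
  latent retention scores elute uniformly over 20–100 s, with an empty
  void gap up to 310 s (a gradient held at initial conditions). The
  selection is tie-inclusive on the latent score so identical fingerprints
  never straddle the boundary.
* **Masses** — uniform over 80–600 Da with 20 % of molecules placed within
  5 ppm of an earlier molecule, so accurate-mass search yields
  multi-candidate sets and the ranking reports have populated cells.

External methods (`gen_ecm()`) are strictly monotone warps of the
noise-free reference RT — a scaled cumulative-beta warp by default, with a
dead-time offset (5 % of the method length, since no LC method elutes at
0 s) and measurement noise of 2 % of the method length. Short (< 300 s)
and long (≥ 1500 s) regimes come from `method_length_s`. The true warp is
returned so recovery tests can compare against it. Query ions
(`gen_query_ions()`) add sub-ppm mass noise and record the generating
molecule as truth.

What the generator does **not** emulate: real chemistry (fingerprints are
sampled, not computed from structures), heteroscedastic RT noise, peak
shape and co-elution, adducts beyond \[M+H\]⁺/\[M−H\]⁻, isotope patterns,
retained/non-retained misclassification, or the heavy-tailed error
distribution of real QSRR models on out-of-domain chemistry. Passing tests
on this generator therefore demonstrate that the *procedures* behave as
designed under their stated assumptions — not that any particular accuracy
level will be met on a real library.

## Numerical choices and degenerate inputs

* Tanimoto similarity on two all-zero fingerprints is undefined and raises
  an error rather than returning a value.
* ppm matching is boundary-inclusive; the window widens monotonically with
  the tolerance.
* `evaluate_errors()` refuses non-positive experimental RTs (the relative
  error would be undefined).
* Polynomial fitting requires at least degree + 1 *distinct* predicted-RT
  values and raises an explicit rank-deficiency error otherwise.
* All-tied paired error arms make the Wilcoxon signed-rank test undefined;
  the report flags this instead of fabricating a P value.
* Empty groups in the similarity-impact analysis produce a "not run"
  report, never a test on an empty arm.
* Power-basis coefficients for the JSON serialisation are recovered by
  interpolating the orthogonal-basis fit at degree + 1 points — exact for
  polynomials, numerically stable over the anchor range.

## Problem sizes used by the test suite

The validation suite scales the study design down to desk size, chosen
once as follows: model recovery uses 5000 molecules (enough for the
network to reach the 18 s noise floor's neighbourhood within 2.5×); the
stratified naive-versus-deep comparison uses 10 000 molecules, a power
choice — the location difference between the arms is about two percentage
points of relative error, and the 1000-fold Bonferroni correction demands
raw P values below 5 × 10⁻⁵, which needs strata of roughly the sizes this
yields (about 600/2300/2500 at the 90/80/50 % thresholds, a few times
smaller than the study-scale strata the procedure was designed around).
Oracle-equivalence checks (k-NN versus exhaustive search, trapezoid AUC
versus rank statistic) run at a few hundred molecules where brute force is
cheap. The acceptance script runs the full pipeline at 4000 molecules.

## Known limitations

* The fingerprint implementation hashes atom environments from SDF
  connection tables with a valence-heuristic implicit-hydrogen count and
  no ring-membership or aromaticity flag in the atom invariant; it is
  deterministic and ECFP-like but will not reproduce any specific
  commercial fingerprint bit for bit.
* The regressor has no early stopping, no hyperparameter search and no
  ensembling by design; it characterises a fixed, published-style
  configuration rather than the best attainable model.
* RT-error filtering is known to be fragile: the selected threshold varies
  with the anchor draw. The projection object records its seed precisely
  so that this variability is visible and reproducible rather than hidden.
* Projections assume conserved elution order; they are inappropriate for
  pairs of methods (e.g. different HILIC systems) where that assumption
  fails.
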