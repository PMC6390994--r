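---
title: "Hierarchical patterns of joint involvement with sparse multilayer NMF"
author: "jointNMF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical patterns of joint involvement with sparse multilayer NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointNMF)
```

## The problem

Childhood arthritis (JIA) is recorded at every clinic visit on a standard
homunculus of assessable joints — 71 sites in the default catalog shipped
here: the cervical spine plus 35 bilateral joint types (TMJs,
sternoclavicular joints, shoulders, elbows, wrists, finger MCPs, thumb IPs,
finger PIPs and DIPs, sacroiliac joints, hips, knees, ankles, subtalar and
midfoot joints, MTPs and toe IPs). A patient-by-joint binary matrix of this
kind is too wide, and cohorts too small, for joint-by-joint supervised
testing. The package instead learns a small number of *patterns* of joint
involvement with an unsupervised, hierarchical, sparse factorization, and
then asks whether those patterns — and how tightly a patient's joints align
with them — predict the longitudinal course of disease.

The pipeline has five stages, each its own module surface:

1. **Co-involvement statistics** — involvement frequencies $P(x)$, pairwise
   co-involvement $P(x,y)$, conditional co-involvement $P(y\mid x)$, a
   same-side versus opposite-side skew statistic per joint-type pair, and a
   permutation test of left/right mirror symmetry.
2. **Sparse NMF** — $X \approx WH$ with $W, H \ge 0$, minimizing
   $\lVert X - WH\rVert_F^2 + \alpha \lVert W\rVert_1$ by multiplicative
   updates, followed by hard sparsification of $W$.
3. **Model selection** — bi-cross-validation (BiCV) over rank and $\alpha$
   grids with one-standard-error selection rules.
4. **Multilayer composition** — a second NMF on the (rescaled) layer-1
   scores; the composite loading $C = W_1^{s} W_2^{s}$ maps high-level
   factors back to joints; each factor's *key joints* are its positive
   composite entries; patients are assigned to their highest-scoring factor
   and classified by *degree of localization*.
5. **Longitudinal analyses** — per-visit re-scoring through the frozen
   model, baseline-group-to-destination transition matrices with a
   permutation null, and time-to-zero-joints survival models (Cox
   proportional hazards, log-rank, Kaplan–Meier).

## The factor model

With joints in rows and patients in columns, `fitNMF()` runs the standard
multiplicative updates for the penalized Frobenius objective,

$$W \leftarrow W \circ \frac{XH^\top}{W H H^\top + \alpha/2}, \qquad
  H \leftarrow H \circ \frac{W^\top X}{W^\top W H},$$

which never increase the objective (asserted per-iteration in the test
suite over random instances). The L1 penalty applies to $W$ only: sparse
*joint patterns* are the goal, while patient scores stay dense so that
group assignment and projection remain informative. Initialization is a
deterministic NNDSVD variant (zeros backfilled with the matrix mean so the
multiplicative updates can leave them); optional random restarts keep the
best final objective, ties broken by start order. After the updates, the
scores are re-solved exactly by per-patient non-negative least squares with
$W$ frozen, and each $W$ column is rescaled to unit maximum — loadings then
read as 0–100% contributions — with the compensation folded into $H$ and
the removed scales stored.

Two numerical choices matter downstream:

* **Exact NNLS for scores.** Anywhere scores are (re)estimated with frozen
  loadings — after fitting, after sparsification, and in `projectScores()`
  — an active-set NNLS solve per patient is used instead of iterating the
  multiplicative H-update. The multiplicative update approaches zeros only
  geometrically, and its slow tail would otherwise leave projection of the
  training cohort ~3% away from the stored scores; with the exact solver
  the two agree to machine precision, and all-zero patients get exactly
  zero scores.
* **Sparsification** (`sparsify()`) zeroes $W$ entries below a fraction
  (default 0.1) of their column maximum and re-solves $H$; the per-factor
  Spearman correlation between pre- and post-sparsification scores is
  stored so the user can confirm patient ordering survived. A threshold
  that would empty a factor raises an error suggesting a lower value.

## Bi-cross-validation

`bicv()` partitions rows and columns independently into $f$ folds
(default 3) per replicate. For each of the $f^2$ held-out blocks $A$ the
complementary blocks give the Owen–Perry prediction
$\hat A = B\,D^{+}C$, with $D^{+}$ the pseudo-inverse of the rank-$k$ fit
of the training block $D$ — so held-out entries are never touched by the
fit that predicts them. Every entry is held out exactly once per
replicate, and the per-replicate $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$
pools all entries. `q2()` also offers a squared-correlation variant
(`method = "corr"`) since "reconstruction accuracy" is sometimes reported
that way; the PRESS form is the default.

`selectRank()` applies a parsimony rule: the smallest rank whose mean
$Q^2$ is within one standard error of the best. `selectAlpha()` mirrors
it: the largest penalty within one standard error of the unpenalized mean,
i.e. the sparsest model that costs nothing measurable in held-out
accuracy. These one-SE rules are this package's policy; published analyses
of the 71-joint homunculus fixed 19 low-level and 7 high-level factors,
and those are the shipped defaults for homunculus-shaped data
(`fitMultilayer(k1 = 19, k2 = 7)`). The default of 50–200 replicates is
an interactive compromise; the reference analyses used 2,000, available
via the `replicates` argument.

## Multilayer composition and key joints

Layer 2 factorizes the layer-1 score matrix after each score row is
rescaled to unit maximum. The row scales are stored in the model and
re-applied verbatim when external cohorts are projected
(`projectMultilayer()`), so validation data are scored exactly as the
discovery data were. The composite loading $C = W_1^{s} W_2^{s}$ is
column-normalized and then sparsified with the same relative-threshold
rule as the layers. The key joints of a high-level factor are the strictly
positive entries of its sparsified composite column. Sparsifying the
composite itself is a deliberate reading of "key joints have nonzero
contributions": without it, the product of two *just-above-threshold*
loadings — each individually too small to matter — can deposit an
arbitrarily small stray entry in $C$ and inflate a pattern's key set.

Patients are assigned to their highest-scoring high-level factor
(`assignGroups()`); exact ties are flagged and broken towards the lowest
factor index, and all-zero score vectors go to a reserved `"unscored"`
group rather than being dropped. Group–factor overlap is tested by
normalizing scores patient-wise to the patient's maximum, z-scoring
factor-wise, and applying one-sided z-tests with Benjamini–Hochberg
correction (FDR < 0.1). Group–label (e.g. ILAR subtype) association uses
the chi-squared contingency test without continuity correction, flagging
cells whose adjusted standardized residual is at least 1.96.

## Degree of localization

For each patient, the fraction of active joints that are key joints of
their assigned pattern determines the category: **localized** when the
fraction is ≥ 90%, **partially localized** in [60%, 90%), **extended**
below 60%. The comparisons are made in integer arithmetic
($10\,n_{key} \ge 9\,n_{active}$, $10\,n_{key} \ge 6\,n_{active}$), so
boundary fractions like 9/10 and 3/5 classify exactly with no binary
floating-point drift. The thresholds are configuration constants taken
from the published analysis; this package does not re-derive them.
`thresholdSweep()` reports, for any threshold grid, the proportion of
patients at or above each threshold with bootstrap standard errors
(default 2,000 resamples).

## Longitudinal analyses

`scoreVisits()` projects every non-missing visit through the frozen model;
a visit with no active joints short-circuits to the absorbing state
`ZERO`, and unassessed visits are `MISSING` (missingness is encoded by
absence throughout the I/O layer and is never imputed).
`transitions()` uses reach-any-visit semantics: a patient counts once per
destination state reached at any follow-up visit, per baseline stratum;
the denominator excludes patients with no observed follow-up. The null
distribution permutes baseline stratum labels across patients, keeping
each whole follow-up trajectory attached to its patient so within-patient
correlation is preserved; Holm–Bonferroni adjustment and a 0.05 level flag
enriched cells (2,000 permutations by default). A per-visit Markov
chain was considered and rejected: the reported quantity is
baseline-group × destination, not a chained transition kernel.

`timeToZero()` is first-passage: the event time is the month of the first
all-zero visit, and later flares do not undo the event; patients never
reaching zero are censored at their last observed visit, and patients with
no follow-up are excluded with a warning. Cox models, log-rank tests and
Kaplan–Meier curves are computed by the survival package behind thin
validated interfaces (`fitCox()`, `logrank()`, `kmCurve()`): Efron tie
handling by default (the visit grid creates heavy ties; Breslow by
argument), Wald intervals per level, the partial-likelihood-ratio global
test, and $R^2 = 1 - \exp(-\mathrm{LR}/n)$ (the Cox–Snell form, chosen
because published values do not name a variant). Monotone-likelihood
warnings are captured and reported in the fit's `diagnostics` rather than
silenced.

## The synthetic cohort generator

No cohort of this kind is publicly deposited, so `makePlantedModel()` /
`simulateBaseline()` / `simulateCourse()` generate cohorts with known
ground truth; they are first-class, tested code, and every other module's
recovery properties are exercised against them.

The planted model draws `k1` disjoint bilateral joint-type pairs as
low-level supports and partitions them into `k2` high-level patterns.
Per patient: a pattern (uniform weights by default), a target localization
category from the mixture, a random subset of the pattern's key pairs
(each pair kept with probability 0.7; the contralateral partner
co-activated with probability 0.8, reflecting the predominantly symmetric
involvement of JIA), then symmetric per-joint noise flips (default rate
0.02), and finally an adjustment of the *number* of active non-key joints
into the target category's band. Design points worth stating explicitly:

* **Noise precedes the band adjustment.** Applying noise after the band
  adjustment would shift roughly half the cohort out of its intended
  category (about 1.4 expected stray joints against a median of ~5 active
  joints), so the generator's realized localization mixture would not be
  the one asked for, and the ground-truth category would disagree with the
  recomputed degree of localization. With noise inside the loop, the
  realized mixture equals the target exactly and the closed-loop identity
  holds by construction.
* **Non-key additions are mixed-membership.** Nonlocalized patients draw
  their extra joints as whole bilateral pairs from *other* patterns' key
  sets (uniform background only as a fallback), emulating patients who
  genuinely match several patterns. Uniform random additions would instead
  create a diffuse background whose chance correlations with factor scores
  are indistinguishable from weak real loadings at realistic cohort sizes.
* **The planted pattern stays dominant.** Extended patients receive
  strictly fewer non-key than key joints. The assigned group is by
  definition the argmax pattern, so a "planted group" that were not the
  patient's dominant pattern would be meaningless as ground truth.
* **Disease course** resolves each active joint independently per visit
  with a (pattern, category)-specific hazard — defaults 0.45 / 0.30 / 0.20
  per visit for localized / partial / extended, a deliberately monotone
  ordering. This is the simplest mechanism that yields category-dependent
  time-to-zero with a known direction; no claim is made that it matches
  real JIA dynamics. Optional flares and dropout are off by default.
* The default localization mixture (0.561, 0.194, 0.245) mirrors the
  published discovery-cohort split (359/124/157 of 640 patients).

What the generator does **not** emulate: per-joint involvement frequency
gradients along the body axis, treatment effects, ILAR-subtype-specific
patterns, or severity grades. Tests passing on these cohorts demonstrate
that the pipeline recovers the structure it is designed for at realistic
size and noise; they do not certify performance on any specific clinical
registry.

## Problem sizes used by the tests

The test-suite and acceptance-script simulations use discovery-shaped
cohorts of 600 patients on the 71-joint catalog (19 + 7 factors), toy
cohorts of 80–400 patients on an 8-pair catalog (6 + 3 factors), BiCV with
50 replicates on 60×60 planted matrices, 100–200 replicate null
calibrations, and 400–1,000 simulation Cox-coverage runs — sizes chosen so
each recovery property is measured with comfortable Monte-Carlo margins
while a full run stays interactive.

## Known limitations

* Exhaustive factor alignment (`alignFactors()`) is intended for the small
  high-level factor counts used here (k ≤ 8).
* The BiCV pseudo-inverse path assumes the rank-$k$ training fit has full
  factor rank; degenerate fits fall back to the Moore–Penrose behavior of
  `MASS::ginv`.
* The long TSV dialect encodes an assessed zero-joint visit with the
  reserved joint id `"."`; files produced by other tools that omit such
  visits lose them (they become MISSING, not ZERO).
* Multiplicative updates converge to stationary points; for the
  identifiable planted structures used in testing this is reliably the
  global optimum, but real data may benefit from `n_restarts > 1`.
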