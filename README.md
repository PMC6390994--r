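# jointNMF

Hierarchical patterns of joint involvement in childhood arthritis, learned
by sparse multilayer non-negative matrix factorization.

## What it does and for whom

Juvenile idiopathic arthritis (JIA) is documented at every visit on a
standard homunculus of assessable joints — 71 sites in the default catalog
here. Clinicians recognize recurring constellations (dactylitis, tarsitis,
sacroiliac involvement) that the formal ILAR subtypes do not capture.
`jointNMF` is for biostatisticians and clinical researchers who have
patient × joint binary involvement matrices (with optional follow-up
visits and subtype labels) and want to:

* quantify joint **co-involvement**: frequencies P(x), pairwise P(x,y),
  conditional P(y|x), same-side skew z-scores per joint-type pair, and a
  permutation test of left/right mirror symmetry;
* learn **sparse hierarchical factors**: a first NMF layer groups tightly
  co-involved joints, a second groups those groupings; the composite
  loading maps each high-level pattern to its **key joints**;
* choose ranks and regularization by **bi-cross-validation** (Owen–Perry
  held-out blocks, one-standard-error selection rules);
* assign each patient to their highest-scoring pattern and grade the
  **degree of localization** — the fraction of active joints that are key
  joints of the assigned pattern (localized ≥ 90 %, partial 60–90 %,
  extended < 60 %);
* follow patients over visits: **transition matrices** with a
  label-permutation null (Holm–Bonferroni), and **time to zero joints**
  via Cox proportional hazards, log-rank tests and Kaplan–Meier curves;
* **project external cohorts** through a frozen model with the stored
  scaling parameters, for validation.

The core model is X ≈ WH with W, H ≥ 0, minimizing
‖X − WH‖²_F + α‖W‖₁ by multiplicative updates, followed by hard
sparsification of W (entries below 10 % of their column maximum) and exact
non-negative least-squares re-estimation of the scores. Layer 2 repeats
this on the rescaled score matrix; C = W₁ˢW₂ˢ ties high-level factors back
to joints.

Because registry data of this kind are not public, the package ships a
first-class synthetic-cohort generator (`makePlantedModel()`,
`simulateBaseline()`, `simulateCourse()`) with planted hierarchical
structure, a localization mixture, bilateral symmetry, mixed-membership
non-key involvement and category-dependent resolution hazards; the entire
test suite runs against it.

## Worked example

```r
library(jointNMF)

catalog <- defaultCatalog()                      # the 71-joint homunculus
planted <- makePlantedModel(catalog, k1 = 19, k2 = 7, seed = 42)
sim     <- simulateCourse(simulateBaseline(planted, 640, seed = 43),
                          planted, seed = 44)
X       <- baselineMatrix(sim$cohort)

model  <- fitMultilayer(X, k1 = 19, k2 = 7)      # two sparse NMF layers
model
#> MultilayerModel: 71 joints -> 19 low-level -> 7 high-level factors
#>   key joints per factor: 6, 4, 6, 6, 6, 6, 4

groups <- assignGroups(model, X)
table(assignedGroup(groups))
#>  G1  G2  G3  G4  G5  G6  G7
#>  85  99  92  90  91  83 100

loc <- localizationTable(X, groups, model)
table(loc$category)
#>  extended localized   partial
#>       147       362       131

surv <- timeToZero(sim$cohort, covariates = data.frame(
  group = loc$group,
  localization = factor(loc$category, c("localized", "partial", "extended")),
  row.names = loc$patient))
fit <- fitCox(surv, c("group", "localization"))
fit$table[grep("localization", fit$table$term), ]
#>                   term  beta     HR ci_lower ci_upper     z        p
#> 7  localizationpartial -1.21 0.2967   0.2327   0.3784  -9.8 1.13e-22
#> 8 localizationextended -3.05 0.0473   0.0312   0.0719 -14.3 1.99e-46
```

Reading the output: the fitted model recovered seven high-level patterns
of 4–6 key joints each; 640 simulated patients split into seven patient
groups; 362 are localized (≥ 90 % of their active joints are key joints of
their assigned pattern). In the Cox model the hazard ratios below 1 mean
partially localized and extended patients reach zero joint involvement
more slowly than localized patients — the direction the generator planted
(per-visit joint resolution hazards 0.45 / 0.30 / 0.20), recovered with
tight confidence intervals.

The methods vignette (`vignettes/multilayer-nmf.Rmd`) documents the model,
its numerical choices, the generator's design and its limitations.

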