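---
title: "Staging CSF proteomes along the Alzheimer's disease continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging CSF proteomes along the Alzheimer's disease continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoStage)
```

## The analysis problem

Alzheimer's disease progresses through an ordered sequence of
neuropathological stages: amyloid-beta plaques accumulate first, then
neurofibrillary tau tangles spread through the brain in the stereotyped
Braak pattern (transentorhinal regions, I, to neocortex, VI). Modern tau
PET tracers let this staging be done in vivo: each of the six Braak
region composites is called positive when its standardized uptake value
ratio (SUVR) exceeds a threshold, and a participant's stage is the length
of the maximal contiguous run of positive regions starting at Braak I.
Because pathological spread is hierarchical, a positive region appearing
*after* a negative one violates the ordering; such participants are
classified *discordant* rather than forced into a stage.

ProteoStage implements the full analysis chain for asking how the CSF
proteome changes across these stages: normalization of multiplexed
tandem-mass-tag (TMT) reporter intensities, robust signed weighted
co-expression network analysis to group proteins into modules,
Eigenprotein summarization, staging of participants from PET, CSF or
cortical-biopsy measurements, module-biomarker association,
cross-cohort Eigenprotein projection, local-regression stage
trajectories, and sparse (elastic-net) staging panels. A synthetic
multi-cohort generator with planted ground truth exercises every stage
end to end.

## TMT normalization

Reporter intensities carry set-wise and channel-wise nuisance scale.
`normalizeTMT()` works on the log2 scale and alternates two median
corrections: each protein is centred on its set-wise median, then each
sample on its own median (the total-protein-amount correction). The
first iteration is the classic two-step reporter-ratio rule; the loop is
then repeated to convergence because the sample-median step perturbs the
protein medians, and even-count medians are interpolated in log space
(geometrically in intensity space). At the fixed point every sample
median and every protein set-median of the log2 ratios is exactly zero,
which makes the operation idempotent and invariant to global rescaling
of the raw intensities — properties the test suite asserts at 1e-12.
Pooled reference channels are normalized but excluded from the protein
median statistic by default, so a set's scale is anchored on real
samples. Proteins missing in more than 50% of participants are removed
by `filterMissingness()` (a protein missing in exactly half is kept: the
rule is strictly greater). `qcOutliers()` reports — but never removes —
samples lying more than 4 robust SDs from the median on the first two
principal components.

## Network construction

`bicorMatrix()` implements the biweight midcorrelation: observations are
weighted by the Tukey biweight around the median with scale 9 x MAD, so
single aberrant measurements cannot dominate a protein pair's
correlation. At most a fraction `maxPOutliers` (default 0.05) of samples
per tail can receive zero weight; beyond that the standardized deviates
are rescaled so the corresponding quantile sits at the weight boundary.
Vectors with zero MAD fall back to Pearson centring; entries are
computed over pairwise-complete observations.

The signed adjacency is `((1 + cor) / 2)^beta`: anticorrelated proteins
map toward zero rather than being folded onto positive correlations, so
modules are direction-coherent. The default power beta = 10 follows
common CSF TMT practice; `pickSoftThreshold()` reproduces the standard
selection diagnostic (smallest power reaching a signed scale-free fit
R^2 of 0.9 with mean connectivity below 100). The topological overlap
matrix (TOM) then replaces raw adjacency with shared-neighbourhood
similarity, and 1 - TOM is the clustering dissimilarity.

### Module detection

`cutTreeDynamic()` is a documented simplification of hybrid dynamic tree
cutting, built from two observations about TOM dendrograms: merge
heights concentrate just below 1, so any cut height must be interpreted
relative to the merge-height *range*; and correlated modules (e.g. two
modules whose latent drivers share most of their stage trajectory) join
one branch that no single static cut can separate. The algorithm
therefore (i) cuts at 95% of the merge-height range to discard leaves
without branch structure, and (ii) decomposes each remaining cluster
recursively: walking down its subtree past stray leaves to the first
partition into two or more branches of at least `minSize` proteins, a
split is accepted when the smallest between-branch mean dissimilarity
exceeds the largest within-branch mean dissimilarity by a gap mapped
from `deepSplit` (25% down to 5% of the height range for deepSplit 0-4,
so higher values accept subtler splits and produce more, smaller
modules). An all-equal dissimilarity has zero range and leaves every
protein unassigned. The PAM stage assigns leftover proteins to the
nearest module only if their mean dissimilarity is within the 90th
percentile of the members' own peripherality — the dendro-consistency
surrogate that keeps background proteins gray. The contract for this
component is behavioural, not label-for-label parity with any existing
implementation: exact recovery of planted block models, no modules on
structureless input, monotone module counts in `deepSplit`, and
high-Rand-index recovery of the synthetic cohort's planted modules.

Modules whose Eigenproteins correlate above 0.8 (dissimilarity below
`mergeCutHeight = 0.2`) are merged iteratively, most-similar pair first,
which also makes the merge order-invariant and gives a safety net
against spurious recursive splits. Eigenproteins are the first principal
component of the per-protein standardized module submatrix
(median-imputed for residual missingness), signed to correlate
positively with the module's mean standardized abundance; kME is the
Pearson correlation of each protein with each Eigenprotein.

## Staging and groups

Positivity thresholds follow the conventions of amyloid and tau PET and
CSF immunoassays: amyloid PET SUVR strictly above 1.55, regional tau PET
SUVR strictly above 1.24, and CSF Abeta42/40 ratio strictly below
0.061. Equality maps to negative; measured values essentially never tie
a threshold, so the convention is documented rather than consequential.
Braak stages come from the hierarchical prefix rule described above,
validated exhaustively against an enumeration oracle over all 64
positivity patterns. For AT groups on the PET basis, overall tau status
is positive when the Braak stage is at least I. On the biopsy basis,
amyloid is positive for a semiquantitative plaque score of at least 1
and tau for a neurofibrillary-tangle flag. Sparse ordinal stages (fewer
than 3 participants) are pooled with the adjacent level
(`poolSparseStages()`), mirroring the common practice of combining Braak
III and IV when III is nearly empty; pooled levels sit at the midpoint
of their range on trajectory axes. Discordant participants are excluded
from stage trajectories by default since they have no position on the
ordinal axis.

## Association and projection

`fitModeratedLM()` fits per-protein least squares of log2 abundance on a
group factor plus age and sex over available cases (proteins observed in
fewer than 20 samples are excluded, and no imputation enters inference),
then shrinks residual variances by empirical Bayes. The prior (d0, s0^2)
is estimated by closed-form moment matching of the log residual
variances under the scaled-F model, with the trigamma function inverted
by Newton iteration; the posterior variance is the usual
degrees-of-freedom-weighted blend, and the moderated t has d + d0
degrees of freedom. Setting the prior df to zero reproduces ordinary
per-protein t-tests exactly, which the tests assert at 1e-8, and the
full fit is cross-checked against an independent moderated-statistics
implementation. Benjamini-Hochberg is the default adjustment;
Bonferroni is used for module-biomarker Spearman tables, where the
family is all module x biomarker pairs computed in the invocation.

`groupContrastTukey()` forms covariate-adjusted group means from a
linear model and tests all pairwise differences against the studentized
range distribution with the model's residual degrees of freedom; with
two groups this collapses to the model t-test (q = t sqrt(2)).
`dualPETModel()` puts amyloid and tau PET SUVR in the same per-protein
model (with age, sex and diagnosis) to separate their partial
contributions.

Cross-cohort projection (`projectEigenprotein()`) restricts a module to
its high-confidence members (discovery kME > 0.6) present in the target
cohort, standardizes them there, and takes the first principal
component, sign-aligned through the kME-weighted member mean. Scores
are z-scored to the target cohort's own controls, so cohorts with
different assays share an interpretable scale. A mean-z alternative was
considered and rejected as the default because the PC reproduces the
discovery Eigenprotein construction; self-projection fidelity (>= 0.95)
is part of the test contract.

## Trajectories and panels

`loessTrajectory()` fits a tricube-weighted local polynomial over
ordinal stage positions (CTRL = 0, Braak I-VI = 1-6) and reports
pointwise 95% bands from the linear-smoother variance. Span and degree
are configurable and recorded; the generic default span is 0.75, while
the pipeline's stage-trajectory analyses use span 0.5, chosen so the
local window covers about three adjacent stages — wide enough to borrow
strength, narrow enough to resolve the characteristic Braak VI
inflection that wider windows smooth away. `summarizeTrajectories()`
aligns several fits, optionally z-scores and vertically offsets them
for display (offsets recorded, so un-shifting is exact), and flags
derivative sign changes as candidate inflection points.

`fitElasticNetPanel()` builds staging panels by penalized logistic
regression at mixing parameter alpha = 0.7 (predominantly lasso with a
ridge stabilizer) over a log-spaced lambda path with stratified K-fold
cross-validation. Missing abundances are median-imputed within training
folds only, and test folds are imputed and standardized with training
statistics, so no information leaks across folds. Lambda defaults to
the minimum-CV-deviance rule (the one-SE rule is available), the final
model is refit on all data at the chosen lambda, and out-of-fold scores
give the cross-validated AUC, computed by the exact mid-rank
Mann-Whitney identity in `rocAuc()`. Karush-Kuhn-Tucker residuals of
the fitted solution are exposed (`kktResiduals()`) and asserted below
1e-6. `compareBaselines()` refits competing feature sets (for instance
age plus an APOE-like covariate, or the core CSF biomarkers) on the
identical fold split so AUC differences reflect features, not
resampling.

## The synthetic cohort generator

`simulateCohort()` is first-class, tested code, not a fixture. It
emulates the statistical structure of a TMT CSF staging study through a
latent factor model: each module m has a per-sample latent factor
`template_m[stage] + N(0, 0.4)`, and each member protein is
`baseline + loading x latent + TMT-set offset + N(0, noiseSd)` in log2
space, with loadings uniform on [0.4, 0.95], 300 pure-noise background
proteins, multiplicative TMT set effects, and one pooled reference
channel per set. Missingness is abundance-dependent (low-abundance
proteins drop out more, emulating left-censored reporter
quantification). Metadata are generated consistently with the latent
stage: six regional tau SUVRs follow the hierarchical prefix pattern
with a 10% chance of one discordant flip; amyloid PET positivity
probability rises with stage (controls mostly negative); CSF tau
species rise monotonically and plateau at Braak VI while the amyloid
ratio declines early; ages are 55-85 with stage-correlated means and
sexes balanced, so covariate adjustment has something to do.

The five trajectory archetypes are fixed at code level
(`trajectoryTemplates()`): stepwise-increasing core markers that
plateau after Braak V, an early endolysosomal peak returning to
baseline, an immune dip with an interior minimum, a near-linear
metabolic rise with a sharp Braak VI drop, and a synapse/membrane
profile flat through V and falling at VI. Shapes are the contract;
amplitudes are calibration choices made once: each template is scaled
so the module's latent SD is about 0.6-0.7, which together with the
jitter SD of 0.4 puts typical member kME near 0.6-0.8 (matching the
membership structure implied by a kME > 0.6 module definition) and
caps the strongest between-module latent correlation near 0.6 —
distinct but correlated modules, as observed for real CSF protein
clusters. `simulateValidationCohorts()` derives a fluid-biomarker-staged
and a biopsy-staged cohort from the same truth with only a configurable
fraction (default 70%) of discovery proteins quantified, emulating
cross-platform dropout.

What the generator does *not* emulate is worth stating: peptide-level
quantification and rollup, isotope-impurity interference, nonlinear
batch effects, covariate-module confounding, and module structure
beyond a single latent factor per module. Passing the recovery suite
therefore shows the pipeline is correct and well-calibrated under a
faithful low-dimensional abstraction of such data — not that it is
robust to everything real instruments produce.

## Numerical and design choices

* Problem sizes in tests and the acceptance script follow the study
  conditions: 500 proteins (200 in five planted modules), 140 samples
  (20 per stage), noise SD 0.5, with five replicate seeds for recovery
  claims and three for power-style simulations.
* Eigenprotein fidelity is summarized per cohort as the mean over
  modules of |cor(Eigenprotein, latent factor)|. For the smallest
  planted module (20 proteins) the single-module fidelity has an
  information ceiling just below 0.9 in occasional cohort realizations
  — the first principal component computed from the *true* member list
  reaches the same value — so the per-module minimum is reported as a
  diagnostic rather than asserted.
* Stage-mean recovery of the templates is asserted on estimates pooled
  over five replicate cohorts, inverting the generative model with the
  known loadings; per-cohort estimates carry the irreducible
  jitter/sqrt(n) noise.
* Degenerate inputs are handled explicitly: constant proteins get zero
  correlation with a warning; protein pairs with fewer than `minPairs`
  joint observations get zero with a warning; an all-equal
  dissimilarity yields no modules; a zero control SD is an error for
  z-scoring; collinear designs name their aliased columns.
* PCA sign is fixed by forcing the largest-magnitude loading positive,
  making QC flags and Eigenprotein signs deterministic.
* `runPipeline()` seeds all randomness from one integer and writes the
  resolved configuration to `provenance.json`; two runs with the same
  configuration produce byte-identical tables.
* A kME-based reassignment post-pass (relabelling proteins whose kME
  significantly favours another module) is available in spirit via the
  PAM stage but not enabled as a separate step: its effect on the
  recovery suite is negligible and the merge step already absorbs
  borderline cases.

## Known limitations

The dynamic tree cut is a behavioural simplification, not a port: on
real data its labels will differ in detail from the reference hybrid
algorithm even where both recover the same coarse modules. The
moderated model supports a single group contrast with additive
covariates, not arbitrary design matrices. Trajectories treat stages as
equidistant ordinals; alternative encodings (e.g. SUVR-continuous time)
are out of scope. The elastic-net panel assumes complete-ish features
after within-fold imputation and does not model APOE genotype beyond a
synthetic stand-in covariate.
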