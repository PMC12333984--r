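---
title: "radiomiR: models, parameters and design choices"
author: "radiomiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radiomiR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Localized radiation injury (a radiological burn) follows a presymptomatic
latency phase during which no clinical sign reveals either the exposure or
its eventual severity. Circulating microRNAs measured by RT-qPCR panels on
plasma are candidate early biomarkers: their abundance shifts with dose days
before symptoms. radiomiR implements the full analysis chain for such
panels — quality control, normalization, supervised multivariate signature
discovery, performance evaluation, and a Bayesian construction that
correlates signatures with clinical outcomes measured on *different*
animals — together with a synthetic cohort generator that provides planted
ground truth for every stage.

The study design the package assumes is four dose groups (0, 20, 40, 80 Gy)
of about 15 animals each, profiled at one timepoint (day 1 or 7 after
exposure), with a complete blood count, CRP, trans-epidermal water loss and
laser-Doppler perfusion ratio recorded per animal, and a separate cohort
carrying day-14 outcomes (injury score, perfusion ratio).

# Quality control

qPCR quantifies abundance as the cycle threshold Ct: one cycle is a two-fold
change, and *lower* Ct means *higher* abundance. Reactions are run for 40
cycles, so Ct readings near the ceiling carry no quantitative information;
values above the detection limit (default 37, strict inequality) are set
missing by `discardHighCt()`.

Three control assays drive sample-level QC:

* **miR-23a-3p** — a universally expressed endogenous reference.
* **miR-451a** — highly abundant in red blood cells; hemolysis contaminates
  plasma with it. The **hemolysis delta** Ct(miR-23a-3p) − Ct(miR-451a)
  rises when red-cell content boosts miR-451a. The flag threshold defaults
  to 7 cycles, the convention of the established delta-based hemolysis
  check; it is configuration-surfaced because laboratories calibrate it.
* **cel-miR-39** — an exogenous spike-in added before extraction. A sample
  whose spike-in Ct deviates from the cohort median by more than 2 cycles
  (default) indicates an extraction-efficiency problem. The check is
  median-relative, hence invariant to plate-wide shifts.

Flags never silently remove data: `applyQC()` marks flagged samples
excluded in the metadata, with a reason, and downstream stages drop them
explicitly. Assays detected in fewer than 75% of retained samples (default)
are removed; this detection-rate rule is the package's operationalization of
"reproducibly detected", and it is reported per assay because signature
content depends on it. The whole chain is idempotent.

# Adaptive (−)ΔCt normalization

ΔCt normalization subtracts a reference abundance from each assay, removing
per-sample extraction-efficiency offsets. Instead of a fixed housekeeping
gene, `findNormalizerSet()` derives the reference set from the data:

1. Assays with complete Ct across retained samples are clustered on their
   per-sample Ct coordinates (Euclidean distance, Ward minimum-variance
   linkage — `hclust(method = "ward.D2")`, the classical Ward criterion).
2. Walking the merge tree bottom-up, every *first-formed* cluster of size
   ≥ k (both children smaller than k; default k = 3) is a candidate. Such
   clusters have at most 2k − 2 members.
3. Within each candidate, every k-subset is scored by the sum of Euclidean
   distances of its members to the subset centroid ("dispersion"), and the
   global minimum wins; ties break on lexicographic assay order for
   determinism.

Scoring every k-subset of a candidate (at most four triples when k = 3)
rather than taking the k members nearest the full-cluster centroid makes the
selection *exactly* the minimizer over all subsets that co-occur in a
first-formed cluster — a property the test suite verifies against brute
force — while the full audit trail of candidates and dispersions is kept in
the result for inspection.

`toNegDeltaCt()` then computes (−)ΔCt = −(Ct − mean normalizer Ct) per
sample: a log2-expression-scale value that *increases* with abundance and is
bit-identical under any per-sample additive offset. Samples missing a
normalizer Ct cannot be normalized and are dropped with a log entry; control
assays are dropped from the feature space.

# Sparse multiblock PLS-DA

Signature discovery couples two blocks — miRNA expression and clinical
covariates — against the dose-group outcome, in the DIABLO style. Per
component, each block's loading vector is updated as the unit-norm,
sparsified image of the design-weighted sum of the other blocks' scores plus
the outcome-block score; the centered class-indicator block participates
with full connectivity and no sparsity. Sparsity is rank-based
soft-thresholding: the `keepX` largest-magnitude entries are kept and shrunk
by the (keepX + 1)-th largest absolute value, preserving signs, so the
support size is exactly `keepX`. After convergence (maximal loading change
< 1e-6, at most 100 iterations, non-convergence flagged) each block is
deflated on its own score, which makes successive within-block scores
exactly orthogonal; the outcome block is deflated too by default (both
modes are available, the difference is negligible on these designs).

Design choices worth knowing:

* **Design matrix.** Data blocks are connected with weight 0.1 and every
  block with weight 1 to the outcome: the components' job is discrimination
  first, inter-block correlation second. The weight is configurable.
* **Initialization and determinism.** Loadings start at the dominant left
  singular vector of X_bᵀY with a fixed sign convention; together with
  fixed tie-breaks the whole fit is deterministic given data and
  configuration — no RNG anywhere in the solver.
* **Prediction.** A new sample is preprocessed with training statistics,
  projected through the components (deflation replayed), block scores are
  averaged with equal weights, and the nearest training-class centroid
  (Euclidean) wins; exact ties break to the lexicographically first class
  and are flagged. Negative distances serve as continuous per-class scores
  for ROC analysis.
* **Tuning.** Leave-one-out cross-validation over a grid of component
  counts (1–3) and `keepX` values ({3, 5, 7, 10, 15, 20, 30}, clamped to
  the block width) for the miRNA block; the clinical block, being narrow,
  keeps all columns. Preprocessing is recomputed inside each fold. The
  score is the balanced error rate (mean per-class error); ties prefer
  fewer components, then smaller total keepX.
* **Stability.** At the chosen parameters the model is refitted in every
  leave-one-out fold; a feature's stability per component is the fraction
  of folds selecting it. The reported signature is the support of the
  full-data fit annotated with stability; features at stability ≥ 0.5 are
  conventionally called stably selected.
* **Missing clinical values** are median-imputed at block assembly, with a
  log entry; remaining missing values are hard errors naming the cell.

Cross-block variable similarity — the quantity drawn in correlation-circle
plots and heatmaps — is Σ_h cor(x, t_a,h)·cor(y, t_b,h) over components,
computed on the preprocessed training data, with a default reporting cutoff
of 0.5 in absolute value.

# Evaluation

One-vs-rest ROC per dose group uses the rank (Mann–Whitney) construction
with midranks for ties; the AUC therefore equals U/(n₁n₀) and is invariant
under strictly monotone score transforms. The p-value is the two-sided
normal-approximated Mann–Whitney test with tie correction. By default the
scores fed to ROC are *held-out* leave-one-out scores at the tuned
parameters (`looGroupScores()`), not resubstitution scores — honest
performance for a tuned model; resubstitution is available as a flag for
comparison. AUC below 0.5 is reported as-is. Group comparisons of single
clinical variables use the Kruskal–Wallis test (tie-corrected H,
chi-square reference).

Under the null (no effects anywhere), the *tuned* model's LOO balanced
error rate is not an unbiased chance estimate for two reasons: tuning takes
a minimum over the grid (optimistic), and nearest-centroid LOO is itself
pessimistically biased at these sample sizes (the held-out sample's absence
shifts its own class centroid away from it). The package's calibration
check therefore compares the chosen configuration's held-out *accuracy*
against Binomial(n, 1/4) with a Bonferroni correction over the grid size:
the null passes when accuracy is not significantly above chance.

# The Bayesian bridge

Signature coordinates live on one cohort; day-14 outcomes on another; only
dose-group labels are shared. For outcome animal j in group g(j) the model
places a latent coordinate

x_j ~ Normal(μ_g(j), s_g(j)²),  y_j ~ Normal(α + β x_j, σ_y²),

where μ_g, s_g are the group mean/SD of the component's scores in the
signature cohort (plug-in constants), the outcome is standardized
internally, α, β ~ Normal(0, 10²) and σ_y ~ Half-Normal(5). Every retained
draw maps to a correlation

r = β·sd(x) / sqrt(β²·var(x) + σ_y²),

with var(x) the mixture variance of the latent coordinate implied by the
prior and the outcome cohort's group sizes, so r ∈ [−1, 1] draw-by-draw and
is invariant to positive affine transforms of the outcome. Sampling is
Metropolis-within-Gibbs: conjugate normal updates for the latents and
(α, β), random-walk Metropolis on log σ_y (proposal SD 0.3). Defaults: 2
chains, 2500 kept draws per chain after 2000 burn-in, deterministic given
the seed. Split-R̂ and an effective sample size (paired-lag truncated
autocorrelation sum) are reported for every parameter; any split-R̂ above
1.05 flags the result non-converged. The reported two-sided tail
probability is 2·min(P(r > 0), P(r < 0)).

Known limitation: in the near-deterministic corner (outcome noise and prior
SDs both tiny) the latents and slope are so tightly coupled that the Gibbs
chain mixes slowly; the posterior mean of r is accurate there but the
convergence flag trips, honestly. Ordinal injury scores are treated as
continuous after standardization (an ordered-probit variant is out of
scope), and each (component, outcome) pair is modeled separately.

# The synthetic cohort generator

`simulateCohort()` emulates the data-generating process the pipeline
assumes, on the additive Ct (log2) scale:

Ct(s, i) = baseline_i + offset_s + effect_i(dose_s) + bio_(i,s) + tech,

with baselines Uniform(22, 36), per-sample extraction offsets
Normal(0, 0.3), biological SD 0.5, technical SD 0.25, and truncation to
missing above the detection limit (37). A planted signature of 15 assays
(of 300) carries dose effects linear in log2(dose + 1) with random sign and
magnitudes Uniform(0.75, 1.5) cycles at 80 Gy — moderate, detectable
effects; only the 1.5-cycle maximum is externally fixed. Three housekeeping
assays share a common baseline (24, jitter SD 0.1) and biological SD 0.05:
the shared baseline is what lets them form a tight Euclidean cluster on raw
Ct coordinates, emulating a co-expressed stable set. Controls are simulated
at baselines 24 (miR-23a-3p), 21 (miR-451a) and 19 (cel-miR-39, tight SD
0.1 plus the extraction offset); hemolysed samples (probability 0.05) get
miR-451a boosted by 4–8 cycles, putting their hemolysis delta at 7–11
against a normal ≈ 3. The clinical block carries a lymphocyte decrease
(means 4.2/4.0/3.7/2.4 ×10⁹/L — significant only at 80 Gy), a day-7
perfusion-ratio elevation of +0.4 at 80 Gy, and uninformative CRP, TEWL and
remaining CBC fields. Day-14 cohorts (`simulateD14Cohort()`, group sizes
15/13/11/9 — attrition grows with dose) draw a latent severity that is a
*noisy* monotone function of dose (dose and severity correlate but do not
overlap exactly), discretized into an injury score and linearly coupled to
the perfusion ratio.

What the generator does **not** emulate: plate/batch structure, melting
curves, probe-specific amplification efficiencies, correlated miRNA
modules, or non-normal heavy-tailed biological variation. Passing recovery
tests therefore demonstrates the pipeline's correctness under its own
assumptions, not its robustness to every artifact of real panels.

# Problem sizes used by the tests and the acceptance script

The shipped checks run on one CPU in minutes: 100 random instances of ≤ 10
assays for the normalizer-selection oracle; 20 random datasets for the
NIPALS limiting case; 5–10 default cohorts (60 samples × 300 assays) for
planted-signature recovery (the median recovery at stability ≥ 0.5 is
expected ≥ 80%); one zero-effect cohort for the chance-level check; 50–150
null datasets for bridge coverage (1000 kept draws each); and a
strong-signal bridge run. These sizes were chosen to keep each quantity's
Monte-Carlo error well inside the margin it is judged against.

# Worked example

```{r example, eval = FALSE}
library(radiomiR)

params <- simulationParams(seed = 1)
sim <- simulateCohort(params, timepoint = "D1")
qc <- applyQC(sim$ct)
ne <- normalizeCt(qc$ct)
normalizerSet(ne)

bd <- assembleBlocks(ne, sim$clinical)
model <- fitSignatureModel(bd, expression = ne)
signatureTable(model)

loo <- looGroupScores(bd, model@ncomp, model@keepX$miR[1])
oneVsRestRoc(loo$scores, outcomeGroups(bd))

d14 <- simulateD14Cohort(params)$clinical
fitBridge(summarizeCoordinates(model, 1), d14, "injury_score", seed = 2)
```
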