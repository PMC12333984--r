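# radiomiR

Prognostic plasma miRNA signatures from RT-qPCR Ct panels.

Localized radiation injuries (radiological burns) develop after a
presymptomatic latency phase: for days after exposure no clinical sign
reveals who was exposed or how severely. Circulating microRNAs measured by
RT-qPCR on plasma shift with dose during that window. radiomiR is for
biostatisticians and radiobiology groups analyzing such panels: it turns raw
cycle-threshold (Ct) tables into dose-group signatures and links them to
later clinical outcomes measured on *different* animals.

The pipeline:

1. **Quality control** — Ct values above the detection limit (default 37)
   are discarded; hemolysis is scored as Δ = Ct(miR-23a-3p) − Ct(miR-451a)
   (flag at Δ > 7 cycles); a cel-miR-39 spike-in monitors extraction
   efficiency; assays detected in < 75% of samples are removed. Exclusions
   are explicit metadata decisions, never silent row deletions.
2. **Adaptive normalization** — instead of a fixed housekeeping gene, the
   normalizer set is found by Ward clustering of complete assays on their
   Ct profiles; the most stable first-formed cluster (minimum sum of
   member-to-centroid distances) yields k = 3 normalizers, and expression is
   (−)ΔCt = −(Ct − mean normalizer Ct), a log2 abundance scale invariant to
   per-sample extraction offsets.
3. **Sparse multiblock PLS-DA** (DIABLO-style) — miRNA and clinical blocks
   are coupled through a design matrix and discriminate the dose groups
   (0/20/40/80 Gy); per component each block loading is a unit-norm, sparse
   (exactly `keepX` nonzero) linear combination, tuned by leave-one-out
   cross-validation on the balanced error rate, with per-feature
   **stability scores** (fraction of folds selecting the feature; ≥ 0.5 is
   "stably selected").
4. **Evaluation** — one-vs-rest ROC per dose group from held-out LOO scores;
   AUC is the Mann–Whitney statistic U/(n₁n₀), p-values from the
   tie-corrected normal approximation; Kruskal–Wallis utilities for single
   variables.
5. **Bayesian bridge** — signature components and day-14 outcomes live on
   disjoint cohorts sharing only dose groups. A latent-variable model
   (x_j ~ N(μ_g, s_g²) from the signature cohort; y_j ~ N(α + βx_j, σ_y²))
   is sampled by Metropolis-within-Gibbs and every draw maps to a
   correlation r = β·sd(x)/√(β²var(x) + σ_y²) ∈ [−1, 1], reported with 95%
   credible intervals, split-R̂ and effective sample sizes.

A seeded synthetic-cohort generator (`simulateCohort()`,
`simulateD14Cohort()`) reproduces the assumed data-generating process —
planted dose-responsive assays, a housekeeping cluster, extraction offsets,
hemolysis events, Ct truncation, dose-dependent lymphopenia, latent-severity
day-14 outcomes — and exports the ground truth for recovery testing.

## Worked example

```r
library(radiomiR)

params <- simulationParams(seed = 1)
sim <- simulateCohort(params, timepoint = "D1")
qc  <- applyQC(sim$ct)
ne  <- normalizeCt(qc$ct)
normalizerSet(ne)
#> [1] "miR-sim-001" "miR-sim-002" "miR-sim-003"   # the housekeeping triple

bd    <- assembleBlocks(ne, sim$clinical)
model <- fitSignatureModel(bd, expression = ne)
model
#> SplsdaModel: 2 component(s), blocks miR, clinical
#>   keepX[miR]: 20, 20
#>   signature: 40 selected feature(s)

head(signatureTable(model))
#>   component       miRNA stability loading max_median_group
#> 1         1 miR-sim-040         1    0.42               80
#> 2         1 miR-sim-045         1   -0.25                0
#> 3         1 miR-sim-082         1    0.30               80
#> ...

# all 15 planted assays sit among the stability >= 0.5 features here
mean(sim$truth$signature_assays %in%
     signatureTable(model)$miRNA[signatureTable(model)$stability >= 0.5])
#> [1] 1

loo <- looGroupScores(bd, model@ncomp, model@keepX$miR[1])
oneVsRestRoc(loo$scores, outcomeGroups(bd))
#>   group  auc p_value n_pos n_neg
#> 1     0 0.97 6.4e-08    15    43
#> 2    20 0.84 1.0e-04    15    43
#> 3    40 0.75 6.3e-03    13    45
#> 4    80 0.91 3.4e-06    15    43

d14 <- simulateD14Cohort(params)$clinical
fitBridge(summarizeCoordinates(model, 1), d14, "injury_score", seed = 2)
#> BridgeResult
#>   posterior r: mean 0.840, 95% CrI [0.732, 0.912]
#>   two-sided tail probability: 0.0000
#>   converged (all split-Rhat <= 1.05): TRUE
```

Reading: the tuned two-component signature separates dose groups with
held-out AUCs 0.75–0.97, and its first component correlates strongly
(posterior mean r = 0.84) with the injury score of an independent day-14
cohort — the quantity that makes the latency-phase signature *prognostic*.

An end-to-end run with artifacts and a digest manifest:

```r
runPipeline(pipelineConfig(seed = 1), outDir = "run")
```

or from a shell via the thin CLI: `Rscript inst/scripts/radiomir.R run
--seed 1 --out run` (subcommands `simulate | qc | normalize | fit |
evaluate | bridge`).

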