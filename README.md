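# drvar

Survival analysis and variance decomposition for dietary-restriction (DR)
lifespan studies in *Drosophila*.

## The problem

Fly DR experiments compare a restricted diet against a higher-nutrient
"ad libitum" (AL) diet, but lifespan outcomes are shaped by much more than
diet: genotype, sex, the laboratory, and cohort-to-cohort "stochastic"
variation between nominally identical replicate runs. A rigorous two-lab
factorial design — 2 labs × 4 cohorts × 4 genotypes (Canton-S, Oregon-R,
w1118, wDahomey) × 2 sexes × 2 diets, on the order of 16,000 flies — lets
those sources of variation be separated and the reproducibility of DR
effects be quantified. `drvar` implements that analysis chain as a tested,
reusable package, together with a synthetic lifespan generator so every
stage runs and is validated without any external data.

## What it computes

* **Survival estimators, written from scratch** (the `survival` package is
  used only as an independent cross-check in the test suite):
  * Kaplan–Meier product-limit curves and medians (smallest event time *t*
    with *Ŝ(t)* ≤ 0.5);
  * two-group Mantel–Haenszel log-rank tests,
    χ² = (Σ(O−E))² / ΣV on 1 df, with a direction call from the sign of
    O − E;
  * Cox proportional-hazards fits by Newton–Raphson on the partial
    likelihood, Efron (default) or Breslow tie corrections;
  * Cox–Snell pseudo-R², R² = 1 − exp((2/n)(ℓ₀ − ℓ));
  * a Schoenfeld-residual check of the proportional-hazards assumption
    (score test of zero slope of scaled residuals on transformed event
    time).
* **Likelihood-based variance decomposition**: for factors
  *I* = {lab, sex, diet, cohort, genotype}, fit the full Cox model and the
  reduced model dropping each factor in turn, then

      contribution(X_j) = (ℓ_full − ℓ_reduced,j) / Σ_{i∈I} (ℓ_full − ℓ_reduced,i)

  with subset and stratified variants (e.g. per-genotype analyses).
* **The DR/AL pair battery**: one log-rank test per (lab, cohort, genotype,
  sex) stratum — 64 pairs in the full design — Bonferroni-corrected at
  α/m (0.05/64 = 0.00078125), with the longer-lived arm of each significant
  pair called from KM medians.
* **Cross-laboratory concordance**: Spearman rank correlation of per-group
  mean (or median) longevities between the two labs.
* **A Gompertz lifespan simulator** (hazard a·e^{bt}) over the factorial
  design with fixed log-hazard effects, a random per-(lab, cohort) shift
  modelling stochastic cohort variation, right censoring, and optional
  Weibull baseline / crossing-hazards toggles for robustness and power
  studies.

## Worked example

```r
library(drvar)

ds <- simulate_lifespans(study_like_config(seed = 1))
stratum_counts(ds, "lab")
#>       lab    n n_events
#> 1 Hoffman 8000     7654
#> 2     Lyu 8000     7701

decompose(ds)
#> Variance decomposition (all records; n = 16000, events = 15355, efron ties)
#>    factor delta_loglik contribution_pct r2_reduced
#>       lab       32.692             2.44     0.1409
#>       sex      229.190            17.08     0.1195
#>      diet        4.604             0.34     0.1439
#>    cohort      174.106            12.98     0.1255
#>  genotype      901.088            67.16     0.0424
#> full model: loglik = -131529.654, Cox-Snell R2 = 0.1444
```

Genotype dominates (67% of the attributable likelihood gain), cohort noise
outweighs the lab effect, and diet explains well under 1% — the ranking the
generator is designed to emulate. The pair battery and concordance follow
the same objects:

```r
pb <- run_pair_battery(ds)          # 64 pairs, threshold 0.05/64
cross_lab_concordance(ds)
#> Cross-lab concordance (mean longevity, 64 matched groups): rho = 0.802, p = 1.73e-15

km <- km_estimate(ds$age_days[ds$lab == "Hoffman"],
                  ds$event[ds$lab == "Hoffman"])
km_median(km)
#> [1] 53.41659
```

Real data enter through `read_lifespan_csv(path, column_map = ...)`, which
normalises arbitrary headers and labels onto the canonical schema
(`lab, cohort, genotype, sex, diet, age_days, event`) with row-numbered
validation, and results leave through `write_report()` (lossless CSV/JSON
twins of the decomposition and pair tables).

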