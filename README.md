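# traumaDyNA

Base-deficit-stratified analysis of trauma-induced systemic inflammation.

Severe blunt trauma triggers a systemic inflammatory response whose early
trajectory differs between patients who arrive with marked metabolic
acidosis and those who do not. Admission arterial base deficit (BD, in
mEq/L — the amount of base needed to titrate blood back to normal pH) is
the standard bedside marker of that acidosis; a cutoff of 4 mEq/L
separates patients at elevated risk of organ dysfunction from the rest.
`traumaDyNA` implements, as a tested pipeline, the analysis that asks
whether BD ≥ 4 patients mount a *differently wired* inflammatory
response: it stratifies a cohort at the BD cutoff, compares clinical
outcomes between strata, tests per-cytokine group×time effects, ranks
mediators by AUC fold change, and infers time-windowed correlation
networks among circulating mediators (Dynamic Network Analysis, DyNA).

It is intended for researchers analysing longitudinal multiplex cytokine
panels (Luminex-style, pg/mL) together with a per-patient clinical table,
and for methodologists who want a reproducible, simulation-backed
reference implementation of DyNA.

## Methods at a glance

- **Exclusion and stratification.** Patients with serum ethanol
  > 10 ng/dL or prehospital fluids > 2 L are excluded (both confound
  admission BD); the rest are split into `BD_LT` (BD < 4) and `BD_GE`
  (BD ≥ 4).
- **Contingency statistics.** Relative risk for 2×2 tables,
  RR = [a/(a+b)] / [c/(c+d)], with the Katz log-method interval
  exp(ln RR ± z₁₋α/₂ √(1/a − 1/(a+b) + 1/c − 1/(c+d))); uncorrected
  Pearson chi-square; Fisher exact; Mann–Whitney U (exact by enumeration
  for small tie-free samples).
- **Trajectories.** Draws are binned to a nominal grid (4, 12, 20 h,
  then daily to day 7); each mediator is tested by fixed-effects two-way
  ANOVA (group, time, group×time) on log10 concentrations with
  sum-to-zero contrasts and Type III sums of squares; per-group AUCs are
  trapezoidal integrals of the mean trajectory, and mediators with a
  significant group effect are ranked by fold = AUC(BD≥4)/AUC(BD<4).
- **DyNA.** Within each adjacent 8-h window ([0,8), [8,16), [16,24) h)
  and each stratum, per-patient window means of log10 concentrations are
  correlated across patients (Pearson); an edge joins two mediators when
  r ≥ 0.7. Network density = (edges × nodes) / (maximum possible edges
  among those nodes) = 2E/(N−1), so a complete graph on N nodes scores N.
- **Synthetic cohorts.** Because patient-level biobank data are not
  public, a seed-reproducible generator emulates the study design
  (70 + 84 patients, 22 mediators, log-normal concentrations,
  detection-limit censoring, missing draws) and can *plant* correlation
  blocks, giving the network analysis a known ground truth.

## Worked example

The published surgical-intervention counts (51 of 84 BD ≥ 4 patients vs
29 of 70 BD < 4 patients operated within 24 h) reproduce the reported
relative risk exactly:

```r
library(traumaDyNA)
surgical <- contingency_2x2(51, 33, 29, 41)
rr <- relative_risk(surgical)
sprintf("RR = %.2f, 95%% CI [%.3f, %.3f]", rr$rr, rr$ci_low, rr$ci_high)
#> "RR = 1.47, 95% CI [1.056, 2.033]"
chi_square_2x2(surgical)$p
#> 0.017
```

RR rounds to the printed 1.5 and the interval matches to three decimals;
the chi-square p agrees with the printed p = 0.02. An end-to-end DyNA run
on a simulated study-size cohort — which plants a ρ = 0.85 correlation
block of 10 mediators in the BD ≥ 4 stratum during the first two windows
— recovers that structure:

```r
cfg    <- simulation_config(seed = 2024)   # defaults: n = 70/84, 22 mediators
cohort <- generate_cohort(cfg)
groups <- stratify_by_bd(cohort$patients)
res    <- dyna_run(cohort$samples, groups)
res$density[, c("group", "window", "E", "N", "density")]
#>   group  window  E  N density
#> 1 BD_LT   0-8 h  0  0       0
#> 2 BD_LT  8-16 h  0  0       0
#> 3 BD_LT 16-24 h  0  0       0
#> 4 BD_GE   0-8 h 45 10      10
#> 5 BD_GE  8-16 h 45 10      10
#> 6 BD_GE 16-24 h  0  0       0
```

The high-BD stratum shows a complete subgraph (E = 45 edges among
N = 10 connected mediators, density 2E/(N−1) = 10) in the 0–8 h and
8–16 h windows and none afterwards, while the low-BD stratum stays
sparse throughout — the planted analogue of the early, transient
hyperconnectivity seen in real cohorts. `run_pipeline()` wraps the whole
sequence (exclusions → stratification → clinical report → trajectories →
DyNA) and writes CSV/GraphML outputs with a hash manifest.

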