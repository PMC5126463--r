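---
title: "Base-deficit-stratified inflammation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-deficit-stratified inflammation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumaDyNA)
```

## The scientific question

Blunt trauma patients arriving with an elevated arterial base deficit
(BD ≥ 4 mEq/L) carry a higher burden of metabolic acidosis and, in
observational cohorts, worse in-hospital outcomes. The analysis this
package implements asks whether that clinical divergence is accompanied
by a *differently organised* systemic inflammatory response: higher
circulating mediator levels, and — more tellingly — a denser web of
inter-mediator correlations during the first day after injury.

The pipeline has four stages: cohort exclusion and BD stratification,
clinical contingency comparisons, per-mediator trajectory analysis, and
Dynamic Network Analysis (DyNA). Each is exposed as ordinary functions;
`run_pipeline()` sequences them and writes all outputs with a hash
manifest.

## Stratification and clinical comparisons

Two exclusions precede everything, both because they confound admission
BD rather than because they alter inflammation directly: serum ethanol
> 10 ng/dL (alcohol elevates BD independently of hypoperfusion) and
prehospital fluids > 2 L (dilution lowers it). Both comparisons are
strict `>`, so a patient at exactly the threshold is retained;
stratification is `bd_admission >= 4` into `BD_GE`, the cutoff itself
inclusive. These boundary semantics are deliberate and tested.

Binary outcomes (surgery within 24 h, transfusion) are compared as 2×2
tables. The relative risk uses the Katz log-method interval; that choice
is pinned by numbers: applied to the surgical counts (51/84 vs 29/70) it
returns RR = 1.466 with 95% CI [1.056, 2.033], exactly the published
interval, so no alternative interval method is plausible. The chi-square
is uncorrected Pearson by default (the Yates correction is behind a
flag) because the uncorrected p = 0.017 is consistent with the printed
p = 0.02. A documented continuity-corrected relative-risk variant
(+0.5 to all cells) exists for tables with zero events but is off by
default. We interpret the reported risk statements as risk ratios from
2×2 tables throughout; no time-to-event model appears anywhere in the
source analysis, so none is implemented.

Continuous clinical variables are summarised as mean ± SEM per stratum
and compared by Mann–Whitney U. The U test is exact (full enumeration)
when the pooled sample is ≤ 12 with no ties, and otherwise uses the
tie-corrected normal approximation — the exact path matters only for the
package's own small-sample tests, but it keeps the kernel honest against
an enumeration oracle.

## Trajectory analysis

Raw draw times are mapped to a nominal grid by half-open bins. The
first-day draws sit at 4, 12, 20 h: the source design specifies "three
samples within the first 24 h" without times, and placing one draw in
each 8-h DyNA window makes the windowed analysis well defined with
exactly one value per patient per window. Later bins are centred on the
daily draws (48…168 h) and partition [0, 192) h. Duplicate draws of a
mediator within one bin are averaged.

Each mediator is tested by a fixed-effects two-way ANOVA (group, time,
group×time) on log10 concentrations. Three choices deserve comment:

* **Transform.** log10 by default: cytokine panels are right-skewed
  over orders of magnitude, and the generator is log-normal. A raw-scale
  option is retained because the source analysis does not state a
  transform.
* **Type III sums of squares** with sum-to-zero contrasts (via
  `car::Anova`), so unbalanced strata (70 vs 84 patients, missing draws)
  are handled; on balanced designs this provably equals the classical
  decomposition, which the tests assert against a hand-computed
  cell-means example.
* **No subject term.** The analysis is a two-way ANOVA on all
  observations, matching the named method; a mixed model with a patient
  random effect would be the modern choice and would give different
  (generally more conservative) p-values. This is a faithfulness
  decision, documented rather than silently "improved".

AUCs integrate the per-group mean trajectory by the trapezoid rule over
nominal times. The units are reported as pg·h/L, following the
convention of the published AUC tables even though concentrations are
pg/mL; we document the apparent unit inconsistency rather than rescale.
Trapezoid was chosen because time-integrated units imply quadrature; a
sum-of-means alternative (`auc_sum_means`) is exposed for sensitivity
checks since the source method statement does not name one. There is no
extrapolation beyond the first/last observed point inside the interval:
with the default grid, a "0–24 h" AUC is the integral from 4 to 20 h.
Mediators enter the fold-change ranking when their ANOVA *group* effect
has p < α (default 0.05); the published table legends are ambiguous
between the group and interaction effects, and we default to the group
effect because fold change is a group-level contrast. No multiplicity
correction is applied across the 22 mediators, matching the source
analysis; a Benjamini–Hochberg adjustment can be applied by the caller
to the returned p-values.

## Dynamic Network Analysis

For each stratum and each window [0,8), [8,16), [16,24) h:

1. each patient's samples in the window are averaged per mediator on the
   log10 scale (one value per patient — pooling repeated samples would
   mix within- and between-patient variation);
2. mediators are correlated across patients (Pearson by default;
   Spearman behind a flag). Mediator pairs with fewer than `min_pairs`
   (default 8) complete observations get no correlation and can never
   form an edge — a floor that prevents spurious edges from tiny
   overlap;
3. an edge joins mediators with r ≥ 0.7. The threshold rule is read
   literally as signed (positive co-variation); an absolute-value mode
   exists because anti-correlated mediator pairs are biologically
   meaningful even if the source method is silent about them;
4. density = (E × N) / (N(N−1)/2) = 2E/(N−1). `N` defaults to the
   *connected* nodes (degree ≥ 1), which matches the stated intent of
   adjusting for "the number of significantly altered nodes"; the
   alternative `node_rule = "all"` counts the whole panel. A complete
   graph on N nodes scores N under this metric — it is not the
   conventional 0–1 graph density, and that is intentional.

## The synthetic cohort generator

No patient-level data are deposited for this kind of study, so the
generator is first-class, tested code whose defaults *are* the study
conditions: 70 `BD_LT` + 84 `BD_GE` patients; the 22-mediator panel;
draws at 4, 12, 20 h and daily to 168 h; concentrations log10-normal
with residual SD 0.4 (about 2.5-fold scatter, typical of plasma
cytokines); group-dependent means whose offsets are the log10 of the
published fold changes for the mediators reported as elevated; admission
BD from truncated normals calibrated to the published stratum means
(1.7 ± 0.1 and 6.7 ± 0.4, mean ± SEM) on either side of the cutoff;
clinical covariates from normals matched to the published cohort table;
detection-limit censoring (LOD/2 substitution, the multiplex-assay
convention); and a 5% chance that a scheduled blood draw is missing.
One ρ = 0.85 equicorrelated block of 10 mediators is planted in the
`BD_GE` stratum for the first two windows only, emulating the early
transient hyperconnectivity that stratum shows; correlated noise is
drawn through the Cholesky factor of the block-structured correlation
matrix, which the config constructor verifies is positive definite.

What the generator does **not** emulate — hence what passing tests do
not show about real data: mediator cross-correlations outside planted
blocks (real panels are diffusely correlated, so real networks are
denser at any threshold); within-patient serial correlation across
days; assay batch effects and plate-to-plate drift; informative
missingness (sicker patients missing more draws); and any mechanistic
coupling between clinical covariates and mediator levels. Planted-block
recovery therefore validates the *machinery* (windowing, correlation,
thresholding, density), not the biological claim.

The distributional form is our assumption: the source analysis never
states one, and log-normality is the field's default for cytokine
panels.

## Numerical choices and degenerate inputs

* All randomness flows through the config seed; identical configs give
  byte-identical tables, and `run_pipeline()` proves it with MD5
  manifest hashes.
* Zero-variance responses, empty design cells and zero residual degrees
  of freedom are explicit errors in the ANOVA, never silent NaNs; the
  failing cells are named.
* Correlations on zero-variance columns are set missing with a warning;
  missing correlations never form edges.
* AUC requires ≥ 2 non-missing points inside the interval; missing
  interior points are spanned by a single trapezoid.
* Fold-change ties are broken alphabetically by mediator name so the
  ranking is deterministic.
* BD values are rounded to 0.01 mEq/L with the truncation boundary
  adjusted so rounding can never move a patient across the cutoff.

## Problem sizes used in the test suite

Unit tests run on cohorts of 10–24 patients; distributional checks use
200–500 patients per stratum at a single time point; planted-network
recovery and the end-to-end acceptance checks use the full 70 + 84
design; ANOVA null calibration uses 1,000 simulated datasets of 20
patients per group at three time points (the acceptance script uses 400).
These sizes were chosen so each assertion has adequate power under its
3-standard-error acceptance band.

## Known limitations

The fixed-effects ANOVA ignores repeated measures within patient; the
density metric has no sampling distribution attached (no test on density
differences is provided, since none is defined in the source method);
DyNA is correlational and directionless — no partial-correlation or
lagged inference; and the generator's calibration to published summary
statistics makes it a structural emulator, not a digital twin of any
real cohort.
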