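# mnmaudit

Criterion-based audit of maternal near-miss cases in R.

A **maternal near miss (MNM)** is a woman who nearly died but survived a
complication of pregnancy, childbirth or the 42 days after its termination;
together with maternal deaths (MD) they form the **severe maternal outcomes
(SMO)** used to audit obstetric care where deaths alone are too rare to
learn from. Audits include cases by explicit rules — the WHO near-miss
criteria (11 clinical, 8 laboratory-based, 6 management-based) or a
low-resource adaptation (the "Haydom" profile: unmeasurable laboratory
criteria dropped, the transfusion threshold lowered from ≥5 to ≥1 unit, ICU
admission and the disease-based criteria eclampsia, sepsis and uterine
rupture added).

`mnmaudit` makes those rules executable and implements the analyses built
on them:

* **Rule engine** — `builtin_registry()` encodes every criterion as a
  predicate over case-record fields with named parameters
  (e.g. shock = SBP < 90 mmHg sustained 60 min, pulse ≥ 120/min, fluids
  > 2 L); profiles (`WHO`, `WHO-clinical`, `Haydom`) ship as editable JSON.
  Missing measurements never fire a criterion.
* **Classification & indicators** — `classify_cohort()`,
  `compute_indicators()`: SMO ratio per 1,000 live births,
  case fatality rate CFR = MD / (MNM + MD), per-criterion frequencies,
  data-completeness report.
* **Diagnostic validity** — the criteria set as a test for maternal death
  among all delivered women: `build_confusion()`, `validity_metrics()`
  (sensitivity, specificity, PPV, NPV with Wilson / Wald / Clopper-Pearson
  intervals).
* **Threshold sweep** — `transfusion_threshold_sweep()` re-classifies at
  each blood-transfusion threshold and tracks positives, sole-transfusion
  cases, CFR and validity.
* **Stepwise elimination** — `stepwise_elimination()` greedily excludes the
  most frequently used criterion, removes its cases, recomputes and
  repeats, partitioning criteria into *independent* vs *passive*
  contributors; `reconstruct_from_marginals()` rebuilds a case×criterion
  matrix from a printed elimination grid.
* **Synthetic cohorts & fixtures** — `generate_cohort()` simulates a
  delivery cohort with latent-severity criterion co-occurrence and
  realistic missingness; `fixture_haydom_cohort()`, `fixture_who_matrix()`
  and `fixture_confusion_tables()` deterministically reconstruct a
  published two-year audit (9,471 deliveries, 248 positives, 32 deaths).
* **Pipeline** — `run_audit()` produces the whole report bundle
  (classification CSV, indicator/validity JSON, elimination TSV, sweep CSV).

## Worked example

```r
library(mnmaudit)

fx <- fixture_haydom_cohort()                 # 248-case reference cohort
cl <- classify_cohort(fx$cohort, audit_profile("Haydom"))
compute_indicators(cl, fx$denominators)
```

```
Near-miss indicators (profile 'Haydom')
  deliveries 9471, live births 9136
  MNM 216 + MD 32 = SMO 248
  SMO ratio : 27.1 per 1,000 live births
  CFR       : 12.9%
```

27.1 severe outcomes per 1,000 live births, and one in eight included women
died. Validity of the same profile against death, among all 9,471 women:

```r
profile_validity(cl, total_population = fx$denominators$n_deliveries)$metrics
```

```
Diagnostic validity (95% CI, wilson)
  sensitivity : 100.0%  [89.3%-100.0%]
  specificity :  97.7%  [97.4%-98.0%]
  ppv         :  12.9%  [9.3%-17.6%]
  npv         : 100.0%  [100.0%-100.0%]
```

Every death is captured (no false negatives), at the price of a low PPV:
most positives are near misses, driven by one-unit transfusions. Raising
the threshold:

```r
transfusion_threshold_sweep(fx$cohort, "Haydom", fx$denominators)
```

```
Transfusion threshold sweep (profile 'Haydom')
 threshold_units n_positives n_sole_transfusion cfr_percent sensitivity
               1         248                101        12.9         100
               2         171                 24        18.7         100
               5         147                  0        21.8         100
 specificity  ppv npv
        97.7 12.9 100
        98.5 18.7 100
        98.8 21.8 100
```

A two-unit threshold removes the 77 women whose only criterion was a single
unit of blood — none of whom died — lifting PPV to 18.7% with sensitivity
intact. And the elimination ranking on the 92 WHO-identified cases:

```r
stepwise_elimination(fixture_who_matrix())
```

```
<elimination_trace> 92 cases, 17 criteria, 12 steps
  step  1: shock                    removed 51 of 92 -> 41 remain
  step  2: unconsciousness          removed 13 of 41 -> 28 remain
  step  3: cardiac_arrest           removed  8 of 28 -> 20 remain
  ...
  passive: cpr, gasping, stroke, uncontrollable_fit
  unused : acute_cyanosis
```

Shock alone accounts for 51 of 92 cases; CPR, gasping, stroke and
uncontrollable fit never identify a case on their own and are candidates
for removal.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch through the installed package, the positive
predictive value and specificity of the Haydom criteria at a two-unit
transfusion threshold (via the reference cohort and the sweep) and the
number of cases remaining after the first elimination step (via the
marginal-reconstructed WHO matrix), and writes them as JSON.

## Documentation

The vignette `vignettes/near-miss-audit.Rmd` documents the rule
definitions, the tie-breaks and rounding conventions, what the fixtures
reconstruct (and the one marginal that printed tables cannot pin down),
the synthetic generator's model and its limits.
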