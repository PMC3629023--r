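---
title: "Criterion-based audit of maternal near-miss cases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criterion-based audit of maternal near-miss cases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnmaudit)
```

## The problem

A maternal near miss (MNM) is a woman who nearly died but survived a
complication of pregnancy, childbirth or the 42 days after its termination; a
maternal death (MD) is a death in the same window, from any cause. Near
misses occur more often than deaths and share most of their clinical
characteristics, which makes them the workhorse of criterion-based clinical
audit: cases are included when they satisfy explicit, predefined inclusion
criteria, and the resulting counts drive quality-of-care indicators.

The WHO near-miss criteria comprise 11 clinical, 8 laboratory-based and 6
management-based rules. In a rural referral hospital without blood bank,
blood-gas analysis or most chemistry assays, many of these cannot fire:
six laboratory criteria and two management criteria are unmeasurable, and a
five-unit transfusion is practically impossible where relatives are the
blood supply. The low-resource ("Haydom") adaptation therefore drops the
unmeasurable criteria, lowers the transfusion threshold from five units to
one, and adds ICU admission and three disease-based criteria (eclampsia,
sepsis, uterine rupture). This package implements both rule sets as an
executable registry, plus the analyses that compare them: cohort
indicators, diagnostic validity against maternal death, a transfusion
threshold sweep, and a greedy stepwise elimination ranking criteria by
independent contribution.

## The rule engine

Each criterion is a declarative predicate over episode-summary fields of a
case record with named, defaulted parameters (`builtin_registry()`). Three
evaluation rules matter:

* **Missing means not met.** A criterion whose required fields are not all
  present is *not evaluable*, and a non-evaluable criterion is never met
  (`met` implies `evaluable`). This mirrors field reality: a criterion that
  needs an oximeter simply never fires on a ward without one, which is the
  mechanism behind underreporting, not an error state.
* **Deaths are included from any cause.** The MD label comes from the vital
  outcome alone, even with zero met criteria. The criteria act as a
  diagnostic *test* only in the validation module, where test-positivity is
  "meets at least one included criterion".
* **Profiles are data, not code.** The WHO, WHO-clinical and Haydom profiles
  ship as JSON files under `inst/extdata/profiles/`; a local adaptation is a
  copy with edited criterion lists or parameter overrides.

Numerical choices where the source definitions leave room:

* The clot-observation window is quoted as "7–10 minutes"; the predicate
  uses a single `clot_threshold_min` parameter defaulting to the lower
  bound (7 min), which is the stricter reading; the parameter makes the
  ambiguity explicit and overridable.
* "Unconsciousness > 12 h" and "GCS < 10" are alternates joined by OR, and
  either field alone suffices for evaluability.
* Sepsis needs a clinical infection sign plus at least 3 of 4 systemic
  signs; it is evaluable when the infection sign and at least three of the
  four sign fields are present, so that "met" can never be asserted from
  fewer observed signs than the rule requires.
* The record fields for the six unmeasurable laboratory criteria exist in
  the schema (so the registry's predicates are real and the WHO profile is
  complete) but low-resource data simply never populate them.

## Indicators and the transfusion threshold

`compute_indicators()` reports the severe-maternal-outcome ratio
(SMO = MNM + MD per 1,000 live births) and the case fatality rate
(CFR = MD / SMO, the mortality index). Ratios are carried at full precision
and rounded only at presentation with `round_half_up()` (one decimal,
half away from zero), which reproduces published renderings such as
27.146 → 27.1 and 18.713 → 18.7.

`transfusion_threshold_sweep()` reclassifies the cohort with the
transfusion parameter overridden at each threshold. "Sole transfusion"
cases are evaluated against the full profile minus the transfusion
criterion: a case counts as sole when transfusion is its only met
criterion at that threshold. One published figure is deliberately *not*
reproduced: the source text states the CFR after excluding sole one-unit
recipients as 22.6% while printing the fraction 32/171, which equals
18.7%; the package reports the computed value.

## Validity

`build_confusion()` treats the criteria set as a test for death among all
delivered women; women with no recorded event enter the true-negative cell
via the `total_population` argument, so the 2x2 table totals the delivery
cohort. Metrics with a zero denominator are reported missing rather than 0.

Binomial intervals default to Wilson, which behaves well at the boundary
proportions (0/n, n/n) that dominate these tables; Wald and Clopper-Pearson
are selectable. The intervals printed in the source audit for 32/32
sensitivity (91.1–100%) are not reproduced by Wilson, Wald, Clopper-Pearson
or Jeffreys (all give lower bounds near 89–92%, none exactly 91.1); the
original software's method is unknown, so only point estimates are treated
as reference values and the interval method is an explicit, documented
choice.

## Stepwise elimination

The refinement procedure ranks criteria by frequency of use, excludes the
most frequent, removes all remaining cases that carry it, recomputes
frequencies and repeats until no cases remain. Criteria selected while
still covering at least one case are *independent* contributors; criteria
whose remaining count reaches zero before selection are *passive* (they
only ever fired alongside stronger criteria); criteria never met at all are
reported in a third *unused* list rather than being conflated with the
passive ones.

Ties are broken by (1) frequency in the original full cohort, then (2)
column order — the rule the published trace itself follows when two
criteria reach count 8 simultaneously and the one that was more frequent
from the start is excluded. The published table excludes its final six
count-1 criteria "simultaneously for space reasons"; the implementation
runs them as sequential singleton steps under the same tie-break, which
yields identical marginals and partitions.

A key structural property, verified by property tests: the procedure
depends only on the per-step frequency marginals, never on within-step
co-occurrence beyond the selected criterion. That is what licenses
`reconstruct_from_marginals()`: from a printed elimination grid one can
build *some* case-by-criterion matrix — removed cases all carry the
selected criterion, count drops give the co-carriers, assigned first-fit by
case index — and its replay reproduces every printed cell. The first-fit
assignment is declared canonical for the fixtures.

## Fixtures: a stated world, reconstructed from printed tables

`fixture_confusion_tables()` returns the three printed 2x2 tables (WHO
clinical 77 positive, WHO 92, Haydom 248; 32 deaths; 9,471 women).
`fixture_who_matrix()` rebuilds the 92-case WHO incidence matrix from the
elimination grid. `fixture_haydom_cohort()` extends it to the full 248-case
record-level cohort reproducing the published marginals: the Haydom
frequency column, 216 MNM + 32 MD, 92 WHO positives, and the transfusion
structure (108 one-unit recipients, 77 sole; 54 two-unit, 22 sole; exactly
two recipients at or above five units, set to 6 and 5 units as described
for the two actual cases).

Printed tables constrain only marginals, so the remaining freedom is fixed
deterministically and documented here:

* units 3–4 are not printed; the 20 unaccounted recipients are set to
  12 at 3 units and 8 at 4 units, two of the 3-unit recipients being
  sole-transfusion (the 55 Haydom-only criterion occurrences then exactly
  cover the 55 non-sole extra cases, one criterion each, index-ordered);
* all 32 deaths sit in the shock block, so false negatives are zero under
  every profile, as in all three printed tables;
* the 9,223 event-free women are carried as denominators, not rows
  (`materialize_negatives = TRUE` produces them physically).

One marginal is knowingly not matched: the canonical first-fit matrix gives
78 cases with at least one clinical criterion where the printed
WHO-clinical table has 77 — the true co-occurrence is unrecoverable from
marginals. The WHO-clinical validity numbers are therefore computed from
the printed confusion table, not from the cohort fixture.

The Haydom-profile elimination is not pinned to the published listing
either: the published independent counts there sum to 243, not 248, and
four criteria appear in none of its lists, so that trace serves as an
illustration only.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with defaults equal to the audited cohort's magnitudes: 9,471
deliveries, live-birth rate 9136/9471, case rate 248/9471, death rate among
cases 32/248, per-criterion prevalences from the published frequency
column, the published transfusion-unit distribution (with the 3–4 unit
filler above), and sole-one-unit fraction 77/108.

Criterion indicators and death are generated through a Gaussian copula on a
latent severity scalar: indicator $i$ fires when
$\Phi(\rho z + \sqrt{1-\rho^2}\,\varepsilon_i) < p_i$ with shared severity
$z$ and loading $\rho$ (`severity_loading`, default 0.6, a moderate
correlation chosen once as clinically plausible co-occurrence). Because the
transformed variate is uniform whatever $\rho$, every configured
probability is an *exact* marginal — the basis of the 3-standard-error
parameter-recovery property tests — while higher severity still raises
criterion counts and death risk jointly. One-unit recipients are sole with
exactly the configured probability (the complement is conditioned on
carrying another criterion); zero-unit cases are rejection-sampled to carry
at least one criterion, the only place where marginal prevalences are
mildly conditioned.

Cases receive field values that make their intended criteria fire through
the real predicates (a shock case gets SBP 80 sustained, pulse 130, fluids
2.5 L) — never a label injection. Routine admission measurements are then
filled with unremarkable values and masked at the configured missingness
rates (defaults follow the published completeness: temperature 65%
recorded, urinary output 10%, oxygen saturation 4.8%, ...). Masking never
touches the evidence fields of a case's met criteria: a case is in the
audit because the criterion was observed, so published per-criterion counts
are observed counts while completeness describes routine documentation.
Consequently, observed completeness of a field that also evidences a common
criterion sits slightly above one minus its masking rate; recovery tests
for missingness use configurations where the masked field backs no
generated criterion.

What a green test does *not* establish: the generator has no gestational
age, parity, referral pattern or temporal structure, its within-case
values are canonical rather than distributed, and criterion co-occurrence
beyond a single severity factor (e.g. syndrome clusters) is not modelled.
It validates the pipeline's logic and statistical behaviour, not clinical
realism of individual records.

## Degenerate inputs and limitations

Empty cohorts classify to zero counts and an SMO ratio of 0 with CFR
reported missing; zero-denominator metrics are missing, not zero; an
incidence matrix with an all-zero row (a positive case carrying no
criterion — possible only for deaths) is rejected at construction, and
`run_audit()` skips the elimination stage in that situation rather than
silently dropping cases. The package does not compute SOFA scores, does
not attribute causes of death, does not model the audit-meeting process,
and provides no optimal set-cover alternative to the greedy elimination —
the published procedure is greedy by frequency and is reproduced as such.
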