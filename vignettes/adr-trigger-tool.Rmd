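---
title: "Screening and evaluating an ADR trigger tool for geriatric admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and evaluating an ADR trigger tool for geriatric admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrtrigger)
```

## The screening model

An ADR trigger tool is a checklist: a set of clinical events (*triggers*)
each paired with the drug classes that commonly cause that event in older
patients. Screening an admission means asking, for every documented
clinical event that matches a trigger and every associated drug class with
at least one prescribed drug in the record, whether that *trigger–drug
combination* is a genuine adverse drug reaction. The tool is deliberately
mechanical — it has high recall on its target events and modest precision,
and the quantity that summarises its usefulness is the **positive
predictive value**

$$\mathrm{PPV} = \frac{\#\{\text{combinations adjudicated as ADR}\}}{\#\{\text{detected combinations}\}},$$

computed overall and per trigger, where a combination counts as an ADR
when its WHO-UMC causality category is *possible*, *probable* or
*certain*.

`adrtrigger` implements the explicated form of the Dutch geriatric
guideline's tool: 16 triggers, with clinically indistinguishable events
merged into a single trigger (fall/collapse/(orthostatic)
hypotension/dizziness/syncope; delirium/confusion/drowsiness), bleeding
split into gastrointestinal, intracranial and other bleeding plus
supratherapeutic INR, and glucose/electrolyte disturbances split by
direction. Drug classes are pinned to WHO ATC prefixes (e.g. thiazide
diuretics `C03A`, loop diuretics `C03C`, NSAIDs `M01A`) or explicit codes
(digoxin `C01AA05`; duloxetine, venlafaxine and mirtazapine as the
"miscellaneous antidepressants"). The whole catalogue ships as an
editable YAML file (`system.file("extdata", "trigger_tool.yaml", package =
"adrtrigger")`), so a deployment can adapt synonym lists or class
definitions without touching code.

Two catalogue choices deserve a note. The guideline's delirium row names
"drugs with anticholinergic and sedative properties" by reference to a
supplementary list that is not restated here; the default class is a
broad-brush set of prefixes from published anticholinergic/sedative burden
lists (opioids, antiepileptics, psycholeptics, antidepressants, sedating
antihistamines, urinary antispasmodics, belladonna alkaloids) and is
explicitly user-replaceable. A consequence is that one drug may resolve to
more than one class — morphine is an opioid *and* carries sedative
properties — which is intended: `classify_drug()` returns every matching
class, and detection emits one combination per (trigger, class). Second,
the original (pre-explication) tool listed a generic "cardiac therapy"
class for delirium; the explicated tool replaced it with digoxin and
anti-Parkinson drugs, and we follow the explicated version. Users who want
the legacy behaviour can add a `C01`-prefix class to their own
configuration.

## Counting rules

Detection follows two rules. Drugs of the *same* class linked to the same
trigger are one combination (oxycodone + morphine with constipation →
constipation–opioids); drugs of *different* classes are separate
combinations (a thiazide + a loop diuretic with hyponatraemia → two).
Combinations are therefore unique per (patient, trigger, class), with all
contributing drugs aggregated. Event matching is a case-insensitive exact
match of normalised labels against controlled synonym lists — records are
assumed pre-structured, and no free-text processing is attempted. By
default only admission-letter events are screened (screening happened on
the day of admission); recognition and causality may draw on both letters.

## Causality and agreement

The WHO-UMC scheme is applied either holistically (a rater supplies the
category directly) or from structured evidence fields through a decision
table shipped as data (`whoumc_decision_table.yaml`): *certain* requires a
plausible time course, alternatives excluded, positive dechallenge and a
positive rechallenge or a pharmacologically definitive event; *probable*
relaxes rechallenge and allows alternatives to be merely unlikely;
*possible* requires only the plausible time course; insufficient data is
*unclassifiable*; everything else is *unlikely*. Rules are evaluated
top-down, so the table returns the highest qualifying category, and the
table is monotone: strengthening any single evidence field never lowers
the category (this is property-tested).

The dual-rater protocol treats *any* disagreement — including
unclassifiable versus an ordered category, whose ordinal distance is
undefined — as requiring a discussed resolution, with a third expert as
the final escalation. Inter-rater agreement is plain (unweighted) Cohen's
kappa over the 5×5 confusion matrix, with the conventional bands (poor
< 0.00, slight 0.00–0.20, fair 0.21–0.40, moderate 0.41–0.60, substantial
0.61–0.80, almost perfect 0.81–1.00); a kappa value falling between two
printed ranges takes the band whose range starts below it. When both
raters use one identical category throughout, expected agreement is 1 and
kappa is undefined; we return 1 (if observed agreement is 1) or 0, with a
warning, preserving the perfect-agreement identity.

## Recognition by usual care

A combination is *recognised* when the attending physician explicitly
documented the trigger–drug link, or — failing that — when the trigger is
documented and at least one contributing drug was withdrawn, discontinued
or dose-adjusted. Changes are matched by normalised drug name, since
discharge letters name products rather than ATC codes. This rule
knowingly over-counts: a drug stopped for lack of indication is
indistinguishable from one stopped because of the ADR, and persistence of
changes after discharge is not evaluated. Recognition rates are always
computed over an explicit causality restriction set (all ADRs, or probable
+ certain only); unclassifiable combinations are never silently included,
and an empty stratum reports an undefined rate rather than zero.

## Evaluation outputs

`compute_performance()` (or `performance_from_counts()` for aggregated
data) returns per-trigger rows in catalogue order — including zero-count
triggers — with combination counts, shares, causality counts, ADR counts
and PPVs, plus a totals row, optional stratified recognition tables and
reporting-level drug-class attribution (fine classes grouped to labels
like "Diuretics" or "Agents acting on RAAS" via an editable mapping).
Proportions are carried unrounded; display formatting rounds percentages
half away from zero to one decimal, which is what published tables use.
The PPV denominator *includes* unclassifiable combinations, whereas the
default recognition denominator excludes them; both denominators are
explicit in the output. Excluding triggers (e.g. the low-PPV fall and
delirium rows) recomputes totals over the remaining rows; on the shipped
reference counts this raises the overall PPV from 41.8% to 62.2%.

The shipped reference fixtures transcribe the published evaluation of the
tool on 345 acute geriatric admissions (941 combinations, 393 ADRs). Two
transcription notes: the published total row prints a mean of 2.0
associated drugs per trigger, but the count-weighted mean of the printed
per-trigger means is 2.27 (the original total was computed from raw data;
we report the recomputed value when working from aggregated counts), and
the printed claim that the four most frequent triggers cover 86.3% of
combinations recomputes to 810/941 = 86.1%; the package always reports
recomputed values.

## The synthetic-cohort generator

The study's patient-level records are not public, so the package ships a
generator whose defaults encode the published cohort conditions and whose
output carries full ground truth. Per patient:

* **Age** is normal with mean 84 and SD 6.7, truncated below at 70 and
  rounded; the SD is chosen so the untruncated interquartile range is the
  published 79–88. **Sex** is female with probability 0.61.
* **Chronic drug count** is 5 plus a negative binomial (mean 5.8, size 3),
  chosen as the simplest shifted count distribution with median 10 and
  IQR roughly 8–13 above the polypharmacy minimum of 5.
* **Combination slots** per patient are negative binomial with size 1 and
  mean 941/345 ≈ 2.73, truncated at 16. This geometric form reproduces,
  analytically, the published pattern: ≈ 27% of patients with no
  combination, and a conditional median of 3 with IQR 2–5 among patients
  with at least one.
* Each slot draws a **trigger** with probability proportional to the
  published per-trigger combination counts, a class of that trigger, and
  one or more catalogue drugs of that class; a matching clinical event
  (one synonym of the trigger) is documented in the admission letter. The
  **true causality category** is drawn from the trigger's published
  causality mixture, and **recognition evidence** is planted with the
  published recognition probability for that (trigger, category):
  probable and certain use the probable+certain stratum rate, the
  possible-only rate is solved from the two published strata, unlikely
  combinations are recognised at the rate implied by the overall
  classifiable recognition count (153/536), and unclassifiable never.
* Tool-neutral **background drugs** (statins, PPIs, levothyroxine, ...)
  fill the medication list, and noise events and noise medication changes
  on non-contributing drugs are added.

The subtle design problem is class overlap: the fall trigger shares every
hyponatraemia class, the three bleeding triggers share all their classes,
and the delirium class covers most psychotropics. A drug planted for one
trigger is then mechanically detected under a second documented trigger —
exactly as in the real screening, where one drug documented under two
events counts under both. The generator embraces this: slots take a
conflict-free class where one exists; otherwise the class is shared and
the sibling combination under the other trigger is planted too, with its
own causality and recognition draw, and credited against that trigger's
later slots so per-trigger totals track their weights. Recognition
evidence is materialised at the end of each patient: medication changes
are only planted on drugs contributing to a single combination (a change
in a shared drug would recognise every combination it touches), explicit
trigger–drug links otherwise. Under the shipped catalogue this makes the
set of detected combinations exactly the planted ones; with user-supplied
configurations any residual extra detections are kept and labelled
`planted = FALSE` in the ground truth (with causality drawn from the same
per-trigger mixture) rather than suppressed, and the ground truth reports
the incidental rate.

What the defaults deliver, measured over 20 replicates at n = 345: overall
PPV mean ≈ 0.416 against the mixture-implied 393/941 = 0.418; 73–74% of
patients with at least one combination (published: 73%); ≈ 53% with at
least one ADR (published: 52%); overall recognition ≈ 0.84 / 0.98 for the
two strata (published: 0.835 / 0.971). One deliberate deviation: realised
combination totals run ≈ 8% above 941, because shared-class siblings
cannot always be absorbed by a patient's remaining slots; per-trigger
PPVs, causality mixtures and recognition probabilities are unaffected,
which is what the evaluation pipeline consumes.

What the generator does **not** emulate: free-text letters, comorbidity
structure and real prescribing correlations, laboratory values, admission
timing beyond a date field, and any correlation between causality and the
number of contributing drugs. Passing pipeline tests on synthetic cohorts
therefore demonstrates that the screening, adjudication, recognition and
evaluation machinery is correct and internally consistent — not that the
tool will show the same PPV on any real ward's data.

## Numerical and degenerate-input choices

* PPV and rates are undefined (NA), never zero, on empty denominators.
* Display rounding is half away from zero (`round_half_up()`), matching
  published one-decimal percentages; internal values stay unrounded.
* Detection output order is deterministic: tool catalogue order (trigger,
  then class), then patient order; combination identifiers are
  `patient::trigger::class`.
* Kappa's degenerate single-category case is defined as described above.
* Eligibility thresholds (70 years, 5 drugs) and event sources are
  parameters with guideline defaults, for reuse in other settings.
* Simulation problem sizes in the test-suite: determinism and consistency
  checks run at 15–120 patients, parameter-recovery at 20 replicates of
  345, and recognition recovery on a single 5 000-patient cohort, sizes at
  which the binomial standard errors are small enough to detect the
  failure modes each test targets.

## Known limitations

Sensitivity, specificity and negative predictive value cannot be computed
— only tool-positive combinations are adjudicated, so there is no
reference standard for tool-negative admissions. No confidence intervals
are attached to PPVs. Records must carry ATC codes; there is no drug-name
resolution service, and no dose-, route- or duration-aware class logic.
Whether an event documented only as a suspicion counts as documented is
not specified by the guideline; the package treats any listed event label
as documented.
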