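---
title: "Methods: ontology-aware longitudinal phenome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-aware longitudinal phenome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiphenome)
```

## The problem this package addresses

Childhood-onset epilepsies split into genetic and non-genetic
aetiologies with different comorbidity spectra, treatment patterns and
healthcare-utilization trajectories. `epiphenome` implements a
hypothesis-free, case-control phenome analysis over coded
electronic-health-record (EHR) concept streams: every ontology term a
person has ever been annotated with becomes a candidate hypothesis, and
terms are tested for association with case status cross-sectionally, by
age bin, and in medication-exposure form. Because real clinical
concept streams cannot be shared, the package pairs every analysis stage
with a seeded synthetic-EHR generator whose ground truth (planted odds
ratios, encounter-rate curves) makes the whole pipeline verifiable by
parameter recovery.

## Ontology handling

Annotations use a directed acyclic `is_a` graph parsed from OBO text
(`parse_obo()`). Only `is_a` edges are traversed; `part_of` and other
relations are ignored, the convention for phenotype reasoning over the
Human Phenotype Ontology. Obsolete terms are dropped at parse time and
`alt_id`s are resolved to primary ids before mapping, so annotations
recorded under superseded identifiers are not silently lost.

Propagation (`propagate_annotations()`) applies the true-path rule: a
person annotated with a term implicitly carries every ancestor. The age
attached to a propagated ancestor is the **minimum** age among the
descendant annotations contributing it. We chose the minimum because it
is the age of the earliest evidence of the broader phenotype, which is
what an age-binned onset analysis should see; the alternative (each
bin's own observations only) is recovered by binning before
propagation. Propagation is idempotent and makes per-term carrier
counts monotone along edges — both properties are enforced by tests.

System-level analyses use the direct children of a designated root
(`onto_children()`, e.g. the children of "phenotypic abnormality"),
and `rooted_subgraph()` extracts an organ-system subtree to report
which members are independently significant. Where a person contributes
to a system-level term only through an already-significant descendant,
we report the raw propagated counts; attribution-aware counts can be
derived from the subgraph output, and we deliberately did not fold an
attribution rule into the scan itself.

## Cohort construction

* **Eligibility** (`apply_eligibility()`): an epilepsy billing code
  (ICD-10 `G40*` or ICD-9 `345*`), any EEG procedure code, and first
  epilepsy code at age 0–5 years. EEG CPT code lists are site-specific
  and therefore configuration, not constants; the bundled fixtures use a
  stand-in code (`EEG1`).
* **Missing dates** (`drop_missing_dates()`): persons with any undated
  encounter are removed outright and reported. No imputation, matching
  the conservative handling appropriate for encounter-date corruption.
* **Concept collapsing** (`collapse_events()`): exact duplicates are
  removed, then identical codes within 30 days are merged
  *transitively* (a chain at days 0, 25, 50 is one event) keeping the
  earliest age. One month is taken as 30 days. Transitive merging was
  chosen because the artefacts being absorbed (late documentation,
  billing echoes) chain; the merge runs on identical raw codes within a
  code system, the conservative reading — merging on mapped concept id
  instead would additionally collapse cross-vocabulary synonyms.
* **Ages** are float years from the age-zero anchor; all intervals are
  half-open `[lo, hi)`.
* **Matching** (`match_cohorts()`): propensity scores from a logistic
  model of case status on sex, encounter-median age and ancestry
  (unknown ancestry is its own level), then greedy 1:1
  nearest-neighbour matching without replacement. "Median age" is the
  median over the person's encounter ages, the quantity that also
  drives the encounter-age comparisons. Cases are processed in
  descending propensity order (hardest to match first) with ties — and
  candidate-control distance ties — broken by person id, which makes the
  matching a pure function of the data, invariant to row order; no
  random numbers are consumed. Covariates without variation are
  excluded from the model (they carry no information and would make the
  logistic fit degenerate) but still appear in the balance table.

## Association machinery

`fisher_exact()` implements exact conditional inference for 2×2 tables
under the noncentral hypergeometric model:

* two-sided p-value by the point-probability rule (sum of all tables
  with the same margins whose probability does not exceed the observed
  one, with the classical `1 + 1e-7` relative tolerance);
* odds ratio as the conditional maximum-likelihood estimate, solved from
  the monotone score equation `E_psi[X] = a`; boundary tables give 0 or
  `Inf` exactly — no Haldane correction — so a table with an empty cell
  yields an honest one-sided interval with an infinite endpoint;
* 95% CI by inverting one-sided exact tests at 2.5% per tail, solved on
  the log-odds scale to tight tolerance (1e-10).

The test suite verifies all three components against an independent
`choose()`-based enumeration for **every** margin configuration up to
N = 40, and against `stats::fisher.test()` on random panels (whose CI
endpoints are solved at a coarser tolerance; agreement is checked on
the exact tail-probability scale).

`phenome_scan()` applies this machinery to a person-by-term indicator
matrix. Bonferroni families are per scan: the family size is the number
of terms actually tested in that scan, so separate vocabularies and
separate age bins correct within themselves. `min_carriers` defaults
to 1 (every observed term is a hypothesis). Depletions (OR < 1) are
reported in the same scan. Calibration studies can pass
`conf_int = FALSE` to skip estimate/CI computation.

λ diagnostics (`inflation_lambda()`) use the genomic-control
convention: p-values are converted to 1-df chi-square quantiles and the
median is divided by 0.4549364. Note that with sparse binary phenome
data, Fisher p-values are discrete and conservative, so λ well below 1
is the expected behaviour of a calibrated scan — λ near 1 is guaranteed
only for continuously distributed null p-values, which the
uniform-grid unit tests exercise. A Bonferroni threshold is reported as
`alpha / n_tests`; for a 512-test family at α = 0.05 this is
9.77 × 10⁻⁵ (we always compute the quotient rather than matching any
externally rounded constant).

## Longitudinal analyses

Observation age bins follow the ILAE nosology groups:
neonatal/infantile `[0, 2)`, childhood `[2, 12)`, juvenile `[12, 18)`,
adult `[18, ∞)`. The "2–12"-style notation is ambiguous at the
boundary; we assign boundaries upward (age 2.0 is childhood), keeping
the bins a partition.

`binned_scan()` re-runs the phenome scan per bin, where a person
carries a term in a bin iff any (possibly propagated) observation falls
in it. `trajectory_matrix()` reshapes per-bin log ORs into a term ×
bin grid (non-significant cells blank; boundary log ORs capped at
±log 100 so heatmaps and distances stay finite), and
`cluster_trajectories()` groups rows with Ward (ward.D2) agglomeration
on Euclidean distance, missing cells treated as 0. Ward/Euclidean is
the default because trajectories are small dense vectors on a common
scale; merge heights are verified against a Lance–Williams
implementation in the tests.

`transition_window()` scans 2-year sliding windows over ages 12–22 (a
range bracketing the paediatric-to-adult care handover) for the largest
case/control ratio of mean annual encounter counts among persons
observed in the window, with a Welch t-test inside the peak window.
Ties take the earliest window; windows with fewer than two observed
persons per group are skipped. Annual counts are not prorated for
partial observation years; persons contribute only to age-years they
were observed in. `window_concept_enrichment()` compares concept
presence during versus before the window, within each group separately,
restricted to persons observed in both periods (requiring both periods
is the stricter convention; the alternative — all persons — inflates
in-window denominators for late entrants).

Utilization contrasts use Welch t-tests for counts and means; cost
comparisons use Wilcoxon rank-sum tests (exact below a combined n of
20, tie-corrected normal approximation otherwise) because encounter
costs are heavily right-skewed. Admission-frequency contrasts condition
on at least one admission of that type.

## Medication analyses

Prescriptions are normalized to generic names with a
mechanism-of-action class and a rescue (benzodiazepine) flag; the
bundled `asm_dictionary()` is an editable starting point, not a
formulary. A drug enters the binned prescription scan only if
prescribed to at least 1% of the cohort, implemented as
`ceiling(0.01 × cohort size)` distinct exposed persons (6 of 503).
Exposure is any prescription event; dose and duration are out of scope.
`unique_asm_count()` counts distinct anti-seizure medications per
person; `rescue_prescription_count()` counts *events* in the rescue
class. The concept "long-term drug therapy" is treated as an ordinary
coded concept (it arrives with a concept id), not derived from
prescription records.

## Two-stage replication

Odds ratios are mapped to point-biserial correlations in two standard
steps: `d = ln(OR)·√3/π` (logistic latent-variable standardized
difference), then `r = d/√(d² + 4)` (equal-group-size conversion). The
map is odd in `ln(OR)`, strictly increasing, and bounded, with
boundary ORs 0/∞ mapping to ∓1, so replication summaries are insensitive
to infinite boundary estimates. We define `sign(r) = sign(ln OR)`
throughout; summaries of published effect lists that use a different
sign convention (e.g. negative mean r under predominantly enriched
effects) cannot be reproduced from ORs alone, so the package reports
all counts and denominators explicitly rather than committing to an
unstated convention.

Direction concordance counts sign agreement of `ln OR` among stage-1
nominal (p < 0.05) pairs; an OR of exactly 1 in either stage is not a
match. CI coverage asks whether the stage-1 point estimate lies in the
stage-2 95% CI, evaluated on the bounded r scale (the conversion is
monotone, so OR-scale evaluation — available by converting inputs —
differs only at infinite endpoints). Pairs untested in stage 2 are
excluded, never imputed. Percentages are rounded to 2 decimals by
`pct()`.

## The synthetic-EHR generator

`simulate_cohort()` draws, per person: demographics from category
frequencies; an observation window (first encounter age uniform on
[0, 0.4] years, follow-up span gamma with mean 8.2 and SD 5 years,
truncated at age 22 — chosen to match a paediatric cohort followed into
early adulthood with ~8 years' mean follow-up); encounter ages from a
piecewise-constant Poisson process with per-group rate curves and a
case-specific 1.7× rate bump at ages 18–20 (the transition-period
signature); log-normal costs per setting (outpatient median $370,
sdlog 0.29, with a ~1.054× case multiplier); and catalogue-based
prescriptions calibrated to means of ≈4.5 vs ≈3.2 unique ASMs and ≈12
vs ≈8 rescue prescriptions per person.

Concept annotations are generated in two layers. Each person first
receives a latent **carrier** set: each phenotype leaf term
independently with its baseline prevalence (default 0.05) in controls
and an odds-scaled probability in cases for planted effects
(`p'/(1−p') = OR · p/(1−p)`). Planting at the person level makes the
planted OR exactly the estimand of the cross-sectional scan, which is
what parameter-recovery tests require; effects are planted on leaf
terms only, so ancestor enrichment emerges through propagation rather
than being planted twice. Per encounter, a negative-binomial number of
concept slots (group-specific mean; size 3) is split between the
carrier set and a "routine concept" pool with Zipf-like weights, and
every carrier term is forced to appear at least once (inside its age
bin for bin-restricted effects), so observed carriers equal true
carriers. Age-bin-restricted effects are expressed only inside their
bin.

A single global seed fans out into one RNG substream per person, so any
subset of persons can be regenerated exactly. Ages are emitted at 1e-6
year resolution so that text fixtures round-trip bit-exactly.

What the generator does **not** emulate: clinical free text, calendar
seasonality, informative dropout, code-system migration artefacts, and
correlated comorbidity structure beyond what propagation induces.
Passing recovery tests therefore demonstrates the statistical machinery
is correct and calibrated under the stated generative model — not that
the pipeline is robust to every real-EHR pathology.

`null_config()` equalizes every group-dependent parameter and plants
nothing, so any downstream association is a false positive; the
family-wise error of the full scan is checked against the Bonferroni
bound over replicates.

## Problem sizes used by the verification studies

The calibration studies run at the sizes they state: family-wise error
over 200 replicates of a 500-term ontology with 200 persons per arm;
planted-OR coverage (OR 3, baseline prevalence 0.2) over 200 replicates
of 1000 persons per arm on a 40-term ontology with a lightweight
encounter stream (flat rate 1/year, mean follow-up 4 years — the
cross-sectional scan depends only on carrier status, so encounter
volume is a nuisance dimension); transition recovery over 100
replicates of 250 per arm observed over the full 0–22-year range with a
flat 3.63/year base rate. The exhaustive Fisher verification covers
every margin configuration to N = 40 for p-values and every table to
N = 16 (plus a seeded larger sample) for estimates and intervals.

## Numerical choices and degenerate inputs

* Degenerate 2×2 tables (an empty margin) return p = 1 with undefined
  OR/CI rather than erroring, so scans over sparse terms never abort.
* p-values of exactly 0 are clipped to the smallest positive double in
  λ computation, with a warning.
* `welch_t_test()` returns t = 0, p = 1 for two constant equal samples
  and p = 0 for constant separated samples.
* Matching with fewer controls than cases returns the maximal partial
  matching with a warning.
* All-missing trajectory rows are excluded from clustering with a
  warning; ties in agglomeration follow `stats::hclust`'s deterministic
  lowest-index convention.
* Pipeline tables print floats at 6 significant digits; re-running with
  an identical config byte-reproduces every table.

## Known limitations

The propensity matching is greedy rather than optimal; with heavy
covariate overlap this is standard practice, but pathological orderings
can leave avoidable distance on the table. The generator's routine-pool
mechanism gives cases and controls different annotation *volumes* under
the default (non-null) configuration, which is realistic but means the
default configuration must not be used for false-positive-rate studies
— that is what `null_config()` is for. Fisher p-values over rare terms
are conservative, so the scan's power at very low prevalence is limited
by design rather than by implementation.
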