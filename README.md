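# epiphenome

Ontology-aware, longitudinal case-control phenome analysis of coded
electronic-health-record (EHR) concept streams, built for studies that
contrast genetic against non-genetic childhood-onset epilepsy but
applicable to any matched case-control cohort with ontology-mapped
encounter data.

For whom: biostatisticians and clinical informaticians who have (a) an
ontology in OBO format, (b) a mapping from source codes to ontology
terms, and (c) person/event/encounter/prescription tables, and who want
a tested, reproducible pipeline from raw coded events to
phenome-wide association results, age-binned trajectories,
healthcare-utilization contrasts, medication-pattern scans and
two-stage replication summaries.

## What it computes

For each ontology term *t*, person-level presence/absence after
true-path propagation (a person annotated with *t* carries every
ancestor of *t*) yields a 2×2 table against case status

|            | carrier | non-carrier |
|------------|---------|-------------|
| cases      | a       | b           |
| controls   | c       | d           |

tested by Fisher's exact test with the **conditional maximum-likelihood
odds ratio** under the noncentral hypergeometric model: the OR solves
E<sub>ψ</sub>[X] = a on the margin-conditioned support, the 95% CI
inverts one-sided exact tests at 2.5% per tail, and boundary tables
yield OR 0 or ∞ with one-sided intervals. P-values are
Bonferroni-corrected within each scan family, and calibration is
summarized by the genomic-control inflation factor
λ = median(χ²(p)) / 0.4549.

Longitudinal structure uses the ILAE-style observation bins [0,2),
[2,12), [12,18), [18,∞) years: per-bin scans, term × bin log-OR
trajectory matrices with Ward clustering, a sliding-window detector for
the paediatric-to-adult transition bump in encounter rates, and
per-bin anti-seizure-medication (ASM) exposure scans with a
1%-of-cohort prevalence filter. Two-stage designs are summarized by
effect-direction concordance, CI coverage and Pearson correlation on
the bounded point-biserial scale, r = d/√(d²+4) with d = ln(OR)·√3/π.

A seeded synthetic-EHR generator (`simulate_cohort()`) with planted
term-level odds ratios and a configurable age-18–20 encounter-rate bump
makes every stage verifiable by parameter recovery; `null_config()`
gives a fully symmetric null for family-wise-error calibration.

## Worked example

```r
library(epiphenome)

# simulate a discovery-scale cohort with two planted effects
g <- simulate_ontology(n_terms = 120, n_filler = 10, seed = 42)
leaves <- attr(g, "roles")$term[attr(g, "roles")$role == "leaf"]
cfg <- sim_config(n_cases = 259, n_controls = 244, seed = 42,
                  ontology = g,
                  planted_effects = tibble::tibble(
                    term = leaves[1:2], or = c(3, 0.3)))
sim <- simulate_cohort(cfg)

scan <- scan_simulation(sim)    # map -> propagate -> matrix -> scan
head(tidy(scan), 3)
#> # A tibble: 3 × 12
#>   term        name      a     b     c     d    or ci_low ci_high        p  p_adj
#> 1 SIM:0000129 <NA>    245    14   206    38  3.22   1.65    6.62 0.000204 0.0269
#> 2 SIM:0000131 <NA>    233    26   191    53  2.48   1.46    4.30 0.000352 0.0464
#> 3 SIM:0000133 <NA>    224    35   180    64  2.27   1.41    3.71 0.000466 0.0615
glance(scan)[, c("n_tests", "lambda", "bonferroni_threshold", "n_significant")]
#> # A tibble: 1 × 4
#>   n_tests lambda bonferroni_threshold n_significant
#> 1     132  0.903             0.000379             2

tidy(scan)[tidy(scan)$term %in% leaves[1:2],
           c("term", "a", "c", "or", "ci_low", "ci_high")]
#> # A tibble: 2 × 6
#>   term            a     c    or ci_low ci_high
#> 1 SIM:0000033    31    12 2.62  1.27     5.76
#> 2 SIM:0000037     4    13 0.279 0.0654   0.921
```

Both planted leaves are recovered with exact CIs covering the truth
(2.62 for a planted 3; 0.279 for a planted 0.3). The top-ranked terms
here are "routine encounter" concepts: under the default configuration
cases have more annotations per encounter, so visit-level concepts
become case-enriched — the utilization signal the generator plants on
purpose. λ = 0.90 on 132 discrete exact tests indicates a calibrated,
slightly conservative scan. The transition detector on the same cohort:

```r
tw <- transition_window(sim$persons, sim$encounters)
tw$best[, c("lo", "hi", "ratio", "p")]
#> # A tibble: 1 × 4
#>      lo    hi ratio      p
#> 1    17    19  1.71 0.0215
```

Under the default follow-up distribution only a minority of persons are
still observed past age 18, so the peak window [17, 19) only overlaps
the planted 18–20 bump; with full observation of the age range
(`followup = list(full = TRUE)`) the detector recovers [18, 20) in
essentially every replicate (see the acceptance study). An end-to-end
run over files (eligibility screen,
missing-date exclusion, 30-day concept collapsing, propensity
matching, all scans and tables):

```r
write_fixtures(sim, "cohort_dir")
res <- run_pipeline(list(input_dir = "cohort_dir", output_dir = "out",
                         seed = 1))
```

which writes `associations.tsv`, `binned_associations.tsv`,
`trajectory_matrix.tsv`, `utilization.tsv`, `transition_report.tsv`,
`asm_bin_matrix.tsv`, a JSON manifest, and friends. `autoplot(scan)`
draws the QQ plot; `plot_trajectory_heatmap()` and
`plot_annual_encounters()` cover the longitudinal figures.

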