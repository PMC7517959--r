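# pdactrials

Census and Impact Scoring of the pancreatic cancer clinical-trial
landscape.

Pancreatic ductal adenocarcinoma (PDAC) remains without a
paradigm-changing therapy beyond multi-agent chemotherapy, so the
registered interventional-trial pipeline is the best available evidence
for what may change practice next. `pdactrials` is for meta-researchers
and trialists who want that landscape analysis to be reproducible: it
curates a registry snapshot through an explicit filter funnel, expands
multi-arm trials into per-intervention records, tabulates census tables
over controlled taxonomies (therapeutic category, mechanism of action)
with the rendering conventions such tables actually use, and ranks
late-phase trials with an additive eight-criterion **Impact Score**.

## The model in brief

* **Curation funnel.** Interventional trials in phases I–III with status
  recruiting / active-not-recruiting / enrolling-by-invitation, minus
  pancreatic-NET and non-therapeutic studies. Exclusions are attributed
  to the first failing rule in a fixed order, and the funnel conserves
  counts by construction.
* **Census tables.** For each facet *f* and denominator *N*, a table row
  is (code, count *n*, exact percentage 100·*n*/*N*, rendered
  percentage). Rendering is either *half-up* rounding to a 1 or 0.5
  grid (with a `< 1%` floor), or *largest-remainder* apportionment:
  floor every cell to the grid, then grant leftover steps by decreasing
  fractional remainder until the row sums to its target (100, or the
  parent row's rendered value).
* **Impact Score.** For trial *i* with level ℓ<sub>ic</sub> on criterion
  *c*, IS<sub>i</sub> = Σ<sub>c</sub> points(*c*, ℓ<sub>ic</sub>) over
  the eight criteria (novelty 5/2/1/0; promise ±2; allocation ±1; PFS
  and OS improvement 2/1/0; susceptible fraction 3/2/1; desired impact
  3/1/0; status 0/−5), so IS ∈ [−7, 18]. Survival deltas (months) and
  susceptible fractions are binned with strict `>` thresholds and closed
  middle ranges.
* **Synthetic registry generator.** Seeded quota sampling that hits the
  snapshot marginals exactly (430 trials, 590 interventions, 515
  systemic therapies, 41 + 10 decoys), so the full pipeline is testable
  offline.

## Worked example

```r
library(pdactrials)

# A full-scale synthetic snapshot: 481 records, curated to 430.
reg     <- generate_registry(generator_config(seed = 1))
curated <- apply_filters(reg)
glance(curated)
#> # A tibble: 1 × 3
#>   input_count excluded output_count
#>         <int>    <int>        <int>
#> 1         481       51          430

tabulate_landscape(curated, "phase")
#> # Landscape table: facet=phase denominator=trials total=430
#>   code   label        depth count exact_pct rendered_pct
#> 1 I      Phase I          0   134     31.2  31%
#> 2 I_II   Phase I/II       0    94     21.9  22%
#> 3 II     Phase II         0   165     38.4  38%
#> 4 II_III Phase II/III     0     5      1.16 1%
#> 5 III    Phase III        0    32      7.44 7%

# Largest-remainder rendering makes the row sum to 100 (note 32/430 -> 8):
render_percentages(c(134, 94, 165, 5, 32), 430,
                   mode = "largest_remainder", target_total = 100)
#> [1] "31%" "22%" "38%" "1%"  "8%"

# Rank the packaged 37-trial late-phase compendium by Impact Score.
ranked <- rank_trials(score_assignments(phase3_assignments()))
head(ranked[c("registry_id", "total", "rank")], 3)
#>   registry_id total rank
#> 1 NCT03377491    15    1
#> 2 NCT03504423    13    2
#> 3 NCT03126435    11    3
```

The top-ranked trial is the tumor-treating-fields study PANOVA-3
(15 of 18 points: novel mechanism in PDAC, prior phase III success in
another cancer, non-randomized historical control, +4.6-month PFS and
+8.2-month OS deltas, broadly applicable, directly treating, active);
AVENGER 500 (devimistat + mFOLFIRINOX) follows at 13.

A census-table figure is one call away: `autoplot(tabulate_landscape(...))`.

## Package tour

| Area | Functions |
| --- | --- |
| Registry IO | `read_registry()`, `write_registry()`, `as_trials()`, `validate_trials()` |
| Curation | `filter_spec()`, `apply_filters()`, `expand_interventions()`, `group_phase3()` |
| Census | `tabulate_landscape()`, `systemic_filter()`, `render_percentages()`, `round_percentages()` |
| Impact Score | `impact_rubric()`, `bin_survival_delta()`, `bin_susceptibility()`, `score_assignments()`, `rank_trials()` |
| Synthetic data | `generator_config()`, `generate_registry()`, `generate_assignments()`, `census_quotas()` |
| Pipeline / CLI | `run_curate()`, `run_aggregate()`, `run_score()`, `run_generate()`; `inst/cli/pdactrials.R` |

Fixtures under `inst/extdata/` are plain text; the per-trial rubric
assignments beyond the two published worked examples are synthetic
reconstructions (see `?phase3_assignments` and the methods vignette,
`vignettes/landscape-methods.Rmd`).
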