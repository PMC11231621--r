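# rnteract

Nursing workload is hard to measure: nurse-patient ratios ignore what care
actually happened, and time-motion studies are subjective, intrusive
snapshots. EHR audit logs — the user-level metadata hospitals must keep
(who accessed which record, what was read or entered, when, and from which
workstation) — offer a scalable, unobtrusive proxy for the documentation
side of that workload. But raw audit logs are unstructured streams;
`rnteract` structures them into a nurse-centric logical data model so that
temporal machine-learning methods can be applied, and ships every step of a
reference analysis pipeline around it.

The package is for clinical-informatics and nursing-workforce researchers
who want to mine audit-log extracts (or prototype against simulated ones)
for charting-pattern archetypes and their association with nurse outcomes
such as resignation or missed work.

## The model

Four vector families, all governed by reconfigurable value sets:

- **NTask** — per nurse *k*, a temporal vector `⟨NTask(k, i)⟩, i = 1..N`
  over a fixed-resolution time grid (a day, an hour, 30 minutes, …); each
  element is a task code from a task value set, by default
  `1 = no EHR interaction, 2 = read EHR data, 3 = input EHR data`. Empty
  intervals are idle; multi-action intervals resolve by a configurable
  priority (input > read by default).
- **NType** — a static vector of dimension *M* of intrinsic/situational
  nurse characteristics (employment years, accreditation, average weekly
  hours and primary assignment — the latter two derivable from the audit
  log itself).
- **NPanel** — a static vector of dimension *O* summarising the assigned
  patient panel (ER/OR admissions, discharges home, average length of stay).
- **NOutcome** — a static vector of dimension *P* of longer-term outcomes
  (salary increase, resignation, promotion as YES/NO; missed work days).

Static families are deliberately time-independent (they vary far more
slowly than NTask), and categorical/boolean elements can be rendered
numeric by an injective table transformation, so the whole model is
consumable by any ML method.

On top of the model the package implements one reference analysis:
k-medoids (PAM: greedy BUILD seeding, best-improvement swaps, deterministic
multi-start) on positionwise Hamming distances between aligned NTask
sequences, silhouette-based choice of k, and a per-cluster
enrichment/depletion screen — Fisher exact tests for discrete properties,
seeded permutation tests for numeric ones, Benjamini-Hochberg FDR across
the full set — plus cluster-conditional outcome rates with Wilson
intervals as the baseline predictor. A seeded simulator plants
block-charting vs continuous-charting archetypes with archetype-dependent
outcome rates so the whole pipeline is testable without protected data.

## Worked example

Encoding the canonical five-period scenario — nurse 55 reads the EHR in
period 1, does nothing with it in periods 2–4, then writes a note in
period 5:

```r
library(rnteract)

vs   <- default_task_value_set()
grid <- time_grid("2024-03-04 07:00:00", "1 hour", 5)
events <- tibble::tibble(
  nurse_id    = 55L,
  timestamp   = grid$start + c(10 * 60, 4 * 3600 + 10 * 60),
  action      = c("read EHR data", "input EHR data"),
  section     = c("flowsheet", "notes"),
  location_id = "OR-WS1")

build_ntask(events, grid, vs)
#> <NTask (55, 2, 1, 1, 1, 3)>
```

The printed tuple carries the nurse id followed by the N task codes: read
(2) in the first interval, idle (1) in the next three, input (3) in the
last.

A full simulated analysis — 60 nurses, half continuous charters and half
block charters:

```r
cfg    <- sim_config(n_nurses = 60, seed = 1)
bundle <- simulate_cohort(cfg)
cohort <- encode_cohort(bundle$events, cfg$grid, hr = bundle$hr,
                        hr_events = bundle$hr_events, adt = bundle$adt,
                        window = cfg$window)

fit <- cluster_trajectories(trajectory_distances(cohort), k = 2, seed = 1)
glance(fit)
#> # A tibble: 1 × 6
#>       k objective silhouette iterations  seed     n
#>   <int>     <dbl>      <dbl>      <int> <int> <int>
#> 1     2       397      0.472          9     1    60

cluster_conditional_rates(fit, cohort, "resignation")
#> # A tibble: 2 × 5
#>   cluster     n   rate  ci_lo ci_hi
#>     <int> <int>  <dbl>  <dbl> <dbl>
#> 1       1    30 0.0667 0.0185 0.213
#> 2       2    30 0.6    0.423  0.754
```

The two recovered clusters match the planted archetypes exactly
(adjusted Rand index 1 against the simulator's truth labels), and the
block-charting cluster (cluster 2) carries the planted elevated
resignation rate — `enrichment_report(fit, cohort)` ranks that property
among the top enrichments at q < 1e-4, alongside the home-unit contrast in
`primary_assignment`. `autoplot(fit, cohort)` draws the trajectory heatmap;
`autoplot()` on the enrichment report gives the effect-vs-q overview.

The same stages are scriptable from a shell via the thin CLI wrapper:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "rnteract.R", package = "rnteract"))')" \
  simulate --config run.yaml --out sim
```

with `encode`, `cluster`, `enrich` and `report` following the same pattern;
real audit extracts replace the simulator at the `encode` boundary.

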