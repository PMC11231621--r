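---
title: "Methods: modelling nurse-EHR interactions from audit logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling nurse-EHR interactions from audit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnteract)
```

## The modelling problem

EHR audit logs record every user-level interaction with the health record:
what was accessed, whether data were reviewed or entered, when, and from
which workstation. For nurses this stream is a scalable, unobtrusive proxy
for the documentation component of workload — but it arrives as an
unstructured event list with no task taxonomy. `rnteract` imposes a
nurse-centric structure on it: a temporal task vector per nurse plus three
static attribute vectors, each element governed by an explicit value set so
the model can be as coarse or as granular as a study needs.

- **NTask(k, i)**, i = 1..N: one task code per time interval on a fixed
  grid. Intervals are half-open `[t, t + Δ)` — a convention the data leave
  open; half-open intervals guarantee each event lands in exactly one
  interval, and a boundary timestamp belongs to the later one.
- **NType / NPanel / NOutcome**: static tuples of nurse characteristics,
  patient-panel features and long-term outcomes. These are modelled as
  time-independent because their variation is much slower than the
  interval-level task signal; the cohort stores exactly one tuple per nurse
  per family.

Two NType elements are derived from the log itself. *Average weekly hours*
sums, per calendar day in the log's timezone, the span between the first
and last interaction, aggregates by ISO week, and averages over weeks with
activity; overnight work therefore splits at midnight, a deterministic
convention chosen so the quantity is well-defined from timestamps alone.
It is a lower bound on true hours — it sees only documented activity.
*Primary assignment* is the modal unit among mapped workstations, with a
lexicographic tie-break for determinism.

Several interval-level events must collapse to one code. The resolver uses
a configurable priority order, by default input > read > idle: when a nurse
both reviews and documents within one interval, the documentation action —
the workload signal of interest — wins. An empty interval is the idle code
(code 1). Whether "no EHR interaction" means off-shift or
on-shift-but-not-documenting is not distinguishable from the log; the model
treats the two identically unless the caller restricts the grid to shift
windows.

One deliberate representation choice: the nurse id is *not* part of the
mathematical payload. The display form `(55, 2, 1, 1, 1, 3)` prepends the
id to the N codes purely as a serialisation convention
(`to_printed_tuple()` / `parse_printed_tuple()`); distances and clustering
operate on the codes alone.

Missing data are first-class: audit logs carry little about the nurse
beyond the id, and auxiliary HR/ADT sources may be absent, so absent
elements are explicit `NA`s, never imputed. The NType hours element stores
the measured value; a binned representation is possible through a
user-supplied table transformation but is not a default, since no canonical
binning exists. Average length of stay in the default NPanel schema is
declared integer and rounded half-to-even. Panel size is not a default
schema element (it is not part of the default value set); users can add it.

## Clustering trajectories

Task codes are categorical on an aligned grid, so the minimal faithful
dissimilarity is the positionwise Hamming distance — the count of intervals
in which two nurses' codes differ. The `method` argument of
`trajectory_distances()` is the declared plug-in point for alternatives
(e.g. an edit distance if grids were ever unaligned).

Patterns are recovered with k-medoids (PAM) rather than a centroid method:
medoids are actual nurses, so every "archetypical activity pattern" the
model reports is an exhibitable trajectory. The implementation is fully
deterministic:

1. **BUILD seeding** — the first medoid minimises total distance; each
   subsequent medoid maximally reduces the objective, ties to the smallest
   id. (An alternative max-min spread seeding was considered and rejected:
   it tends to seed on outliers, and on small instances it can strand the
   swap phase in a local optimum that best-improvement swaps cannot leave.)
2. **Swap phase** — best-improvement swaps of a medoid against a non-medoid
   until no swap lowers the total within-cluster distance to medoids; the
   objective is non-increasing by construction.
3. **Deterministic multi-start** — because the swap phase is a local
   search, the descent is repeated with each of the `n_starts = 5`
   smallest-total-distance points as first medoid, and the best objective
   wins. On random instances with n ≤ 8 this reproduces the exhaustive
   optimum over all medoid sets (verified in the test suite against
   brute-force enumeration for k = 2 and k = 3).

The number of clusters, when not fixed by design, is chosen by maximising
the mean silhouette width (computed by definition from the distance matrix;
singletons get width 0) over a candidate range, ties to the smallest k. An
all-identical cohort makes the silhouette degenerate; the smallest
candidate is returned with a warning. Partition agreement is measured by
the adjusted Rand index, implemented from the pair-counting formula.

## Enrichment, depletion and the baseline predictor

Each (cluster, static property) pair is tested for over- or
under-representation against the rest of the cohort:

- **Boolean properties**: two-sided Fisher exact test on the in/out × YES/NO
  table. Exactness matters because clusters can be small.
- **Categorical properties**: one-vs-rest per level, so every level gets its
  own interpretable enriched/depleted verdict rather than an omnibus p.
- **Numeric properties**: a seeded permutation test of |mean_in − mean_out|
  with p = (1 + #{permuted ≥ observed}) / (n_perm + 1) — exact-valid,
  assumption-light, and deterministic given the seed (each test in a report
  uses a distinct seed offset).

The *effect* is the plain difference of proportions or means
(in-cluster minus out-cluster); a ratio can be derived from the reported
counts if preferred. Direction is "enriched" when the effect is positive,
and a zero effect is reported as enriched by a fixed tie rule so output is
deterministic. Because the report is a screen across many tests, not a
confirmatory analysis, multiplicity is handled with Benjamini–Hochberg FDR
across the full result set.

`cluster_conditional_rates()` is the reduction of "predictive modelling per
cluster" to its honest baseline: predict a new nurse's outcome by the
empirical rate of the cluster their trajectory falls into, with Wilson 95%
intervals for boolean outcomes (the Wilson bounds are pinned to exactly
0/1 at degenerate counts to avoid floating-point cancellation). Richer
models can replace this baseline behind the same interface; none ship, by
design.

## What the simulator emulates

The simulator exists to make every downstream claim testable without
protected data. Each nurse draws an archetype from a mixture; the archetype
drives

- a **first-order Markov chain** over the task states per interval — the
  simplest generator that produces the contrast of interest between
  charting throughout a shift and charting in a terminal block;
- an optional **burst rule** forcing the final `ceiling(f·N)` intervals to
  a given state (the block charter's end-of-shift documentation block);
- **event emission**: each non-idle interval emits `1 + Poisson(rate − 1)`
  events with that interval's action label, timestamps uniform within the
  interval, and workstations drawn with 0.9 probability from the home
  unit. Because idle intervals emit nothing and active intervals emit at
  least one correctly-labelled event, encoding the emitted events on the
  same grid reproduces the planted state sequence *exactly* — the central
  self-consistency oracle of the package;
- **static draws**: Bernoulli booleans at archetype-specific rates realised
  as dated HR events, Poisson missed days realised as distinct absence
  dates, Poisson ADT counts with gamma lengths of stay.

Defaults (chosen once as a realistic study scale, stated here as the
package's own choices): 60 nurses, an even two-archetype mixture, a
24 × 30-minute grid (one 12-hour shift), rate 2 events per active
interval, a 28-day outcome window. The two shipped archetypes are the
*continuous charter* (input-dominant transition rows, home unit ICU) and
the *block charter* (idle-dominant rows with a forced input burst over the
final 20% of the shift, home unit OR). Resignation probabilities of 0.60
(block) vs 0.05 (continuous) plant a strong, recoverable outcome contrast;
the remaining outcome rates and missed-day means are milder illustrative
contrasts — the strength of any real association between charting pattern
and outcomes is precisely the open scientific question this tooling is
meant to study, not a claim the defaults encode.

What the simulator does *not* emulate: patient-level trajectories,
multi-nurse interactions, shift rotations or seasonality, vendor-specific
audit schemas, or realistic marginal distributions of HR attributes.
Passing tests therefore demonstrate internal correctness of the encoding,
clustering and testing machinery under a controlled generative model — not
that real audit logs contain recoverable archetypes of this shape.

## Numerical and testing choices

- Problem sizes in the test suite are chosen to keep oracles exhaustive
  where possible: brute-force Hamming recomputation at n = 5, exhaustive
  medoid enumeration at n ≤ 8, full permutation enumeration at n = 6,
  complete 2×2 table enumeration for all margins ≤ 12. Stochastic
  properties use 20 seeded replicates (archetype and effect recovery) or
  1000 replicates (permutation-test calibration at nominal level 0.05,
  accepted within [0.03, 0.07]).
- Fisher two-sided p sums hypergeometric point probabilities ≤ the observed
  one; the test oracle allows 1e-12 absolute slack on that comparison,
  which at these margins is far below the spacing of distinct
  probabilities, so ties are classified exactly.
- The PAM swap acceptance uses a 1e-12 strict-improvement margin so
  floating-point noise cannot cycle; distances are integers here, so the
  margin is purely defensive.
- Seeds: `simulate_cohort()` derives everything from one config seed via a
  scoped RNG (`withr::with_seed`), so bundles are byte-reproducible and the
  caller's RNG state is untouched. Pipeline artifacts are stamped with the
  seed and a config hash.

## Known limitations

- Hamming distance ignores temporal adjacency: a pattern shifted by one
  interval is maximally distant. For studies of timing offsets an
  alignment-aware distance should be plugged in.
- The enrichment screen tests each property marginally; correlated
  properties (e.g. home unit and archetype, both archetype-driven in the
  simulator) will co-signal.
- Hours-per-week from first/last daily interactions underestimates true
  hours and is sensitive to isolated off-shift log-ins.
- The CLI and cohort bundle formats are deliberately plain (CSV + JSON
  sidecar); very large cohorts would warrant a columnar store, which is out
  of scope here.
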