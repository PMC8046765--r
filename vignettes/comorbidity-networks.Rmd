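---
title: "Chronological comorbidity networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronological comorbidity networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidnet)
```

This vignette is the package's own account of the science it implements:
the chronological relative-risk model and its assumptions, the network
summaries built on it, the map-equation community objective, the synthetic
cohort generator used for validation, and the numerical and design choices
made where the problem left them open.

## 1. From encounters to chronology

The raw input is a longitudinal diagnosis table: one row per coded diagnosis
per clinical encounter (`patient_id`, optional `birth_date`, `event_date`,
`icd9_code`). Preprocessing proceeds in a fixed order:

1. **Three-digit collapsing.** ICD-9 codes are truncated to their category:
   numeric codes keep the (zero-padded) digits before the decimal, V codes
   keep `V` + two digits, E codes keep `E` + three digits. Category-level
   codes trade specificity for statistical support and capture outpatient
   comorbidity better than coarser groupings.
2. **Follow-up filter.** Only patients whose earliest-to-latest encounter
   span is at least `min_followup_years` (default 5) are retained, so every
   patient contributes a comparable observation window. The span uses *all*
   encounters, including non-diagnostic V codes, because follow-up is a
   property of contact with the health system, not of any particular
   diagnosis. Years are days/365.25 throughout; no other year convention is
   defined by the problem.
3. **First occurrences.** For each patient and code, the earliest event date.
   Only first occurrences define chronology; repeat encounters are ignored.
4. **Network exclusions.** V codes (health-service contact, not disease),
   pregnancy/childbirth codes 630–679 (the emulated cohort excludes women of
   childbearing potential), symptoms/signs/ill-defined conditions 780–799,
   and unclassified complications 996–999 are removed from the *network*;
   the descriptive prevalence table keeps them. E codes (external causes)
   are retained through the exclusions — they are not on the exclusion
   list — but in practice essentially never reach 10 % prevalence, so the
   choice is documented rather than consequential.
5. **Prevalence filter.** A code enters the network only if at least
   `prevalence_threshold` (default 10 %) of the retained cohort has a first
   occurrence of it; the boundary is inclusive. Exclusions are applied
   before prevalence, so the threshold is evaluated only for codes that
   could enter the network.

Applying the collapsing or the filters twice equals applying them once; the
test suite asserts this idempotence along with order-invariance of the
first-occurrence extraction.

## 2. The chronological relative risk

For an ordered pair *(i, j)* each cohort patient falls into exactly one of
six categories by comparing first-occurrence dates: `N(i→j)` (*i* strictly
first), `N(i→~j)` (*i*, never *j*), `N(j→i)`, `N(~i→j)` (*j*, never *i*),
`N(~i&~j)`, and the *coincident* group (same-day first occurrences), which
enters neither numerator nor denominator. The statistic is

$$RR(i,j)=\frac{N(i\to j)\,/\,\bigl(N(i\to j)+N(i\to\sim j)\bigr)}
{\bigl(N(\sim i\to j)+N(j\to i)\bigr)\,/\,\bigl(N(\sim i\to j)+N(j\to i)+N(\sim i\,\&\sim j)\bigr)}.$$

The comparator pools patients who developed *j* without a *prior* *i* —
those who never had *i* and those whose *i* came later — against those with
neither code. Edge cases: if no patient ever has *i* the entry is undefined
(`NA`); if the comparator risk is zero while the exposed risk is positive
the entry is `+Inf` and still creates an edge (RR > 1), with its weight
capped at the maximum finite entry of the matrix so weighted computations
stay finite without changing topology. No minimum pair count is imposed
beyond the prevalence filter, deliberately, so that genuinely strong
relationships among moderately common codes are not discarded; and no
significance screening is applied — the edge rule is RR > 1, exposed as a
configurable threshold defaulting to 1.

### What the statistic is *not*: a calibrated null

The two fractions measure risk over different windows: the exposed fraction
conditions on carrying *i* and counts *j* only in the follow-up remaining
after the first *i*, while the comparator counts *j* anywhere in follow-up.
Under independence (no hazard interaction) this asymmetry biases RR *below*
1. For two independent codes with per-patient lifetime prevalence $q$ and
exchangeable ordering, the expected categories give

$$RR_{\text{null}} \approx \frac{1-q+q^2/2}{\,2-2q+q^2/2\,},$$

which is ≈ 0.52 at $q = 0.3$, ≈ 0.92 at $q = 0.95$, and approaches 1 only
as $q \to 1$, where the statistic degenerates. The acceptance suite
measures exactly this: on ten independent-hazard cohorts (2000 patients, 20
codes, per-timestep hazard 0.02, 10–16-year follow-up, prevalence ≈ 95 %)
the median defined RR is ≈ 0.92 — inside the broad [0.8, 1.25] calibration
band, but *systematically* below 1: essentially every defined null pair
falls under 1, so a sign-balance test around 1 fails by construction. The
practical consequence is conservative and direction-sensitive behaviour:
under moderate prevalence an RR > 1 edge requires a genuine directional
excess, not mere co-occurrence. Users comparing edge counts across cohorts
with different prevalence profiles should keep this null drift in mind.

## 3. The directed graph and its summaries

Nodes are the retained codes (isolated nodes are kept — a code can pass the
prevalence filter yet have no RR > 1 relationship); edges are ordered pairs
with RR > 1, weighted by RR. All summaries are computed from first
principles in the package and validated against brute-force oracles and
independent igraph implementations in the tests:

* **Edge density** — `n_edges / (n_nodes · (n_nodes − 1))`: the fraction of
  possible directed relationships realised (self-loops are impossible).
* **Reciprocity** — the fraction of edges whose reverse edge also exists,
  i.e. pairs elevated in both directions.
* **Diameter** — the longest unweighted shortest directed path over
  reachable ordered pairs, by breadth-first search from every node;
  unreachable pairs are ignored and one realizing path is reported.
* **Hub and authority scores** (Kleinberg HITS) — alternating power
  iteration `authority ← Aᵀ·hub`, `hub ← A·authority` with per-step
  normalisation, deterministic uniform initialisation, and final scaling so
  the maximum hub and maximum authority are exactly 1 (matching the
  convention of reporting the top score as 1.00). A hub is a *preceding*
  diagnosis pointing at important subsequent diagnoses; an authority a
  *subsequent* diagnosis receiving flow from important precursors.
* **PageRank** — power iteration on the damped transition operator with
  damping 0.85, uniform teleportation, dangling nodes redistributing
  uniformly; scores sum to 1.

Two conventions deserve note. First, centralities default to RR-weighted
adjacency — the edge weight is the strength of the chronological
relationship — with `use_weights = FALSE` switching to binary adjacency,
since either convention is defensible. Second, HITS convergence: a graph
composed of several weakly coupled communities has near-tied leading
eigenvalues of $A^\top A$, which makes power iteration converge slowly (the
gap, not the size, sets the rate). The iteration cap is therefore generous
(50 000; each step is two sparse matrix–vector products) while the
tolerance stays at 1e−12; genuine non-convergence still raises an error
naming the tolerance reached rather than returning a half-converged vector.

## 4. Map-equation communities

Communities are found by minimising the flat two-level map equation: the
expected per-step description length, in bits, of a random walk encoded
with one index codebook across modules and one codebook per module,

$$L(M)=q_\curvearrowleft H(Q)+\sum_m p_m^{\circlearrowright} H(P_m),$$

with node visit rates taken as the PageRank stationary distribution at
damping $1-\tau$ and module exit rates using *recorded* teleportation
(teleport steps count as exits):
$q_m = \sum_{\alpha\in m} p_\alpha\bigl[\tau\,(n-n_m)/n+(1-\tau)\sum_{\beta\notin m}P(\alpha\to\beta)\bigr]$.
Logarithms are base 2 and $0\log 0 = 0$. With all nodes in one module the
exit terms vanish and $L$ reduces to the entropy of the visit rates — a
closed form the tests assert.

Choices made where the problem left them open:

* **Two-level, not hierarchical.** The analysis this package supports
  reports flat communities; multilevel codebooks are out of scope.
* **Teleportation $\tau = 0.15$**, aligned with the PageRank damping
  default, and the same weighted/binary flag as the centralities, so one
  flow model underlies both.
* **Search.** Each restart begins from singleton modules and sweeps nodes
  in random order, moving each node to the neighbouring (or a fresh) module
  that most decreases $L$, until a sweep makes no move; module-merge passes
  follow. The candidate set always includes the all-in-one partition, so
  the returned codelength never exceeds the singleton or one-module
  baselines. One hundred seeded restarts are the default; ties break
  towards fewer modules, then lexicographically smaller canonical labels,
  making the result deterministic given the seed. A move is accepted only
  if it improves $L$ by more than 1e−12 bits, preventing floating-point
  cycling.
* **Validation.** On graphs of up to 8 nodes the search is compared against
  exhaustive enumeration of *all* set partitions (Bell-number many); the
  acceptance suite requires the optimum in at least 95 % of 50 random
  graphs, and planted two-block and four-block constructions must be
  recovered (adjusted Rand index ≥ 0.8; exactly four modules on the
  default simulator).

## 5. The synthetic cohort generator

No public data of the required form exists, so validation rests on a
simulator whose planted structure the pipeline must recover. It is a
discrete-time per-patient hazard model:

* Each patient receives a follow-up window uniform on
  `followup_years_range` (default 5–16 years, mirroring an EHR linkage
  period with a 5-year minimum), a staggered entry date, and a birth date
  placing age at entry around 66 ± 5.5 years, so age summaries are
  exercised; age has no effect on hazards (none is modelled in the
  emulated analysis).
* At each 30-day timestep every not-yet-acquired diagnostic code *j* fires
  with probability `min(1, h_j · Π_{i acquired} κ(i→j))`. The default
  baseline hazard 0.003 per step yields ≈ 30 % lifetime prevalence at the
  median window — comfortably above the 10 % filter yet far from
  saturation. A monthly step keeps long calibration runs fast while dates
  remain day-resolved: each event lands on a uniformly drawn day inside
  its timestep.
* The default multiplier matrix is block-structured: 24 codes in four
  blocks, κ = 6 within a block, 1 across. This is the "four-community"
  ground truth; κ of this size produces within-block RRs around 1.6–2.5,
  strong enough to recover yet far from deterministic.
* Acquired codes emit Poisson repeat encounters (`revisit_rate`, default
  1/year), V codes are scattered uniformly at the same intensity
  (default 3 distinct V codes), and with probability `coincident_prob`
  (default 0.02) a new first occurrence is snapped onto an existing
  same-patient first-occurrence date, so the coincident-day exclusion rule
  is exercised.
* Event codes carry a random sub-digit (e.g. `253.4`) so the collapsing
  step has work to do.

Determinism is structural: per-patient substreams derive from the master
seed via a sequential draw, so growing `n_patients` never reshuffles
earlier patients, and identical configurations give byte-identical event
tables.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: ICD-9 semantics beyond code shape, mortality and
informative censoring, inpatient/outpatient structure, seasonality,
age- or sex-dependent hazards, coding-practice drift over calendar time.
Recovery of planted structure demonstrates the *pipeline's* correctness,
not the clinical validity of any particular real-world network.

## 6. Trajectories and ego views

`top_successors()` / `top_predecessors()` rank a focal code's out- or
in-neighbours by edge RR (ties by code order). `greedy_max_rr_path()`
formalises "follow the greatest relative risks" as a stepwise argmax walk:
from the current node take the highest-RR out-edge to an unvisited node,
stopping at the optional target, at a dead end, or at `max_len` nodes. When
a target is supplied but the walk dead-ends, the path so far is returned
with `reached = FALSE` — no backtracking, as nothing in the formalised
procedure defines one. These are illustrative devices, not optimal-path
searches; a max-product path algorithm is deliberately out of scope.

## 7. Degenerate inputs and numerical conventions

* Empty event tables flow through every preprocessing stage and produce
  empty outputs, not errors; an edgeless graph yields defined behaviour
  (density 0, uniform PageRank, a valid one-module partition) and errors
  only where a quantity is genuinely undefined (reciprocity, diameter,
  HITS).
* Malformed input rows (unparseable codes or dates) are rejected and
  counted, with the run aborting if they exceed 10 % of rows.
* The RR matrix reuses one patient classification per unordered pair (the
  six counts are swap-symmetric), and its long export carries all six
  counts so any entry can be re-derived by hand.
* All percentages reported in prevalence tables use one-decimal rounding,
  `round(100·n/cohort, 1)`.

## 8. Validation problem sizes

The test suite validates each component at sizes where independent oracles
are exact: micro-cohorts of ≤ 12 patients and ≤ 4 codes against a
brute-force enumerator (200 cohorts), graphs of ≤ 8 nodes against dense
eigendecomposition, linear solves, Floyd–Warshall and exhaustive partition
enumeration (50–100 graphs), and simulator-based recovery runs at 2000
patients × 20–24 codes over 10 seeds each for null calibration, planted
pairs/hubs and community recovery. These sizes were chosen so the full
suite exercises every claim with comfortable statistical margins while
remaining a routine desktop run.

## 9. Known limitations

The chronological RR is a marginal, unadjusted measure: no age, sex or
calendar-time adjustment, no confidence intervals, and the null drift of
Section 2 means RR magnitudes are not comparable across very different
prevalence regimes. First occurrence in an extract is not disease onset —
left truncation at the start of the observation window is inherited from
the data, not corrected. Communities come from one objective (the map
equation) under one flow model; modularity-style alternatives are
deliberately not offered. The simulator validates mechanics, not clinical
substance.
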