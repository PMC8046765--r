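# comorbidnet

Chronological comorbidity networks from longitudinal diagnosis records.

Patients accumulate diagnoses in a characteristic order: hypertension tends
to precede chronic kidney disease, diabetes precedes neuropathy. Given a
longitudinal table of coded clinical encounters (one row per diagnosis per
visit), `comorbidnet` characterises this chronology as a **directed network**
over three-digit ICD-9 diagnosis categories and summarises which diagnoses
drive, and which follow, the accumulation of multimorbidity. It is aimed at
epidemiologists and health-services researchers working with EHR or claims
extracts.

## The statistic at the core

For each ordered pair of diagnoses *(i, j)*, every cohort patient falls into
exactly one of six categories by comparing the dates of their *first*
occurrence of each code: *i* strictly before *j* (`N(i→j)`), *i* but never
*j* (`N(i→~j)`), *j* before *i* (`N(j→i)`), *j* but never *i* (`N(~i→j)`),
neither, or *coincident* (both first occurrences on the same day — these
patients are excluded from the calculation entirely). The chronological
relative risk is

```
            N(i→j) / (N(i→j) + N(i→~j))
RR(i,j) = ─────────────────────────────────────────────────
           (N(~i→j) + N(j→i)) / (N(~i→j) + N(j→i) + N(~i&~j))
```

the risk of developing *j* after a prior *i*, relative to the risk of *j*
without a prior *i*. Pairs with RR > 1 become directed, RR-weighted edges.
The package computes the graph's edge density, reciprocity and breadth-first
diameter, Kleinberg hub/authority scores (scaled to a maximum of 1) and
PageRank by power iteration, flat two-level map-equation (Infomap-style)
community detection with multi-restart search, and ego/trajectory views
(top-RR successors and predecessors of a focal diagnosis, greedy
maximum-RR paths).

Because real EHR extracts of this kind cannot be shared, the package ships a
synthetic cohort simulator with *planted* structure — a hazard-multiplier
matrix κ where carrying diagnosis *i* multiplies the per-timestep hazard of
acquiring *j* by κ(i→j), organised in community blocks — so that every stage
is testable against a known ground truth.

## Worked example

```r
library(comorbidnet)

cfg <- sim_config(n_patients = 500, n_codes = 12, n_blocks = 3, seed = 42)
sim <- simulate_cohort(cfg)
head(sim$events, 3)
#>   patient_id birth_date event_date icd9_code
#> 1     P00001 1935-08-16 2001-12-29     V03.7
#> 2     P00001 1935-08-16 2002-04-28     V03.9
#> 3     P00001 1935-08-16 2002-05-15     V02.9

coll <- collapse_events(sim$events)              # "401.9" -> "401" etc.
fu   <- filter_followup(coll$events, min_years = 5)
fo   <- first_occurrences(fu$events)
codes <- prevalence_filter(
  fo[fo$code3 %in% network_exclusions(unique(fo$code3)), ],
  cohort_size = length(fu$patients))             # >= 10 % of patients

rrm <- rr_matrix(fo, codes, fu$patients)
#> Chronological RR matrix: 12 codes, 482 patients, 132/132 ordered pairs defined

g <- build_graph(rrm)                            # edges where RR > 1
unlist(graph_stats(g))
#>      n_nodes      n_edges   n_isolated edge_density  reciprocity     diameter
#>   12.0000000   36.0000000    0.0000000    0.2727273    1.0000000    1.0000000

head(centrality_table(g), 4)
#>   code3 label       hub authority   pagerank
#> 4   253   253 1.0000000 0.9981814 0.08402875
#> 2   251   251 0.9971271 0.9882807 0.08329797
#> 3   252   252 0.9905689 1.0000000 0.08376951
#> 1   250   250 0.9805603 0.9808639 0.08223710

detect_communities(g, n_runs = 50, seed = 42)
#> Map-equation partition: 3 modules, codelength 2.6419 bits (50 runs)
#> module
#> 1 2 3
#> 4 4 4

top_successors(g, "250", k = 3)
#> Top successors of 250 by chronological RR
#>   code3       rr
#> 1   253 1.621617
#> 2   251 1.607644
#> 3   252 1.580208

greedy_max_rr_path(g, "250", max_len = 5)
#> Greedy max-RR path: 250 -> 253 -> 252 -> 251
#>   step RRs: 1.62, 1.67, 1.61
```

The three planted community blocks are recovered exactly (modules of four
codes each); within-block relative risks sit around 1.6 while cross-block
pairs fall below the RR > 1 edge threshold. 27 % of the possible directed
pairs carry an edge and every edge is reciprocated, as expected when the
planted multipliers are symmetric.

`run_pipeline(pipeline_config(sim = cfg, outdir = "out"))` runs all of the
above in one call and writes the event table, prevalence table, RR pair
table, GraphML/GEXF/DOT exports, centrality and community tables, and a
machine-readable run manifest. A thin command-line wrapper with `simulate`
and `run` subcommands is installed under `inst/cli/comorbidnet`.

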