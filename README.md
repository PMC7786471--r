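# collabnet

Measuring the development of interprofessional collaboration networks in
community health-care districts from two-round ego-nomination surveys.

Professionals caring for community-living older people — general
practitioners, practice and district nurses, social care workers,
physiotherapists, pharmacists and others — are surveyed before and after an
intervention: each respondent names the colleagues they collaborate with
and rates each contact on a 1–10 scale.  A snowball-plus-fixed-list design
fixes the network boundary and classifies every actor into rings:
**ring 1** (program participants), **ring 2** (consented responders outside
the program) and **ring 3** (nominated non-responders, whose outgoing ties
are missing while their incoming ties are observed).  `collabnet` turns
these survey records into directed valued networks and quantifies network
development with the standard descriptive suite:

- **number of contacts** — out-degree, average degree over observed actors,
  and density (present arcs / *n*(*n*−1));
- **E-I index** per ring — (E − I)/(E + I) over internal and external
  contacts, −1 all-internal to +1 all-external;
- **reciprocity** — mutual dyads as a share of connected dyads;
- **diversity** — per actor, `H_i = P_iR × D_iD`, the share of in-ties from
  other disciplines times the share of other disciplines reached (0
  homogeneous … 1 maximally heterogeneous);
- **value** — mean 1–10 rating an actor places on their contacts;

plus paired t tests (with 95% CIs) comparing the two timepoints, a
Table-style pre/post report per district, sociogram rendering, GraphML /
Pajek / edge-list I/O, and a seeded synthetic cohort generator (with an
intervention effect on ring 1 and a spill-over effect on ring 2) so the
whole pipeline runs without any external data.

## Worked example

```r
library(collabnet)

sims <- generate_study(seed = 42)        # three synthetic districts
st   <- sims[["district 1"]]$study       # 49 actors: rings 7 + 9 + 33

average_degree(st$t0, rings = c(1, 2))   # 4.19 contacts at baseline
net_density(st$t0, rings = c(1, 2))      # 0.28
ei_decomposition(st$t1, group = 1, rings = c(1, 2))
#> <ei_decomposition> ring 1 (n=7, boundary): internal 15, external 54, E-I 0.565

compare_networks(st)
#> <network_comparison> rings 1+2
#>       metric    t0    t1 change
#>   avg_degree 4.188 6.688  2.500
#>      density 0.279 0.446  0.167
#>  reciprocity 0.396 0.551  0.155
#>     ei_ring1 0.490 0.565  0.075
#>     ei_ring2 0.407 0.174 -0.233
#> diversity: Paired t test: t = 2.536, df = 15, p = 0.02284, 95% CI [0.030, 0.349], n = 16
#> value:     Paired t test: t = -0.661, df = 15, p = 0.5188, 95% CI [-0.338, 0.178], n = 16
```

Read: responders in rings 1+2 named on average 4.19 collaboration contacts
at baseline and 6.69 afterwards; density rose from 28% to 45% of all
possible relationships and reciprocity from 40% to 55% of connected pairs
(+15.5 percentage points); the positive ring-1 E-I index says program
participants direct most contacts outside their own ring; the discipline
diversity of the 16 responders increased significantly (t = 2.54,
p = 0.023) while the perceived value of contacts did not change.

`build_report(lapply(sims, function(s) s$study))` assembles the full
descriptive table — both ring subsets, both timepoints, per-ring E-I
decomposition, with reciprocity/diversity/value marked `N.A.` in the
ring-3-inclusive columns — and `run_pipeline()` chains simulation (or
ingest of `actors.tsv`/`ties.tsv` survey files), metrics, comparison,
report files and sociogram figures.  A thin command-line front end with
subcommands `simulate | ingest | metrics | compare | report | draw` lives
at `inst/cli/collabnet.R`.

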