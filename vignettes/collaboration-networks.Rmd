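---
title: "Measuring the development of interprofessional collaboration networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the development of interprofessional collaboration networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(collabnet)
```

## The measurement problem

Care for community-living older people is delivered by a heterogeneous
workforce — general practitioners, practice nurses, district nurses, social
care workers, physiotherapists, pharmacists and others — whose ability to
collaborate across disciplines is itself an outcome worth measuring.
`collabnet` implements a survey-to-report pipeline for quantifying how a
district's collaboration network changes between two timepoints, for
example around an interprofessional education program.

Data come from an ego-nomination instrument: each responding professional
(the *ego*) lists the colleagues (*alters*) with whom they collaborate on
care for older people and rates each contact on a 1–10 scale.  Because no
register of all professionals in a district exists, the network boundary is
fixed by a snowball-plus-fixed-list design: the program participants'
nominations define a comprehensive roster, everyone on the roster is then
invited, and the same roster is reused at the second timepoint.  This
yields three *rings* of actors:

* **ring 1** — program participants;
* **ring 2** — professionals who consented and responded (at either
  timepoint) but did not attend the program;
* **ring 3** — nominated professionals who never responded.

Ring-3 actors exhibit *unit non-response*: all of their outgoing ties are
missing, while their incoming ties are observed through their responding
colleagues.  The package treats their out-degree as missing data, never as
zero, and `validate_network()` enforces this asymmetry.

## The metric suite

All metrics operate on a directed valued network per district and
timepoint (`collab_network`), optionally restricted to a ring subset with
`induce_subset()`.  Two reporting subsets mirror the descriptive table the
pipeline produces: rings 1+2 (fully observed responders) and rings 1+2+3
(the whole boundary).

**Number of contacts.**  The out-degree of a responder is the number of
professionals nominated; `average_degree()` averages over actors with an
*observed* out-degree, excluding ring 3 from numerator and denominator.
`net_density()` is the proportion of present arcs among the $n(n-1)$
possible ones.  When ring 3 is included, its missing out-arcs remain absent
from the numerator while the actors stay in the denominator, which biases
density downward; both subset columns are still reported, with this caveat,
because the ring-3-inclusive column describes the whole delineated network.

**E-I index.**  For a group $g$ (here a ring), let $I$ be the number of
arcs with both endpoints in $g$ and $E$ the number of *external* contacts.
Then
$$\mathrm{EI}(g) = \frac{E - I}{E + I} \in [-1, +1],$$
$-1$ when all contacts are internal and $+1$ when all are external; when
$E + I = 0$ the index is undefined and returned as missing rather than 0.
Two counting conventions for $E$ exist in practice.  The default,
`mode = "boundary"`, counts every arc crossing the group boundary in either
direction, so in a two-ring partition both rings share one external count
and the decomposition rows (internal/external contacts, internal and
external average degree per group member) add up across the table.
`mode = "source"` counts only arcs sent by group members, which reads the
index as a property of the group's own choices.  We default to the
boundary convention because it is the one under which the per-ring
internal/external contact rows of the standard descriptive table are
mutually consistent; the source variant is kept for sensitivity analyses.

**Reciprocity.**  `reciprocity()` defaults to the dyad-based ratio: the
number of mutually connected pairs over all connected (non-null) pairs,
i.e. the share of potential reciprocal relationships that are actually
reciprocal.  The arc-based alternative (probability that an observed arc is
reciprocated) is available as `method = "arc"`.  Reciprocity is reported
for the rings 1+2 subset only: with ring 3 included, every dyad touching a
non-responder could never be mutual by construction.

**Diversity.**  The discipline-diversity index of actor $i$ is built from
incoming nominations, which are considered more reliable than
self-reports.  With $R_i$ the in-degree, $R_{div,i}$ the in-ties from other
disciplines, $D_i$ the number of disciplines in the network minus one, and
$D_{div,i}$ the distinct other disciplines among the in-ties,
$$P_{iR} = R_{div,i}/R_i, \qquad D_{iD} = D_{div,i}/D_i, \qquad
  H_i = P_{iR} \times D_{iD} \in [0, 1].$$
$H_i = 0$ indicates fully within-discipline collaboration and $H_i = 1$
maximal heterogeneity.  One published rendering of $P_{iR}$ uses the
complementary fraction $(R_i - R_{div,i})/R_i$; we follow the verbal
definition (*proportion of relationships with members of other
disciplines*), which is the only direction consistent with the canonical
worked example — an actor receiving in-ties from everyone, half own
discipline and half spanning every other discipline, scores
$H_i = 0.5 \times 1 = 0.5$ — and with "higher = more heterogeneous".  The
summation sign sometimes printed in $H_i = \Sigma P_{iR} \times D_{iD}$ is
treated as typographic: $H_i$ is a per-actor product, and district-level
summaries are taken afterwards by `mean_diversity()` (sample SD, $n-1$).
Actors with in-degree 0 have no defined score; a single-discipline network
has no defined diversity at all and raises an error.

**Value.**  `mean_tie_value()` averages the 1–10 ratings an actor placed on
their contacts, skipping unrated ties; non-responders have no defined
value.  `tie_value_summary()` aggregates per-actor means.

```{r worked-example}
# the canonical diversity scenario: 7 actors, 3 disciplines
ids <- c("i", "o1", "o2", "o3", "n1", "n2", "s1")
actors <- data.frame(
  actor_id = ids,
  discipline = c(rep("general practitioner", 4),
                 "district nurse", "district nurse", "social care worker"),
  ring = 2L)
net <- collab_network(actors, data.frame(source = ids[-1], target = "i"))
diversity_index(net, "i")
```

## Pre/post comparison

`paired_t_test()` implements the classical paired t test on differences
*post − pre*, pairing by actor and dropping pairs with a missing value at
either timepoint (the count of dropped pairs is reported).  A positive t
statistic therefore means an increase; published tables produced with the
opposite pair order show the mirrored sign.  Zero-variance differences —
e.g. a network compared against itself — return $t = 0$ with an explicit
warning rather than failing, since survey software leaves this case
undefined.  Tests use two-sided $p$ values at a 95% confidence level and no
multiple-testing correction, as districts are reported separately.

`compare_networks()` reports T0, T1 and change for the network-level
metrics (for density and reciprocity the change times 100 is the
percentage-point change), and paired t tests for the actor-level diversity
and value measures over rings 1+2, the subset where both are defined at
both timepoints.  `build_report()` assembles the full descriptive table:
district × subset × timepoint rows with average degree, density (%), the
per-ring E-I decomposition, reciprocity (%), diversity mean (SD), value
mean (SD) and the paired tests, with reciprocity/diversity/value cells in
the rings 1+2+3 columns marked not-applicable.

## The synthetic cohort generator

Because nomination data of this kind are not publicly deposited, the
package ships a generator that emulates the study conditions and makes the
whole pipeline testable offline.  `cohort_config()` describes one district:

* rosters default to 7 ring-1, 9 ring-2 and 33 ring-3 actors — a district
  of 49 with 16 responders, matching the typical design of 7–10 program
  participants and a 25–40% response rate among the nominated;
  `generate_study()` simulates three such districts (7+9+33, 8+11+56,
  7+13+49) under one master seed with deterministic per-district sub-seeds;
* disciplines are sampled from a mix led by social care workers and
  district nurses (`default_discipline_mix()`);
* arcs are independent Bernoulli draws with baseline probability
  `base_density` (default 0.2, in the range of observed baseline densities)
  at both timepoints; at T1 the arc probability of ring-1 sources rises by
  `effect_ring1` (default 0.15, the order of the observed density change)
  and that of ring-2 sources by `spill_over` (default 0.08), encoding the
  intervention effect and its spill-over onto non-participants;
* after the base draw, the reverse of each arc is added with probability
  `reciprocity_boost` (default 0.3, which brings dyadic reciprocity into
  the 0.25–0.5 band typical at baseline); setting it to 1 makes the
  unmasked graph fully reciprocal;
* tie values are Gaussian (`value_mean` 7.5, `value_sd` 0.6 — contact
  ratings of this kind cluster tightly around 7–8), clamped to $[1, 10]$
  and rounded to one decimal, the precision the survey files carry.

The generator returns both the observed study — ring-3 out-arcs masked,
exactly as unit non-response would leave them — and the counterfactual
unmasked networks as ground truth for calibration checks.  Ring-3 size is
controlled directly (`n_ring3`) rather than through a separate non-response
probability, so the roster composition is exact by construction.

What the generator does *not* emulate: discipline homophily in tie
formation, degree heterogeneity beyond binomial variation, tie persistence
between T0 and T1 (arcs are redrawn independently), geographic structure,
and actors entering or leaving the roster.  Tests passing on synthetic
cohorts therefore certify the pipeline's arithmetic and its handling of
missingness, not the realism of any particular empirical network.

## Numerical and design choices

* Actor identifiers are opaque strings; matching names across survey
  rounds is a pre-processing concern with exact matching assumed.
* Ring membership is fixed per study (classification uses response at
  either timepoint), mirroring a design where one comprehensive roster is
  reused.
* Self-nominations are dropped with a warning; duplicate identical
  nominations collapse; the same ordered pair with conflicting values is
  an error, surfacing data-entry faults instead of silently averaging.
* Alters nominated outside the roster — e.g. new names appearing at the
  second timepoint — are appended as ring 3 with a warning, so no reported
  contact is lost.
* Degenerate metric inputs raise errors (density on fewer than 2 actors,
  reciprocity with no connected dyads, averages with no defined values)
  rather than returning conventional zeros.
* GraphML is the canonical interchange format and round-trips every
  attribute; Pajek NET (direction and value; unrated ties stored as weight
  0, outside the rating range) and delimited edge lists are provided for
  interoperability with classic SNA tools.
* Sociograms use a seeded force-directed layout (none is canonical for
  such figures); node size grows linearly with out-degree — the simplest
  monotone encoding — with non-responders at minimum size, and the
  reciprocity view colors mutual ties blue and one-sided ties red.

## Problem sizes used in the test suite

The correctness of density and reciprocity is established exhaustively on
every directed graph with up to 4 nodes through the public interface, on
all $2^{20}$ directed graphs on 5 nodes through the shared dyad-census
core, and on 500 random graphs with up to 30 nodes against independent
igraph oracles.  The paired t test is compared to R's reference
implementation on 100 random paired samples ($n = 3,\dots,30$) at
$10^{-9}$.  Generator calibration uses 200 replicates of a 60-actor
district ($p_0 = 0.2$, coverage of $\pm 3$ binomial standard errors) and
150+150 replicates for the spill-over contrast.  These sizes give stable
Monte-Carlo verdicts while keeping the default test run in the order of a
minute.

## Limitations

The pipeline quantifies network development descriptively; it performs no
network-level inference (QAP, ERGM or permutation tests), no weighted
density or valued reciprocity, and no centrality measures beyond degree.
Paired tests treat actors as independent pairs, which network dependence
strictly violates — a known limitation of descriptive pre/post designs.
Conclusions about any real district depend on response rates and boundary
quality in ways the synthetic cohorts only partially reproduce.
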