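---
title: "Methods: early social-network formation in weekly cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early social-network formation in weekly cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortnets)
```

# The setting

`cohortnets` analyses the early history of a social network observed as a
sequence of weekly directed graphs. The motivating setting is a student
cohort: once a week each student names the peers they remember working
with, and a directed link runs from the namer to the named student. The
package answers three questions about such data: how quickly do links
stabilize, what group structure does the information flow induce, and
which externally given attributes (pre-assigned section, gender, grade)
explain that group structure.

Every stage is driven either by edge-list/attribute CSV files or by the
built-in synthetic cohort generator, so the full pipeline is testable
without survey data.

# Link turnover

For the ordered weekly networks, `link_counts()` reports per week $t$:

* $E_{tot}(t)$ — number of directed links;
* $E_{new}(t) = |E_t \setminus E_{t-1}|$ — links absent the week before;
* $E_{re}(t) = |E_t \cap \bigcup_{s<t} E_s|$ — links seen in *any* earlier
  week;
* $f_{new}(t)$ — the fraction of links never seen before.

$E_{new}$ and $E_{re}$ deliberately overlap: a link can be new relative
to last week yet re-established relative to an earlier one. For the first
week we set $E_{new} = E_{tot}$ and $E_{re} = 0$; the first week has no
history, and defining the values keeps the table rectangular.

Degree summaries use the cumulative distribution
$P(k) = \sum_{k' \ge k} p_{k'}$ and moment-based spread
$\sqrt{\langle k^2 \rangle - \langle k \rangle^2}$. Because "spread" is
reported sometimes as a standard deviation and sometimes as a standard
error in this literature, `degree_stats()` returns both (`sd` and
`sem = sd / sqrt(n)`). The diameter of a weakly disconnected digraph is
taken as the longest *finite* directed shortest path; unreachable pairs
are ignored rather than treated as infinite.

# Map-equation community detection

Communities are found by minimizing the two-level map equation on the
directed network. A random walker follows a uniformly chosen out-link
with probability $1-\tau$ and teleports to a uniformly chosen node with
probability $\tau$ (always, from a node with no out-links). Its
stationary visit rates $p_i$ come from power iteration
(`visit_frequencies()`, default tolerance $10^{-12}$ on the max-norm
step change; non-convergence is an error, not a silent result).

A partition $M$ with modules $k$ is scored in bits per step:

$$L(M) = q\,H(Q) \;+\; \sum_k p^{\circlearrowright}_k H(P_k),$$

where $q_k$ is the rate at which the walker exits module $k$,
$q = \sum_k q_k$, $H(Q)$ the entropy of the normalized exit rates,
$p^{\circlearrowright}_k = q_k + \sum_{i \in k} p_i$ the rate at which
module $k$'s codebook is used, and $H(P_k)$ the entropy of the module's
normalized node-visit and exit rates. With a single module the index
codebook is unused and $L$ equals the entropy of the visit rates — a
useful exact anchor that the tests exploit.

## Exit-rate accounting

Two accountings of teleportation are implemented:

* **unrecorded** (default): teleportation shapes the visit rates only;
  exit rates count link-following flow,
  $q_k = \sum_{i \in k, j \notin k} p_i (1-\tau)/d^{out}_i$.
* **recorded**: teleportation jumps landing outside the module are
  charged to the exit rate as well.

The default matters in this data regime. Weekly naming networks contain
many students who are named but never name (no out-links, so they
teleport every step). Under recorded accounting their teleportation mass
is charged to every module boundary, and on networks like these — we
verified this both with this package and with an independent
implementation of the original algorithm — the minimum collapses to a
single module. Unrecorded accounting recovers the persistent-partner
groups instead, at the cost of leaving never-naming students in
zero-cost singleton modules. The accounting is a documented switch
(`teleport_exit`), and results are reproducible bit for bit given the
seed either way.

## Search

`detect_communities()` is a greedy Louvain-style search: each run starts
from singletons and alternates node-level moves with aggregated
module-level moves, in randomized order, accepting only strict
code-length decreases; the best of `n_runs` runs is kept (ties broken by
the lexicographically smallest canonical labelling, communities labelled
by decreasing size then smallest member id). Default `n_runs = 100`; the
examples and tests use fewer runs on small networks where the optimum is
reached almost every run. On every test digraph with at most 8 nodes the
search attains the exhaustive minimum over all set partitions, which is
how the suite validates it.

`run_stability()` repeats detection and summarizes the variation of
information between consecutive runs together with mean module count,
directed modularity and code length — the usual robustness report for a
stochastic detector.

# Comparing partitions

`variation_of_information()` computes
$VI = H(X) + H(Y) - 2I(X;Y)$ in bits from the confusion matrix of two
partitions, restricted to their overlapping nodes ("reduced groupings"),
with $0 \log 0 = 0$. $VI$ is a metric bounded by $\log_2 n$ for $n$
overlapping nodes (`vi_upper_bound()`), which makes distances between
weeks with different rosters comparable.

# Attribute segregation

For a partition and a categorical attribute, each community $k$ is
scored by the Kullback–Leibler divergence between its category
distribution and the network-wide one,

$$D_k = \sum_a p_k(a) \log_2 \frac{p_k(a)}{p(a)},$$

and the network total is the size-weighted sum
$S = \sum_k (n_k/n) D_k$. The global distribution $p(a)$ is always
computed from the students present in that week's network, so weeks with
different rosters are each judged against their own cohort composition.
$S$ ranges from 0 (every community mirrors the cohort) to the Shannon
entropy of $p$ (perfect segregation); both limits are verified in closed
form by the tests.

Because $S$ has no convenient analytic null, significance uses a
permutation null: the attribute values are randomly re-distributed over
the partitioned nodes (multiset preserved, network and partition fixed),
$S$ is recomputed `m_perms` times (default 1000), and
$Z = (S_{obs} - \bar S_{null}) / sd(S_{null})$. $|Z| > 1.96$ is flagged
as significant, at the network level and — with `level = "per_group"` —
per community using $D_k$ under the same null. A constant attribute has
zero null variance; the Z-score is reported as `NA` with a warning
rather than a number. The suite checks calibration empirically: with
attributes assigned independently of the partition, $|Z| > 1.96$ occurs
at close to the nominal 5% rate. The null distribution of $S$ is mildly
right-skewed, so calibration is best for communities of roughly ten
nodes or more; with many very small groups the two-sided test is
slightly conservative.

Grades are treated as unordered categories here: the divergence only
uses category frequencies, and ordinality plays no role in the statistic.

# Alluvial diagrams and flow maps

`build_alluvial()` lays out one column per week; boxes are communities
with height proportional to membership count (one global scale factor),
ordered by decreasing size, and streamlines between adjacent columns are
exactly the nonzero confusion-matrix entries, stacked by descending
count. Box colors encode per-community segregation significance: dark
red for section only, green for gender only, purple for both. The
streamline counts conserve the node overlap between adjacent weeks, an
invariant the tests assert.

`aggregate_flow()` produces the companion within-week flow map:
community sizes as accumulated visit rates $\sum_{i \in C} p_i$ and
arrows as the walk flow between ordered community pairs (teleportation
flow included, so even disconnected communities show small symmetric
background flows). Rendering goes to plain SVG with geometry
proportional to counts and flows, so figures are diffable and testable
without a display.

# The synthetic cohort generator

`cohort_config()` describes the emulated study conditions; the defaults
are fixed once and used by the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `n_students` | 160 | cohort size (the emulated study had ~140–170) |
| `n_sections` | 7 | pre-assigned lab/recitation sections, balanced ±1 |
| `gender_split` | 0.3 | share of category "F", typical of a physics intake |
| `grade_vocab` | 7-step scale | includes a fail category; sampled independently |
| `n_weeks` | 7 | weekly waves |
| `mean_out_degree` | 6 | Poisson namings per active student |
| `persistence` | 0.5 | chance an emitted link re-uses a past partner |
| `homophily_section` | 8 | preference weight for same-section partners |
| `homophily_gender` | 2 | weaker preference for same-gender partners |
| `participation` | 0.8 → 0.5 | linearly declining weekly activity |

Each week, active students emit Poisson many links; with probability
`persistence` a link is drawn uniformly from the student's own past
partners, otherwise a new partner is drawn with probability proportional
to `homophily_section^[same section] * homophily_gender^[same gender]`.
Grade is independent of everything by construction, which is what makes
it a negative control for the segregation analysis. One seed drives a
single random stream; replicate $k$ uses `seed + k`.

What the generator reproduces: declining participation and shrinking
active cores; section-driven (and weaker gender-driven) mixing that the
segregation Z-scores detect while grade stays null; a completely-new
link fraction that falls over weeks and falls with `persistence`;
between-week partition distances that shrink as the cohort stabilizes.

What it does not reproduce: the study's tight few-student workgroups —
links are spread over the whole section rather than concentrated in
small persistent cliques, so detected communities are smaller and more
numerous than in real cohorts, and never-naming students appear as
singletons. Week-over-week turnover is also higher than the ~50% seen in
real data, because uniform reuse over a growing partner history rarely
repeats exactly last week's links. Conclusions from passing tests
therefore concern the correctness and calibration of the measures, not
the realism of any particular network statistic.

# Numerical choices

* All logarithms are base 2; all $0 \log 0$ terms are 0.
* Power iteration stops when the max-norm step change drops below
  $10^{-12}$; visit rates are renormalized to sum exactly to 1.
* Greedy moves are accepted only when the code length drops by more than
  $10^{-13}$, which keeps the trajectory strictly non-increasing and the
  search finite.
* Code-length ties between runs are broken by the lexicographically
  smallest canonical labelling, making `detect_communities()`
  deterministic given its seed.
* Degenerate inputs fail loudly: empty networks, empty partitions,
  zero-edge modularity, constant-attribute Z-scores and non-convergent
  visit rates all signal conditions instead of returning numbers.

# Problem sizes used in the checks

The test suite and the acceptance script run on synthetic cohorts of
40–170 students over 2–7 weeks, with 2–20 detection runs per network,
500–1000 permutations per Z-score, 50 replicates for the
homophily-recovery check and 1000 draws for the null-calibration check.
Exhaustive map-equation minima are verified on all digraphs with up to 8
nodes (4140 partitions).
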