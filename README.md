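# cohortnets

Analysis of the early history of social networks observed as weekly
directed graphs — the regime where links are still forming, rosters
fluctuate, and group structure is only beginning to stabilize. The
motivating data are student cohorts in which each student weekly names
the peers they worked with (a directed link from namer to named), plus a
per-student attribute table (gender, pre-assigned section, end-of-course
grade). The package is aimed at researchers studying network formation
in classrooms, departments, or any closed population surveyed in waves.

## What it computes

* **Link turnover.** Per week: total links `E_tot`, new links vs the
  preceding week `E_new`, re-established links present in any earlier
  week `E_re`, and the fraction of completely new links `f_new`;
  cumulative degree distributions `P(k) = Σ_{k'≥k} p_k'`, link-weight
  (re-occurrence) distributions, density and directed diameter.
* **Map-equation community detection.** Two-level map equation on the
  directed network: a teleporting random walker (teleportation rate
  `tau = 0.15`) yields visit rates `p_i`; a partition `M` is scored by
  its per-step description length
  `L(M) = q H(Q) + Σ_k p°_k H(P_k)` in bits, minimized by a seeded
  greedy search over node- and module-level moves
  (`detect_communities()`), with directed modularity for reporting.
* **Partition distances.** Confusion matrices and the variation of
  information `VI = H(X) + H(Y) − 2 I(X;Y)` in bits on the node overlap
  of two partitions, with its `log2(n)` upper bound.
* **Attribute segregation.** Per community, the Kullback–Leibler
  divergence `D_k = Σ_a p_k(a) log2 p_k(a)/p(a)` between the community's
  attribute distribution and the cohort's; the size-weighted total
  `S = Σ_k (n_k/n) D_k`; and permutation Z-scores under random
  re-assignment of attributes with the partition held fixed.
* **Alluvial diagrams and flow maps.** Between-week streamlines equal to
  confusion-matrix entries, boxes sized by community membership and
  colored by segregation significance; within-week community flow maps;
  SVG rendering.
* **Synthetic cohorts.** A generator (`cohort_config()`,
  `generate_cohort()`) producing attribute tables and weekly networks
  with declining participation, link persistence, and section/gender
  homophily, so every stage can be exercised and calibrated without
  survey data.

See the vignette `vignettes/cohort-network-methods.Rmd` for the models,
assumptions, parameter meanings and numerical choices.

## Worked example

```r
library(cohortnets)

cfg <- cohort_config(n_students = 60, n_sections = 4, n_weeks = 4,
                     participation = c(0.9, 0.8, 0.7, 0.7), seed = 11)
coh <- generate_cohort(cfg)

link_counts(coh$networks)[, c("week", "E_tot", "E_new", "E_re", "f_new")]
#>   week E_tot E_new E_re     f_new
#> 1    1   351   351    0 1.0000000
#> 2    2   274   136  138 0.4963504
#> 3    3   246   169  138 0.4390244
#> 4    4   216   161  131 0.3935185
```

Activity declines and the completely-new fraction `f_new` falls from 1
to 0.39: students increasingly return to partners they already used.

```r
part <- detect_communities(coh$networks[[4]], n_runs = 10, seed = 2)
part
#> partition: 60 nodes in 28 communities (L = 3.5126 bits/step)
#> sizes: 10, 6, 5, 5, 4, 4, 3, 2, 2, 1, 1, ...
```

The walk over week 4 compresses to 3.51 bits/step under this partition
(one module would cost the visit-rate entropy, about 5.8 bits); the
singletons are students who were named but never named anyone.

```r
segregation_zscore(part, coh$attrs, "section", m_perms = 1000, seed = 3)
#> segregation of 'section': S = 1.8208 bits (max 2.0000), Z = 10.47 [significant]
segregation_zscore(part, coh$attrs, "grade", m_perms = 1000, seed = 3)
#> segregation of 'grade': S = 1.5219 bits (max 2.6751), Z = 0.43 [n.s.]
```

Communities are strongly segregated by section (`Z = 10.47`, far beyond
the 1.96 band) but not by grade (`Z = 0.43`): grade is assigned
independently in the generator, and the permutation null correctly
refuses to flag it even though its raw `S` looks large — small groups
inflate `S` under the null too, which is exactly what the Z-score
corrects for.

```r
p3 <- detect_communities(coh$networks[[3]], n_runs = 10, seed = 2)
variation_of_information(p3, part)
#> [1] 2.192831          # bits; upper bound log2(60) = 5.91
```

The full pipeline (generate or read data → turnover → communities → VI →
segregation → alluvial SVG, with a checksummed manifest) is
`run_pipeline()`.

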