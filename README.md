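# hoxphys

A biophysical force model of *Hox* gene cluster collinearity, for
developmental and systems biologists who want the mechanical hypothesis as
runnable, testable code.

*Hox* genes sit on the chromosome in the order of their expression domains
along the embryonic anterior–posterior axis (spatial collinearity), are
activated in that order over time (temporal collinearity), and where
several are co-expressed the most posterior active gene is strongest
(quantitative collinearity). The biophysical hypothesis explains all three
mechanically: a posterior morphogen gradient M(x) drives production of
P-molecules whose pulling capacity P(x,t) = α·M(x)·t combines with a
charge-like property N distributed over the cluster fiber
(N = κ_N · span) into an extruding force

    F = P · N

that pulls the cluster — an elastic spring anchored at its 5' end — out of
the chromosome territory (CT) into the interchromosome domain (ICD),
extruding genes one by one past a transcription factory:
E(F) = max{e : ∫₀ᵉ s(u) du ≤ F}, with local fiber stiffness s(u).

On top of the simulator the package provides:

* **Cluster containers and distance algebra** — S4 `HoxCluster` objects
  from distance-list TSV or BED input, descriptive statistics, gene-set
  restriction; the compact mouse HoxD and loose amphioxus reference
  clusters ship as fixtures.
* **A developmental-noise experiment** — Gaussian white noise on the
  factors of phenotypic realization f(i,i+1) = l / d(i,i+1) shows that
  loose, irregular cluster geometries transmit identical noise into a far
  fuzzier body plan than compact vertebrate-type ones (closed-form
  variance oracles included).
* **A qualitative mutant engine** — deletions, tandem duplications and
  cluster splittings classified into UNCHANGED / ANTERIORIZED(_WITH_GAIN)
  / POSTERIORIZED_DELAYED / SILENCED verdicts from the force balance, with
  the nine reference engineered-mutant scenarios packaged as data.
* **Seed-deterministic synthetic generators** for clusters, dispersion
  ladders and stiffness profiles.

## Worked example

```r
library(hoxphys)

distanceStatsReport()
#>             organism n_genes n_distances total_kbp mean_kbp variance_kbp2
#> 1         mouse_hoxd       9           8        94 11.75000       43.6875
#> 2          amphioxus      14          13       446 34.30769      731.4438
#> 3 amphioxus_modified      10           9       446 49.55556     1698.0247
```

The mouse HoxD cluster packs 9 genes into 94 Kbp (mean gap 11.75 Kbp,
population variance 43.7); the amphioxus cluster spreads 14 genes over
446 Kbp; restricting it to the mouse gene complement
(`restrictToGenes(amphi, c(1,3,4,8:14))`) concentrates the same 446 Kbp on
9 gaps, the most irregular geometry of the three.

Perturb all three with *the same* white noise (5% of the pooled mean FPR,
250 realizations) and the geometry alone separates them:

```r
suppressWarnings(compareOrganisms(
  list(hoxFixture("mouse_hoxd"), hoxFixture("amphioxus"),
       hoxFixture("amphioxus_modified")),
  noise = NoiseSpec(level = 0.05, realizations = 250, seed = 1)))
#>             organism ... pooled_mean pooled_variance theoretical_variance variance_rank
#> 1         mouse_hoxd ...   100.03857        20.64597             20.36472             1
#> 2          amphioxus ...   100.11787       203.57908            213.83924             2
#> 3 amphioxus_modified ...   100.41117       434.60703            465.42237             3
```

Pooled means stay at the ideal segment length 100 (the noise is mean-zero)
while the pooled variance of the compact mouse geometry is an order of
magnitude below the loose geometries — the quantitative sense in which
compact clustering buffers developmental noise. The variance *ordering* is
the reproducible claim; exact variance magnitudes depend on an
under-specified noise calibration (see the vignette).

The mutant engine re-derives the reference engineered-mutant outcomes from
the force balance:

```r
res <- suppressWarnings(runScenarios())
res[, c("scenario_id", "expected_verdict", "computed_verdict", "match")]
#>                scenario_id       expected_verdict       computed_verdict match
#> 1                 del_8_10              UNCHANGED              UNCHANGED  TRUE
#> 2               del_i_8_10 ANTERIORIZED_WITH_GAIN ANTERIORIZED_WITH_GAIN  TRUE
#> 3                del_10_12              UNCHANGED              UNCHANGED  TRUE
#> 4                 del_9_12               SILENCED               SILENCED  TRUE
#> 5      del_posterior_12_13  POSTERIORIZED_DELAYED  POSTERIORIZED_DELAYED  TRUE
#> 6      dup_posterior_12_13           ANTERIORIZED           ANTERIORIZED  TRUE
#> 7          split_fixed_end           ANTERIORIZED           ANTERIORIZED  TRUE
#> 8                    del_i           ANTERIORIZED           ANTERIORIZED  TRUE
#> 9 inversion_sparing_anchor              UNCHANGED              UNCHANGED  TRUE
```

For instance `del_8_10` (delete genes Hoxd8–Hoxd10, probe Hoxd11, uniform
elasticity): the deletion removes 16 of 94 Kbp, the force drops
proportionally, and the mutant extrusion E = 68.9 lands within 5% of
L − D = 67 — the probe keeps its position at the CT/ICD border, expression
unchanged. A command-line wrapper for these reports is in
`inst/scripts/hoxphys.R` (subcommands `cluster-stats`, `fpr-sim`,
`expression-sim`, `mutant-predict`, `synth-cluster`).

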