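# seedfate

Seed bank survival accounting and inference for buried seed packet
experiments.

Desert annual plants persist between favourable years as seeds in the
soil, and the fate of those seeds — germinate, decay, or carry over alive
— is hard to observe directly. Buried seed packets make it observable:
every sown seed is recovered and classified at collection, so the seed
bank can be followed seed by seed across growing seasons and compared
between species, microhabitats (for example the shade and runoff zones
created by ground-mounted photovoltaic panels) and burial durations.
`seedfate` is for ecologists running or reanalysing such experiments: it
provides the fate-pool accounting, the survival statistic, the
statistical comparisons typically applied to these data, and a
calibrated multistate simulator so every stage of the pipeline can be
exercised and validated without field data.

## The model

At collection, each recovered seed falls into one of the conceptual-model
pools:

- **expended (F)** — germinated (B) or decayed (A); the two are
  indistinguishable at spring collection and are only ever split for
  display;
- **retained (C)** — still intact; a subset is assayed with tetrazolium
  staining and partitioned into **retained live (D, stained)** and
  **retained dead (E, unstained)**.

Seed bank survival over a burial duration is

```
survival = pl × ps
```

where `pl` is the proportion of recovered seeds retained and
`ps = D / (D + E)` is the staining (viability) rate among assayed seeds.
Survival is computed per elementary stratum (species × cohort ×
microhabitat × burial duration) from pooled counts and then averaged
unweighted across strata; the alternative product-of-pooled-proportions
path is also available, and the two deliberately differ (the product of
averages is not the average of products). Group comparisons use
Mann-Whitney U and Kruskal-Wallis/Dunn rank tests on per-location
survival, and quasibinomial logit GLMs with Type III deviance tests
(sum-to-zero contrasts, Pearson-based dispersion) on retention and
per-seed stain presence.

## Worked example

Nine hand-counted packets ship with the package:

```r
library(seedfate)
x <- readPackets(system.file("extdata", "example_packets.csv",
                             package = "seedfate"))
estimateSurvival(x, by = c("species", "burial_seasons"))
```

```
       species burial_seasons n_recovered n_retained n_assayed n_stained    pl
1 E. mohavense              1          54         18        10         5 0.333
2  E. wallacei              1          42         35        18         5 0.833
3 E. mohavense              2          36          6         3         2 0.167
4  E. wallacei              2          14          4         2         1 0.286
     ps survival
1 0.500    0.167
2 0.278    0.231
3 0.667    0.111
4 0.500    0.143
```

Reading the first row: one season after burial, 18 of 54 recovered seeds
of the rare congener were still intact (`pl = 0.333`), half of the 10
assayed intact seeds stained (`ps = 0.5`), so an estimated 16.7% of its
seed bank was alive in the soil. Averaging the stratum products across
species gives the headline values:

```r
aggregateSurvival(estimateSurvival(x, by = c("species", "burial_seasons")),
                  over = "species")
```

```
  burial_seasons    pl    ps survival
1              1 0.583 0.389    0.199
2              2 0.226 0.583    0.127
```

A full-scale synthetic experiment (540 packets, 4860 seeds, the default
calibrated scenario) exercises the whole pipeline:

```r
res <- runPipeline(scenario = calibratedScenario(), out_dir = "run",
                   seed = 42)
aggregateSurvival(res$survival, over = c("cohort", "microhabitat"))
```

```
       species burial_seasons    pl    ps survival
1 E. mohavense              1 0.314 0.519   0.1622
2  E. wallacei              1 0.833 0.271   0.2272
3 E. mohavense              2 0.161 0.590   0.0957
4  E. wallacei              2 0.202 0.164   0.0427
```

i.e. roughly 16% and 23% first-season survival for the rare and common
congener, declining to about 10% and 4% after two seasons, with the
rare species' aging seed retaining high viability — the qualitative
pattern the scenario was calibrated to. The output directory contains
the packet table, pool summaries, survival tables, Sankey flow JSON/CSV,
rank-test and analysis-of-deviance tables, and a manifest with the seed
and file checksums; rerunning with the same seed reproduces the bundle
exactly. A thin command-line front end is installed at
`inst/scripts/seedfate.R` with `simulate`, `analyze`, `report` and
`recover` subcommands.

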