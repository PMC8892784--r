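# rhythmshift

Analysis pipeline for around-the-clock bulk RNA-seq studies of shift
work, built for the three-group rat heart design: control (C), shift
worker (W), and shift worker with restricted feeding (WRF), each
sampled every 4 h over the day (ZT1–ZT21) with three animals per
timepoint — 54 samples on the fpkm scale.

The package answers three questions about such a design:

1. **Which genes cycle, in which group?** Six per-gene rhythmicity
   detectors — cosinor harmonic regression, Lomb–Scargle, a
   JTK_CYCLE-style Kendall concordance test with an exact
   dynamic-programming null, an ARSER-style autoregressive spectral
   test, a RAIN-style Mack–Wolfe umbrella rank test, and a spectral
   F24 permutation test — are combined per gene with Fisher's method,
   $\chi^2 = -2\sum_{i=1}^{6}\ln p_i \sim \chi^2_{12}$, followed by
   Benjamini–Hochberg adjustment across genes; genes with $q < 0.05$
   are called rhythmic, with phase and relative amplitude
   ($A/\mathrm{mesor}$) from the cosinor fit.
2. **Which genes shift level, regardless of time?** A time-agnostic
   screen pooling each group's 18 samples: Kruskal–Wallis omnibus with
   BH correction ($q \le 0.05$), Mann–Whitney post-hoc tests, compact
   letter display, and pattern categories such as `WRF_up_vs_C_and_W`.
3. **Do the changes look like heart disease?** Scoring against gene
   modules (e.g. cardiac-hypertrophy stages) with a designated null
   module M0: percent-up enrichment by one-sided Fisher's exact test
   vs M0, per-module log2 median-ratio distributions tested by
   Kruskal–Wallis vs M0, and up/down disease gene sets compared to the
   genome-wide ratio distribution by a Kolmogorov–Smirnov test after
   normalizing both sides to 500 quantiles.

A synthetic-data generator (`study_config()`, `generate_study()`)
emulates the full design — group-specific phase clustering, dampened
WRF amplitudes, an out-of-phase W replicate series, and an
animal-gated WRF differential-expression block — and returns the
planted ground truth, so every stage is testable for recovery.

## Worked example

```r
library(rhythmshift)

cfg <- study_config(n_genes = 600, seed = 1)
sim <- generate_study(cfg)
sim
#> <study_sim> 600 genes x 54 samples; planted rhythmic C/W/WRF: 73/38/126; DE: 54; WRF responders: 12/18

study <- filter_expressed(sim$study)   # fpkm > 1 in >= 18 samples
calls <- call_rhythmic_genes_all(study, n_perm = 500, seed = 1)
dplyr::count(calls, group, rhythmic)
#>   group rhythmic     n
#> 1 C     FALSE      484
#> 2 C     TRUE       104
#> 3 W     FALSE      506
#> 4 W     TRUE        82
#> 5 WRF   FALSE      426
#> 6 WRF   TRUE       162
```

The rhythmic counts reproduce the planted phenotype: fewer rhythmic
genes in shift workers (82 vs 104 in control) and substantially more
under restricted feeding (162), and the phase histogram modes sit at
the planted clusters — WRF peaks pile up in the ZT8–9 bin (24 genes),
while W peaks concentrate after ZT13 (the planted ZT12.5 cluster
rotated ~+2 h by the out-of-phase replicate series).
`plot_phase_rose(calls)` draws the corresponding rose plots.

```r
screen <- differential_expression_screen(study)
dplyr::count(screen, category)
#>   category                n
#> 1 WRF_up_vs_C_and_W      42
#> 2 WRF_down_vs_C_and_W     3
#> 3 W_different             1
#> 4 none                  542
```

Of the 54 planted differentially expressed genes (90% up-regulated
2-fold in WRF responder animals), the screen recovers 42 as
up-regulated in WRF versus both other groups, with misregulation
almost exclusively in the WRF group — the hallmark pattern of this
design. `module_enrichment()`, `module_expression_shift()` and
`ks_shift_test()` then score such hits against module catalogs and
disease gene sets; `autoplot()` methods exist for every result type.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/rhythmshift", package = "rhythmshift"))')
Rscript $CLI simulate --seed 1 --n-genes 600 --out out/
Rscript $CLI rhythm --input out/expression.tsv --out out/
Rscript $CLI de --input out/expression.tsv --out out/
Rscript $CLI signature --input out/expression.tsv --de out/de_results.tsv \
    --modules out/modules.tsv --genesets out/disease_sets.tsv --out out/
```

All outputs are TSV plus a JSON run manifest recording versions, seed
and parameters.

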