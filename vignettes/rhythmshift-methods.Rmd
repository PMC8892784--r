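---
title: "Methods: ensemble rhythm detection and shift-work expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble rhythm detection and shift-work expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmshift)
```

## The problem

Rotating or night-shift work desynchronizes peripheral clocks from the
light–dark cycle, and the heart is among the organs whose transcriptome
reorganizes under such schedules. The experimental design this package
analyzes is an around-the-clock bulk RNA-seq study of rat heart: three
groups — control (C), shift worker (W), and shift worker with food
access restricted to non-work hours (WRF) — each sampled at six
Zeitgeber times (ZT1, 5, 9, 13, 17, 21; every 4 h starting 1 h after
lights-on) with three animals per group and timepoint, one sample per
animal, 54 samples in total. Expression is on the fpkm scale and is
used as given; no re-normalization is performed anywhere in the
pipeline.

Three analysis stages are provided, plus a synthetic-data generator
that emulates the design with planted ground truth so every stage can
be tested for recovery.

## Rhythmicity: six detectors and a Fisher ensemble

Each gene in each group is an 18-point time series (6 ZTs × 3
replicates) tested at a fixed 24 h target period. Detectors that fit
or rank the raw observations (cosinor harmonic regression,
Lomb–Scargle, JTK, RAIN) use all 18 points with repeated time values;
spectral detectors (ARSER, F24) operate on the 6-point per-ZT mean
profile. One sampled cycle cannot resolve finer period structure, so
detectors with a period search are restricted to 20–28 h. Every
detector returns p = 1 on a constant (zero-variance) series so that
the downstream combination is always defined.

**Cosinor harmonic regression.** Least squares for
$y = m + a\cos\omega t + b\sin\omega t$, $\omega = 2\pi/24$;
amplitude $A = \sqrt{a^2+b^2}$, phase = fitted peak time, and p from
the F statistic with $(2, n-3)$ df against the intercept-only model.
This fit also supplies the phase and relative amplitude ($A/m$)
reported for every gene.

**Lomb–Scargle.** The variance-normalized periodogram is scanned over
25 periods in 20–28 h and the maximum power $z$ converted to
$p = 1-(1-e^{-z})^{M}$. $M$ is the Horne–Baliunas effective number of
independent frequencies in the band (observation span × bandwidth,
floored at 1), not the raw grid size: with six timepoints over one
cycle the 20–28 h band spans less than one independent frequency, and
exponentiating by 25 would leave the test with essentially zero
rejection probability at any conventional level.

**JTK.** For each candidate peak time on the sampling grid, Kendall
concordance between the data and a reference cosine (replicates share
their ZT's reference value). The per-lag p-value comes from the exact
null distribution of the concordance count for the reference's tie
pattern, computed by dynamic programming — the Jonckheere–Terpstra
statistic decomposes into independent Mann–Whitney statistics, so the
null is a convolution of Gaussian-binomial coefficient vectors. The
distribution assumes untied data; ties in the data (rare for
continuous input) reuse the same distribution. The reported p is the
per-lag minimum × the number of distinct lag patterns (Bonferroni, the
conservative choice), capped at 1.

**ARSER.** Replicates are averaged per ZT; a Yule–Walker
autoregressive model (order by AIC up to $n/4$) estimates the spectral
density, whose dominant interior peak in 20–28 h selects the period
(falling back to 24 h when the spectrum peaks on the window boundary);
the profile is then tested by cosinor regression at the selected
period. Detrending is handled inside the model: the linear slope is a
nuisance term estimated jointly with the harmonic
($\{1, t, \cos, \sin\}$ vs $\{1, t\}$, F with $(2, n-4)$ df).
Estimating the slope first and then testing the residual with
$(2, n-3)$ df looks harmless but spends an unaccounted degree of
freedom — on a 6-point profile this inflates null rejection at
$\alpha = 0.05$ to ≈ 0.25, which is why the joint form is used.

**RAIN.** For each candidate peak ZT, the Mack–Wolfe peak-known
umbrella statistic over the circular rise-then-fall arrangement of the
six timepoint groups, with the normal approximation and a tie-corrected
variance; minimum over peaks × number of candidates (Bonferroni). Ties
in the best statistic resolve toward the latest peak time.

**F24.** The fraction of non-DC spectral power of the 6-point mean
profile carried by the 24 h fundamental (1 for a pure 24 h cosine, 0
for a pure 12 h harmonic), with significance by permuting the ZT
assignment of the raw observations: $p = (1 + \#\{F^{perm} \ge
F^{obs}\})/(1 + N)$. The single-gene function defaults to $N = 10{,}000$
permutations; the genome-wide screen uses a configurable count
(default 1,000, which bounds the per-gene p at ~$10^{-3}$ — far below
any BH threshold the other detectors cannot reach on their own) and
draws one seeded permutation set shared by all genes. Under
exchangeability each gene's p-value remains valid; sharing only
introduces weak dependence between genes, the same trade-off
permutation-based genomics tools commonly make for speed.

**Calibration.** On 5,000 null genes (flat mesor, multiplicative
log-normal noise, cv 0.2) each detector's empirical rejection at
$\alpha = 0.05$ lies in [0.02, 0.07]; the rank-based tests sit at the
conservative end because of their Bonferroni lag/peak correction. This
is verified in the test suite.

**Combination and calling.** Per gene, the detector p-values are
combined with Fisher's method ($\chi^2 = -2\sum\ln p_i$, $2k$ df;
zeros floored at $10^{-300}$), adjusted across genes within each
group's analysis by Benjamini–Hochberg, and genes with $q < 0.05$ are
called rhythmic. Fisher's method assumes independence, but the six
detectors interrogate the same 18 observations and their p-values are
strongly correlated (pairwise correlations 0.3–0.95 under the null in
our simulations). The combined statistic is therefore overdispersed
(null variance ≈ 78 vs the nominal 24) and the combined p-value is
anti-conservative: its null tail at typical BH thresholds is an order
of magnitude above nominal, so the realized false-discovery proportion
of the default ensemble exceeds the nominal q cutoff substantially —
in our recovery simulations roughly 0.4 at q < 0.05 even though every
individual detector is calibrated. This is a property of the reference
procedure itself, which this package reproduces verbatim by default.
`call_rhythmic_genes(brown = TRUE)` offers an empirical Brown-style
correction (the combined chi-square rescaled by moment matching across
genes) that restores null calibration with little loss of power on
strong rhythms; it is off by default because the reference procedure
combines with plain Fisher.

Sensitivity is not the bottleneck: planted cosinor rhythms at relative
amplitude 0.5 and noise cv 0.15 are recovered essentially completely,
with circular phase error around 0.3 h.

## Differential expression

The screen ignores collection time entirely: each group's 18 samples
are pooled. Genes first pass the expression filter (fpkm strictly
above 1 in at least 18 of 54 samples — the screen that retains ~10,000
genes at full scale). Per gene, a Kruskal–Wallis omnibus test across
the three groups is BH-adjusted across genes; genes with $q \le 0.05$
receive all three pairwise two-sided Mann–Whitney tests (exact by
enumeration when the combined n ≤ 12 without ties, otherwise the
normal approximation with tie and continuity corrections). Post-hoc
p-values are deliberately not multiplicity-adjusted — only the omnibus
layer is — mirroring the reference analysis. Compact letters are the
maximal cliques of the "not significantly different" graph at raw
p < 0.05 (groups sharing a letter are indistinguishable), and each
significant gene is categorized: `WRF_up_vs_C_and_W` when WRF carries
a letter distinct from both others and the highest median (symmetric
for down), `W_different` when W's letter is unique, `other` for the
remaining significant patterns.

## Disease-signature scoring

Module catalogs (with a designated null module M0 of
hypertrophy-insensitive genes) are cross-referenced with the expressed
universe first and then restricted to modules of ≥ 50 genes; M0 must
itself survive the bound.

*Enrichment*: per module, a one-sided Fisher's exact test of the 2×2
table (in module vs in M0) × (in the up-regulated set vs not), flagged
at p < 0.05. The contrast is against M0 specifically, not the whole
universe, because M0 is the designated unaffected reference; a
two-sided option is available.

*Expression shift*: per gene, $\log_2(\mathrm{median}_{WRF} /
\mathrm{median}_{C})$ over the 18 samples of each group. Genes with a
zero median in either group have no defined log ratio; they are
excluded (no pseudocount, which would distort the plotted scale) and
their count is reported. Each module's ratio distribution is compared
to M0's by Kruskal–Wallis, and M0's interquartile band is reported as
the reference spread.

*Distribution shift*: both the background (all genes' ratios) and a
gene set's ratios are reduced to 500 quantiles at probabilities
$(i-0.5)/500$ by linear interpolation of the empirical quantile
function, then compared with the two-sample Kolmogorov–Smirnov test at
effective size 500 each. The normalization removes the raw-size
sensitivity of the KS statistic for large sets, but fixes the
effective n at 500 regardless of the true set size: for sets well
below ~500 genes the test is mildly anti-conservative (a 200-gene null
subset is flagged at roughly 2–3× the nominal rate in our
simulations), and for very large sets it is conservative. Users
scoring small sets should interpret borderline KS p-values with this
in mind.

## The synthetic-data generator

`generate_study()` emulates the statistical structure the analysis
assumes, not the sequencing process. Per gene: a log-normal baseline
(mesor; meanlog $\ln 8$, sdlog 1, fpkm scale), per-group cosinor
rhythms, group fold-changes, and multiplicative log-normal noise with
$\sigma = \sqrt{\ln(1+\mathrm{cv}^2)}$ so the coefficient of variation
equals the configured `noise_cv` (expression is positive and fpkm
variance grows with the mean; the reference study states no noise
model, so this is the package's choice).

Defaults are fixed once to mirror the emulated study's reported
structure and are deliberately not estimates of the real data:

* `frac_rhythmic = c(C = 0.10, W = 0.05, WRF = 0.20)` — about
  two-fold fewer rhythmic genes in W and two-fold more in WRF than in
  control, with draws independent across groups (which also yields the
  reported poor overlap between groups).
* Phases: C uniform over the day; W von Mises centred ZT12.5
  (κ = 6, matching a ZT11–14 cluster); WRF an equal mixture of von
  Mises at ZT8 and ZT20.5 (κ = 8, matching ZT7–9 and ZT20–21
  clusters). Concentrations are config-exposed.
* Relative amplitude 0.5 for rhythmic genes; WRF amplitudes damped by
  0.6 (the restored-but-weakened WRF oscillation).
* One W replicate series (replicate 2, all its ZTs) phase-shifted by
  +8 h — the out-of-phase replicate rhythm that degrades W rhythm
  calls. Note for recovery checks: averaging two in-phase and one
  +8 h-shifted series rotates the fitted group phase by the phasor
  mean, ≈ +2 h.
* A differential-expression block of 9% of genes (90% up at 2-fold,
  10% down), planted in WRF only and gated per WRF animal by a
  Bernoulli(2/3) responder flag, reproducing individual-specific but
  within-individual-homogeneous response blocks.
* `noise_cv = 0.2`, and 10,257 genes at full scale.

What the generator does not emulate: read counts and library-size
effects, gene–gene correlation beyond the planted module/DE structure,
tissue heterogeneity, and any real phase relationships between genes.
Recovery of planted structure therefore demonstrates the pipeline's
statistical behavior under its own assumptions, not performance on
real libraries.

`generate_module_catalog()` assigns genes to modules with an optional
planted fraction drawn from a designated up-set (M0 receives the
background), and `generate_disease_gene_sets()` samples up/down sets
from genes whose planted WRF/C fold change clears a threshold
(`shift_log2 = 0` degenerates to uniform draws).

## Numerical choices and degenerate inputs

* Constant series: p = 1 everywhere, amplitude 0, phase undefined.
* p = 0 underflow floored at $10^{-300}$ before logs.
* JTK/RAIN lag and peak multiplicity: Bonferroni over distinct
  patterns/candidates, capped at 1; RAIN best-statistic ties resolve
  to the latest peak.
* Mann–Whitney exact/approximate switch at combined n = 12; ties
  always use the approximation; a fully tied comparison returns p = 1.
* Near-equal cosine reference values in JTK are rounded to 9 decimals
  before tie-grouping so symmetric timepoints form exact tie groups.
* ZT is encoded in sample labels (`C29ZT17`); an optional sidecar
  metadata table can override labels.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale: 5,000 genes for
detector calibration and recovery runs, 2,500 genes for the
three-group phenotype study, and a few hundred genes for end-to-end
determinism, with F24 permutation counts of 500–1,000 in genome-wide
runs. These sizes give stable empirical rates while keeping a full
test run in minutes; all are the package's own choices and are
config-exposed.

## Known limitations

* The default ensemble's combined p-values are anti-conservative (see
  above); treat the q < 0.05 rhythmic calls as the reference
  procedure's output, not as calibrated FDR control, or enable the
  Brown correction.
* The exact JTK null assumes untied observations.
* The 500-quantile KS test misstates its effective sample size for
  sets far from 500 genes.
* Amplitude differences between groups are reported descriptively
  (relative amplitudes per group); no significance test is attached.
* Complete data are required; missing values are rejected rather than
  imputed.
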