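# snctrends

Sliding-window age-trend analysis of small non-coding RNA (miRNA / snoRNA)
expression in cross-sectional cohorts.

## What it is for

Given a probe x sample matrix of log2 expression intensities and the donors'
ages, `snctrends` answers two questions a blood-aging study asks:

1. **Which sncRNAs change *progressively* with age?** Samples are ordered by
   age and grouped into overlapping windows of `w` consecutive donors
   (default 10, sliding by 1). For probe *i* with per-window mean `m_i(k)`
   z-scored across windows to `z_i(k)`, the screen computes the Pearson
   correlation `r_i = cor(z_i, age_k)` against the window mean ages and the
   last/first fold change `FC_i = 2^(m_i(K) - m_i(1))`, and calls the probe
   *increasing* when `r_i >= 0.75` and `FC_i >= 1.5`, *decreasing* when
   `r_i <= -0.75` and `FC_i <= 1/1.5`. The mean z-trajectories of the two
   hit sets yield a *crossing age* (interpolated sign change of their
   difference) and an *acceleration interval* (longest run of
   top-quartile slopes) — candidate "critical ages" of the cohort.
2. **Which sncRNAs differ between young and elder donors?** A classical
   two-group comparison at the 50-year cutoff using an empirical-Bayes
   moderated t — pooled variances shrunk as
   `s2_mod = (d0*s0^2 + d*s^2)/(d0 + d)` with `(d0, s0^2)` fitted by moments
   on the log residual variances — and Benjamini–Hochberg FDR control.

Downstream stages compare the two screens (per-class overlap, union,
percentage), run the two-stage candidate cascade (|FC| >= 2, then prior
literature support), test miRNA target sets for hypergeometric overlap with
GMT gene-set collections, and validate candidates from qPCR Cq tables by
Livak relative quantification (`RQ = 2^-ddCq`) with exact Wilcoxon rank-sum
tests. A synthetic-cohort generator with logistic age trajectories and
ground-truth labels makes the whole pipeline testable offline.

## Worked example

```r
library(snctrends)

sim <- simulate_cohort(seed = 1)        # 500 probes x 38 donors aged 24-79
scr <- age_trend_screen(sim$expr, sim$metadata)
scr
#> Sliding-window age-trend screen
#>   500 probes, 29 windows of 10 samples (step 1)
#>   thresholds: |r| >= 0.75, FC >= 1.5 or <= 0.67
#>   increasing 50, decreasing 25, none 425

pair <- mean_trajectories(scr)
crossing_age(pair)
#> Trajectory crossing age(s): 50.7 years
#>   primary (youngest): 50.7 years

diff_expression(sim$expr, sim$metadata)
#> Young vs elder differential expression (cutoff 50 y, FDR 0.05)
#>   groups: young 17, elder 21
#>   prior df d0 = 302.7, prior variance = 0.09248
#>   52 UP, 26 DOWN of 500 probes
```

The generator planted 50 increasing and 25 decreasing probes with a logistic
inflection at 50 years: the screen recovers all trend probes (no false
positives among the 425 null probes), and the mean z-trajectories of the two
sets cross at 50.7 years, within a year of the true inflection.
`plot(pair)` draws the two trajectories with the crossing marked.

The whole pipeline — normalization, screen, trajectories, differential
expression, screen comparison, candidate cascade, optional enrichment and
qPCR — runs from one configuration:

```r
report <- run_full(modifyList(default_config(), list(seed = 1)))
report$summary$crossing_age       # 50.5
report$summary$screen_sensitivity # 0.987
```

`run_full()` also has a `fixtures` mode that performs the set algebra and
candidate cascade over the bundled reference hit lists (see
`?load_fixture`), requiring no expression matrix.

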