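# suturemorph

Geometric morphometrics and spectral complexity scoring of 2D cranial
suture outlines, built around the human midpalatal suture.

The midpalatal suture interdigitates progressively with age, and its
complexity matters clinically: heavily interdigitated sutures resist
orthodontic palatal expansion. Starting from digitised outline traces
(anterior → posterior polylines, e.g. from cone-beam CT reconstructions),
`suturemorph` provides the full analysis chain:

1. **Semi-landmarks** — resample every trace to a fixed count (default 500)
   of equidistant points, then slide interior points along the curve to
   minimise each specimen's Procrustes distance to the sample consensus.
2. **Superimposition** — generalised Procrustes analysis (translation,
   scale, and rotation removed; reflections disallowed; canonical
   principal-axes orientation).
3. **Morphospace** — covariance PCA of the aligned shape coordinates, with
   specimen scores, explained-variance summaries, and extreme-shape
   reconstruction along components.
4. **Complexity** — a windowed short-time Fourier transform
   power-spectral-density (PSD) score per suture: the curve's
   perpendicular-deviation signal is cut into tapered overlapping windows,
   squared DFT coefficients are averaged per frequency across windows, and
   the averages are summed over harmonics. Straight sutures score exactly
   0; rising values mean deeper, denser interdigitation.
5. **Statistics** — Shapiro–Wilk gate, sequential ANOVA of
   `score ~ age + sex + age:sex` (age continuous, 1 DF per term),
   Welch pairwise age-group t tests with Holm–Bonferroni correction, and
   ICC(A,1) intra-rater reliability across repeated digitisation sessions.

Because no clinical dataset ships with the package, a parametric generator
(`generate_suture()`, `generate_cohort()`) produces suture outlines with
known ground truth — quadratic baseline trend, posterior loop bump,
odd-harmonic interdigitation whose amplitude is linked to age, and
digitisation noise — structured as a 48-specimen cohort in four age
quartiles (20 male / 28 female) by default. I/O covers long/wide delimited
coordinate tables and TPS landmark files.

## Worked example

```r
library(suturemorph)

cohort   <- generate_cohort(cohort_spec(seed = 1))   # 48 synthetic sutures
analysis <- analyze_cohort(cohort, run_config())     # full pipeline
analysis
#> <suture_analysis> 48 specimens, 500 semi-landmarks
#>   PC1 53.6%, PC2 24.7% of shape variance
#>   PSD complexity: mean 2.6288e-06, sd 9.4364e-07
#>   ANOVA: age F = 156.11 (p = 4.54e-16); sex F = 0.98495 (p = 0.326)

analysis$stats$pairwise
#> Pairwise group comparisons (Welch t, Holm-adjusted)
#>    pair     p_raw    p_holm sig
#>  1 vs 2 7.280e-02 7.280e-02
#>  1 vs 3 3.513e-04 1.405e-03   *
#>  1 vs 4 2.075e-08 1.245e-07   *
#>  2 vs 3 5.986e-03 1.197e-02   *
#>  2 vs 4 1.819e-07 9.094e-07   *
#>  3 vs 4 1.341e-03 4.022e-03   *
```

The ANOVA recovers the generator's ground truth: complexity rises strongly
with age (the generator links interdigitation amplitude to age) while sex —
which has no shape link in the generator — stays non-significant, and the
non-adjacent age-group contrasts survive Holm correction. The absolute PSD
score scale is the raw harmonic-power sum of a unit-centroid-size shape;
only comparisons under identical STFT parameters are meaningful, so every
result embeds its parameter set.

Reliability across repeated digitisations of the same outlines:

```r
rel <- reliability_analysis(
  generate_cohort(cohort_spec(seed = 1, session2_jitter_sd = 0.002)))
rel
#> <reliability_report> ICC = 0.9779 [two-way, absolute agreement,
#>   single measurement (ICC(A,1)); 48 subjects x 2 sessions]
```

`write_analysis(analysis, "out/")` exports aligned coordinates, the
morphospace table, the score table with a JSON parameter sidecar, the
statistics report, and the exact run config; a thin command-line wrapper
with `simulate` / `analyze` / `reliability` subcommands lives at
`inst/cli/suturemorph.R`.

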