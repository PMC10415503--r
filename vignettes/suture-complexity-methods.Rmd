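---
title: "Morphometrics and spectral complexity of suture outlines: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometrics and spectral complexity of suture outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suturemorph)
```

## The problem

The midpalatal suture — the fibrous joint between the two palatine processes
of the maxilla — interdigitates progressively with age, and the degree of
interdigitation bears directly on whether orthodontic palatal expansion can
succeed without surgical assistance. Given a two-dimensional outline of the
suture traced from a cone-beam CT reconstruction (anterior to posterior),
`suturemorph` quantifies its shape and its interdigitation complexity and
compares cohorts of such outlines statistically.

The pipeline is: equidistant semi-landmark resampling → Procrustes-distance
sliding → generalised Procrustes superimposition (GPA) → PCA morphospace →
windowed-STFT power-spectral-density (PSD) complexity score → normality
gate, factorial ANOVA, Holm-corrected pairwise t tests, and intraclass
correlation for repeated digitisations.

## Semi-landmarks

A raw trace is an ordered polyline of arbitrary density (≥ 2 points).
`resample_equidistant()` places `n = 500` points at exactly equal arc-length
intervals (linear interpolation within segments; endpoints fixed). 500
points per suture is the pipeline's working density: comfortably above the
Nyquist requirement for the interdigitation frequencies of interest
(tens of cycles per suture) while keeping downstream linear algebra cheap.

Because equidistant placement is arbitrary with respect to anatomy,
`slide_semilandmarks()` then treats interior points as deficient in the
along-curve direction and slides them to minimise each specimen's full
Procrustes distance to the sample consensus (the bending-energy criterion is
the other convention in the morphometrics literature; this package
implements only the Procrustes-distance criterion). The scheme alternates:

1. GPA of the current curves; unit-size consensus $\hat c$.
2. Per specimen, each interior point is displaced along the *local polyline
   segment direction* by the least-squares projection of the residual
   $\hat c_j - \langle a, \hat c\rangle\, a_j$ onto that direction (the
   $\langle a,\hat c\rangle$ factor is the gradient correction for the
   unit-centroid-size constraint).
3. Offsets are clamped to 45% of the gap to each neighbour, so points can
   never cross and the curve stays an ordered function of arc position.
4. The point is re-projected onto the original polyline (no point ever
   leaves the digitised trace), and the step is halved (up to 7 times)
   whenever it would increase that specimen's Procrustes distance to the
   current consensus — making the recorded objective non-increasing.

Iteration stops when the relative change of the total Procrustes sum of
squares falls below `tol` (default 1e-6) or after `max_iter` (default 10)
sweeps. Two numerical facts found while validating against a brute-force
per-point grid search are worth recording: the correct sliding direction is
the polyline's own segment direction, not the chord between flanking
semi-landmarks (with coarse curves these differ enough to stall the
descent); and mutual sliding has a near-flat "common drift" mode — all
curves sliding together changes relative distances only marginally — so the
optimum is a shallow valley rather than a sharp point. Validation therefore
checks that the result is at least as good as, and stationary under,
exhaustive per-point grid search.

## Superimposition

`gpa()` is full generalised Procrustes analysis: every configuration is
centred, scaled to unit centroid size, and rotated to the evolving
consensus; the consensus is the renormalised mean, and iteration ends when
its root-mean-square change drops below `tol` (default 1e-10, `max_iter`
100). Three conventions matter:

* **Reflections are disallowed** (the rotation is constrained to
  determinant +1). Sutures have a fixed anatomical orientation; permitting
  reflection could silently flip a posterior loop from left to right.
* **The rotational gauge is pinned.** Within the loop the new consensus is
  rotated back onto the previous one, so the convergence measure reflects
  shape change rather than orientation drift; afterwards the whole sample is
  rotated once so the consensus lies on its principal axes with the major
  axis running anterior → posterior (first to last semi-landmark). Aligned
  coordinates are therefore invariant (to ~1e-15) under any rigid motion or
  rescaling of the input traces, and byte-reproducible across runs.
* **Initialisation from the mean**, which makes `gpa()` idempotent: re-run
  on its own output it converges in one iteration.

## Morphospace

`pca_shapes()` performs covariance PCA of the flattened aligned coordinates
about the consensus (no correlation scaling — coordinates share units after
superimposition; no tangent-space projection beyond the superimposition
itself). Eigenvector signs are fixed by forcing each loading's
largest-magnitude entry positive, so component orientations cannot flip
between runs. `shape_along_pc()` reconstructs outline shapes at chosen
scores for extreme-shape figures, and `n_components_for_variance()` reports
how many components exceed a cumulative variance threshold.

## The PSD complexity score

The score condenses interdigitation amplitude, count, and looping into one
number. Two conventions are deliberate choices where reasonable alternatives
exist:

* **2D → 1D conversion.** `curve_to_signal()` rotates each aligned curve to
  its own principal axis and takes the perpendicular deviations of the
  semi-landmarks, mean-centred. This is parameter-free, rotation-invariant,
  and degenerates exactly to the zero signal for a straight suture, so a
  straight outline scores exactly 0.
* **Spectral estimate.** `stft()` cuts the signal into windows of
  `window_length = 64` samples at 50% overlap with a Hann taper, and returns
  one-sided squared DFT magnitudes normalised by `window_length^2` (off-DC
  bins doubled), so that with a rectangular taper each window's power sums
  to its mean squared signal (Parseval). Windows that would overrun the
  signal end are dropped rather than zero-padded, because padding injects
  artificial spectral content at the suture ends. `psd_complexity()`
  averages the squared coefficients per frequency across windows and sums
  the averages over harmonics, excluding DC by default (`include_dc`), with
  an optional harmonic cut-off (`max_harmonic`).

The defaults (64-sample Hann windows, 50% overlap over 500 semi-landmarks,
giving 14 windows) trade frequency resolution against stationarity: suture
interdigitation is not homogeneous along the suture, which is the reason for
a *short-time* transform in the first place. The score is the raw
harmonic-power sum of a unit-centroid-size shape; it has no absolute
physical scale, and scores are only comparable between analyses run under
identical parameters — which is why the full parameter set is embedded in
every result and exported as a JSON sidecar next to every score table. An
optional affine report transform (`scale`, `offset`) exists for
presentation but is the identity by default.

Useful exact properties (all tested): straight sutures score 0; scaling the
deviation signal by $k$ scales the score by $k^2$; scores are invariant
under rigid motion of the raw traces; with a rectangular window and DC
included the per-frequency powers sum to the window-averaged mean squared
signal to 1e-9.

## Statistics

The battery mirrors standard practice for cohort comparisons of a single
morphometric score:

* `shapiro_wilk_gate()` — Shapiro–Wilk normality check at α = 0.05
  (Royston's approximation via `stats::shapiro.test`), gating the
  parametric branch.
* `complexity_anova()` — sequential (type I) ANOVA of
  `score ~ age + sex + age:sex` with **age continuous**, so every term has
  one degree of freedom; a quartile-factor age coding (3 DF) is available
  behind `age_as_factor` for sensitivity analysis. With `ages = NULL` the
  model reduces to `score ~ sex`, where the sex F statistic equals the
  squared pooled t statistic.
* `assign_age_quartiles()` — sample-quartile groups with right-closed
  intervals ("> a to ≤ b"), so a specimen exactly on a cut point falls in
  the lower group.
* `pairwise_group_tests()` — Welch t tests for every unordered group pair
  (the robust default where within-group variances differ; a
  pooled-variance variant sits behind `var_equal`), Holm–Bonferroni
  corrected via `holm_adjust()`.
* `intra_rater_icc()` — ICC(A,1): two-way model, absolute agreement, single
  measurement, computed from the subjects × sessions mean-squares
  decomposition. This is the strictest common intra-rater convention — it
  penalises session-level offsets that a consistency ICC would forgive —
  and the model descriptor is carried in every report so the convention is
  explicit. The consistency form is reported alongside for comparison.

## The synthetic cohort generator

No clinical dataset ships with the package, so `generate_suture()` /
`generate_cohort()` provide parametric outlines with known ground truth.
One outline is

$$y(x) = \underbrace{-4\,b\,t(1-t)}_{\text{baseline}}
        + \underbrace{a_\ell e^{-((t-p)/w)^2}}_{\text{posterior loop}}
        + \underbrace{A\,\frac{\sum_{j=0}^{2} d^{\,j}
            \sin\!\big((2j+1)(2\pi k t + \varphi)\big)}{\max|\cdot|}}_{\text{interdigitation}}
        + \varepsilon,\qquad t = x/L,$$

with curvature $b$ (negative convex, positive concave — the PC1-style
contrast), a Gaussian loop bump at arc fraction $p$ (the PC2-style posterior
loop), an odd-harmonic interdigitation series (frequencies $k, 3k, 5k$,
geometric decay $d$) giving finger-like rather than purely sinusoidal
margins, and white digitisation noise $\varepsilon$. The odd-harmonic series
is antisymmetric over half a cycle and normalised to peak amplitude exactly
$A\cdot L$, so a noise-free outline's peak-to-trough is exactly $2AL$ and
ground-truth complexity has a closed form (the outline's mean squared
deviation). Outlines are restricted to single-valued functions $y(x)$; true
self-overlapping loops are emulated by the bump term, and parameter
combinations steeper than $|dy/dx| = 20$ are rejected.

Cohort defaults emulate a 48-patient sample: four age-quartile groups of 12
spanning ≤ 14, > 14–21, > 21–49 and > 49 years (drawn uniformly within
group ranges bounded at 8 and 66 years), 5/6/5/4 males per group (20 male,
28 female). Interdigitation amplitude is linked to age as
$A = 0.015 + 4\times10^{-4}\,\mathrm{age}$ (fraction of suture length) with
normal scatter (sd 0.004): amplitude roughly doubles from childhood to late
adulthood, consistent with the histological picture of progressive
interdigitation, while the scatter keeps individual overlap between
adjacent age groups substantial. Sex has no shape link by default
(`sex_effect = 0`) — the null the statistics should not reject. Noise is
0.002 of suture length, the scale of manual tracing error. Per-specimen
seeds derive from the master seed by a counter-based mixing, so adding a
specimen never shifts the randomness of the others and every cohort is a
pure function of its spec.

What the generator does *not* emulate: true suture overhangs and
self-intersections, spatially varying interdigitation density, correlated
(non-white) digitisation error, and any real relationship between suture
shape and sex. Passing tests therefore demonstrate the pipeline's internal
correctness and its sensitivity/specificity under these idealised
conditions, not clinical performance on CBCT tracings.

## Problem sizes used in the validation suite

The package's property checks run at sizes chosen to make the full suite
fast enough to run on every change while keeping every contract at full
strength where it matters:

* the semi-landmark contract and the end-to-end worked examples run at the
  full default (500 semi-landmarks, sliding on);
* the seed-sweep calibrations (500 null cohorts for the 5% level of the age
  term; 200 age-linked cohorts for the headline-pattern recovery rate) run
  at 100 semi-landmarks with 32-sample windows and sliding off — sliding
  moves points *along* outlines and is irrelevant to the level/power of the
  downstream ANOVA;
* the sliding-vs-grid-search oracle runs on 5-point curves, where the
  brute-force search is exhaustive.

## Known limitations

* The score's absolute scale is the raw harmonic-power sum of a unit-size
  shape; values from differently parameterised runs, or from other PSD
  implementations with different normalisations, are not comparable.
* Procrustes-distance sliding can in principle let semi-landmarks drift
  along near-flat directions of the objective; the iteration cap and the
  no-crossing clamp bound this in practice.
* The ANOVA treats age linearly; a strongly non-linear age effect would be
  better served by the quartile-factor coding or a smooth term, neither of
  which is the default.
* 2D outlines only: the suture's three-dimensional topography is outside
  the package's scope.
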