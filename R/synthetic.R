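# Run fn with a private RNG state so generation never disturbs (and is never
# disturbed by) the caller's random stream.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Counter-based per-specimen seed: a fixed mixing of (master, index, stream)
# so adding a specimen never shifts the randomness of the others.
.derive_seed <- function(master, index, stream = 0L) {
  as.integer((as.double(master) %% 2147483647 * 48271 +
                index * 69621 + stream * 40014) %% 2147483629) + 1L
}

#' Parametric specification of one synthetic suture outline
#'
#' The generator emulates the morphological features of midpalatal suture
#' outlines seen in cone-beam CT tracings: a convex/concave quadratic
#' baseline trend, a localised posterior loop bump, sinusoidal
#' interdigitation built from a decaying odd-harmonic series, and white
#' digitisation noise. Outlines are restricted to single-valued functions
#' y(x) of the anterior-posterior axis so that ground-truth complexity has a
#' closed form; true self-overlapping loops are emulated by the bump term.
#'
#' The interdigitation waveform uses harmonics at 1x, 3x and 5x the cycle
#' frequency with amplitudes decaying geometrically, normalised so that its
#' peak amplitude is exactly `interdigitation_amplitude * length` — the
#' peak-to-trough excursion of a noise-free outline is therefore twice that.
#'
#' @param n_raw_points Number of digitised points along the outline.
#' @param length Suture length in arbitrary planar units.
#' @param baseline_curvature Quadratic trend: negative = convex, positive =
#'   concave.
#' @param loop_amplitude,loop_position,loop_width Gaussian bump emulating a
#'   posterior loop: amplitude as a fraction of length, centre position as a
#'   fraction of the arc, width as a fraction of the arc.
#' @param interdigitation_amplitude Peak interdigitation amplitude as a
#'   fraction of length (nonnegative).
#' @param interdigitation_cycles Number of interdigitation cycles along the
#'   suture (positive integer).
#' @param harmonic_decay Geometric decay of the overtone amplitudes, in
#'   (0, 1].
#' @param noise_sd Standard deviation of white digitisation noise as a
#'   fraction of length.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `suture_spec`.
#' @export
suture_spec <- function(n_raw_points = 400L, length = 1,
                        baseline_curvature = 0.05,
                        loop_amplitude = 0.03, loop_position = 0.8,
                        loop_width = 0.06,
                        interdigitation_amplitude = 0.03,
                        interdigitation_cycles = 8L,
                        harmonic_decay = 0.35,
                        noise_sd = 0.002, seed = 1L) {
  spec <- list(n_raw_points = as.integer(n_raw_points), length = length,
               baseline_curvature = baseline_curvature,
               loop_amplitude = loop_amplitude, loop_position = loop_position,
               loop_width = loop_width,
               interdigitation_amplitude = interdigitation_amplitude,
               interdigitation_cycles = as.integer(interdigitation_cycles),
               harmonic_decay = harmonic_decay,
               noise_sd = noise_sd, seed = as.integer(seed))
  if (spec$n_raw_points < 10L) stop("n_raw_points must be at least 10")
  if (spec$length <= 0) stop("length must be positive")
  if (spec$interdigitation_amplitude < 0) stop("amplitude must be nonnegative")
  if (spec$interdigitation_cycles < 1L) stop("cycles must be positive")
  if (spec$harmonic_decay <= 0 || spec$harmonic_decay > 1)
    stop("harmonic_decay must be in (0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (spec$loop_position <= 0 || spec$loop_position >= 1)
    stop("loop_position must be in (0, 1)")
  structure(spec, class = "suture_spec")
}

# Normalised odd-harmonic interdigitation waveform at arc fractions t:
# antisymmetric over half a cycle, so min = -max and the peak is exact.
.interdig_wave <- function(t, cycles, decay, phase) {
  w <- 0
  for (j in 0:2)
    w <- w + decay^j * sin((2 * j + 1) * (2 * pi * cycles * t + phase))
  dense <- seq(0, 1, length.out = 4096)
  wd <- 0
  for (j in 0:2)
    wd <- wd + decay^j * sin((2 * j + 1) * (2 * pi * cycles * dense + phase))
  w / max(abs(wd))
}

#' Generate one synthetic suture trace
#'
#' Samples `y(x) = baseline + loop bump + interdigitation + noise` at
#' `n_raw_points` along `x` in `[0, length]`. Deterministic for a fixed
#' spec (the spec's seed drives the interdigitation phase and the noise).
#' The noiseless outline's maximum absolute slope is checked; parameter
#' combinations steep enough to approximate a self-intersecting
#' parameterisation are rejected.
#'
#' @param spec A [suture_spec()].
#' @param specimen_id Id given to the generated trace.
#' @param age,sex,session Metadata attached to the trace.
#' @return A [raw_trace()].
#' @export
generate_suture <- function(spec, specimen_id = "synthetic",
                            age = NA_real_, sex = NA_character_,
                            session = 1L) {
  if (!inherits(spec, "suture_spec")) stop("spec must be a suture_spec")
  .with_seed(spec$seed, function() {
    l <- spec$length
    t <- seq(0, 1, length.out = spec$n_raw_points)
    phase <- stats::runif(1, 0, 2 * pi)
    y_base <- -spec$baseline_curvature * l * 4 * t * (1 - t)
    y_loop <- spec$loop_amplitude * l *
      exp(-((t - spec$loop_position) / spec$loop_width)^2)
    y_int <- if (spec$interdigitation_amplitude > 0)
      spec$interdigitation_amplitude * l *
        .interdig_wave(t, spec$interdigitation_cycles, spec$harmonic_decay,
                       phase)
    else 0
    y_clean <- y_base + y_loop + y_int
    slope <- max(abs(diff(y_clean) / diff(t * l)))
    if (slope > 20)
      stop("parameter error: outline too steep (max |dy/dx| = ",
           signif(slope, 3), " > 20); reduce amplitudes or cycle count")
    y <- y_clean + stats::rnorm(spec$n_raw_points, 0, spec$noise_sd * l)
    raw_trace(specimen_id, cbind(t * l, y), age = age, sex = sex,
              session = session)
  })
}

#' Specification of a synthetic suture cohort
#'
#' Defaults emulate a 48-patient cohort split into four age-quartile groups
#' of 12 spanning <= 14, >14-21, >21-49 and > 49 years, with 5/6/5/4 males
#' (20 male, 28 female overall). Interdigitation amplitude is linked to age
#' as `amplitude_intercept + amplitude_slope * age` plus normal scatter —
#' the known ground truth against which the pipeline's age effect is tested.
#' Sex has no shape link by default (`sex_effect = 0`).
#'
#' @param group_sizes Specimens per age group.
#' @param age_breaks Group boundaries in years, length `length(group_sizes)+1`;
#'   group g spans `(age_breaks[g], age_breaks[g+1]]`.
#' @param males_per_group Male count per group (rest are female).
#' @param amplitude_intercept,amplitude_slope Age-to-amplitude link
#'   (fraction of suture length; slope per year).
#' @param amplitude_sd Normal scatter of the per-specimen amplitude.
#' @param sex_effect Additive amplitude shift for males (default 0: none).
#' @param base A [suture_spec()] supplying every other outline parameter.
#' @param session2_jitter_sd If non-`NULL`, a second digitisation session is
#'   generated per specimen by adding coordinate jitter of this sd (fraction
#'   of length) — the input for the reliability analysis.
#' @param seed Master seed; the whole cohort is a pure function of spec and
#'   seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(12L, 12L, 12L, 12L),
                        age_breaks = c(8, 14, 21, 49, 66),
                        males_per_group = c(5L, 6L, 5L, 4L),
                        amplitude_intercept = 0.015,
                        amplitude_slope = 4e-4,
                        amplitude_sd = 0.004,
                        sex_effect = 0,
                        base = suture_spec(),
                        session2_jitter_sd = NULL,
                        seed = 1L) {
  if (length(age_breaks) != length(group_sizes) + 1L)
    stop("age_breaks must have one more element than group_sizes")
  if (any(diff(age_breaks) <= 0))
    stop("age ranges must be non-overlapping and ordered")
  if (any(group_sizes < 1L)) stop("group sizes must be positive")
  if (length(males_per_group) != length(group_sizes) ||
      any(males_per_group < 0L) || any(males_per_group > group_sizes))
    stop("males_per_group must fit within group_sizes")
  structure(list(group_sizes = as.integer(group_sizes),
                 age_breaks = age_breaks,
                 males_per_group = as.integer(males_per_group),
                 amplitude_intercept = amplitude_intercept,
                 amplitude_slope = amplitude_slope,
                 amplitude_sd = amplitude_sd,
                 sex_effect = sex_effect, base = base,
                 session2_jitter_sd = session2_jitter_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic suture cohort
#'
#' Draws per-specimen ages uniformly within their group's range, sets each
#' specimen's interdigitation amplitude through the age link, and generates
#' the traces with per-specimen seeds derived from the master seed by a
#' counter-based scheme (adding a specimen never shifts the others'
#' randomness). When the spec requests a second session, jittered
#' re-digitisations of the same outlines are appended with `session = 2`.
#'
#' @param spec A [cohort_spec()].
#' @return A [suture_cohort()] with ages, sexes and group labels; the
#'   per-specimen ground truth (amplitude, seeds) is attached as attribute
#'   `"ground_truth"` (a data frame).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  g_of <- rep(seq_along(spec$group_sizes), spec$group_sizes)
  n <- length(g_of)
  ids <- sprintf("S%02d", seq_len(n))
  sex <- unlist(lapply(seq_along(spec$group_sizes), function(g)
    c(rep("male", spec$males_per_group[g]),
      rep("female", spec$group_sizes[g] - spec$males_per_group[g]))))
  ages <- numeric(n)
  amps <- numeric(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    g <- g_of[i]
    meta_seed <- .derive_seed(spec$seed, i, 0L)
    ages[i] <- .with_seed(meta_seed, function()
      stats::runif(1, spec$age_breaks[g], spec$age_breaks[g + 1L]))
    amps[i] <- .with_seed(meta_seed + 1L, function()
      max(1e-4, spec$amplitude_intercept + spec$amplitude_slope * ages[i] +
            spec$sex_effect * (sex[i] == "male") +
            stats::rnorm(1, 0, spec$amplitude_sd)))
    sspec <- spec$base
    sspec$interdigitation_amplitude <- amps[i]
    sspec$seed <- .derive_seed(spec$seed, i, 1L)
    traces[[i]] <- generate_suture(sspec, specimen_id = ids[i],
                                   age = ages[i], sex = sex[i])
  }
  if (!is.null(spec$session2_jitter_sd)) {
    jsd <- spec$session2_jitter_sd * spec$base$length
    traces2 <- lapply(seq_len(n), function(i) {
      tr <- traces[[i]]
      pts <- .with_seed(.derive_seed(spec$seed, i, 2L), function()
        tr$points + matrix(stats::rnorm(length(tr$points), 0, jsd),
                           ncol = 2L))
      raw_trace(tr$specimen_id, pts, age = tr$age, sex = tr$sex, session = 2L)
    })
    traces <- c(traces, traces2)
  }
  cohort <- suture_cohort(traces, stats::setNames(as.integer(g_of), ids))
  attr(cohort, "ground_truth") <- data.frame(
    specimen_id = ids, group = g_of, age = ages, sex = sex, amplitude = amps,
    stringsAsFactors = FALSE)
  cohort
}

#' Write a cohort's ground-truth sidecar
#'
#' Exports the per-specimen generating parameters of a synthetic cohort
#' (amplitudes, ages, groups) as JSON, for test harnesses that need the
#' generator's ground truth next to the trace files.
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path) {
  gt <- attr(cohort, "ground_truth")
  if (is.null(gt)) stop("cohort carries no ground truth (not synthetic?)")
  jsonlite::write_json(gt, path, digits = NA)
  invisible(path)
}
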