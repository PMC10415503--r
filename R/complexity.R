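#' Parameters of the PSD complexity score
#'
#' Free parameters of the windowed short-time Fourier transform behind the
#' complexity score. Defaults: 64-sample windows over the 500 semi-landmarks,
#' Hann taper, 50% overlap, DC excluded, all harmonics summed. Scores are
#' only comparable between analyses run under identical parameters, so the
#' parameter set is embedded in every result.
#'
#' @param window_length Window length in samples (must not exceed the signal
#'   length at use time).
#' @param overlap_fraction Fractional overlap between successive windows in
#'   [0, 1); `window_length * (1 - overlap_fraction)` must be a whole number
#'   of samples.
#' @param window_function `"hann"` or `"rectangular"` taper.
#' @param include_dc Include the zero-frequency term in the score.
#' @param max_harmonic Highest harmonic summed into the score, or `"all"`.
#' @return An object of class `complexity_params`.
#' @export
complexity_params <- function(window_length = 64L, overlap_fraction = 0.5,
                              window_function = c("hann", "rectangular"),
                              include_dc = FALSE, max_harmonic = "all") {
  window_function <- match.arg(window_function)
  window_length <- as.integer(window_length)
  if (window_length < 2L) stop("window_length must be at least 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  step <- window_length * (1 - overlap_fraction)
  if (abs(step - round(step)) > 1e-9)
    stop("window_length * (1 - overlap_fraction) must be a whole number of samples")
  if (!identical(max_harmonic, "all")) {
    max_harmonic <- as.integer(max_harmonic)
    if (max_harmonic < 1L) stop("max_harmonic must be >= 1 or 'all'")
  }
  structure(list(window_length = window_length,
                 overlap_fraction = overlap_fraction,
                 window_function = window_function,
                 include_dc = isTRUE(include_dc),
                 max_harmonic = max_harmonic,
                 step = as.integer(round(step))),
            class = "complexity_params")
}

.window_taper <- function(params) {
  l <- params$window_length
  switch(params$window_function,
         hann = 0.5 * (1 - cos(2 * pi * (0:(l - 1L)) / (l - 1L))),
         rectangular = rep(1, l))
}

#' Convert an aligned curve to its 1D deviation signal
#'
#' Rotates the curve to its own principal axis (the major axis of the point
#' covariance), takes the perpendicular-axis coordinate of each semi-landmark
#' in order, and subtracts the mean. The construction is parameter-free and
#' rotation-invariant, and yields the all-zero signal for a perfectly
#' straight suture, so the downstream score degenerates correctly to zero.
#' The major-axis direction is oriented anterior-to-posterior (first to last
#' semi-landmark) so the sampling order of the signal is anatomical.
#'
#' @param coords n x 2 aligned shape coordinates, n >= 4.
#' @return Zero-mean numeric vector of length n.
#' @export
curve_to_signal <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) stop("need at least 4 semi-landmarks")
  centred <- scale(coords, scale = FALSE)
  if (sum(centred^2) == 0) stop("degenerate geometry: zero-variance curve")
  ev <- eigen(crossprod(centred) / n, symmetric = TRUE)
  major <- ev$vectors[, 1L]
  chord <- coords[n, ] - coords[1L, ]
  if (sum(chord * major) < 0) major <- -major
  perp <- c(-major[2L], major[1L])  # right-handed frame
  sig <- as.vector(centred %*% perp)
  sig - mean(sig)
}

#' Windowed short-time Fourier transform power
#'
#' Cuts the signal into windows of `window_length` with the configured
#' overlap, tapers each window, applies the discrete Fourier transform, and
#' returns one-sided squared magnitudes: entry (w, f) is the power of window
#' w at harmonic f-1. Powers are normalised by `window_length^2` with
#' off-DC/non-Nyquist bins doubled, so that with a rectangular taper the row
#' sum equals the window's mean squared signal (Parseval). Windows that
#' would overrun the signal end are dropped — no zero padding, which would
#' inject artificial spectral content at the suture ends.
#'
#' @param signal Numeric vector, at least `window_length` long.
#' @param params A [complexity_params()] object.
#' @return n_windows x (floor(window_length/2) + 1) matrix; columns named by
#'   harmonic number starting at 0 (DC).
#' @export
stft <- function(signal, params = complexity_params()) {
  if (!inherits(params, "complexity_params"))
    stop("params must be a complexity_params object")
  l <- params$window_length
  n <- length(signal)
  if (n < l) stop("window length ", l, " exceeds signal length ", n)
  step <- params$step
  starts <- seq(1L, n - l + 1L, by = step)
  taper <- .window_taper(params)
  half <- l %/% 2L
  fold <- c(1, rep(2, half - 1L), if (l %% 2L == 0L) 1 else 2)
  out <- t(vapply(starts, function(a) {
    x <- signal[a:(a + l - 1L)] * taper
    p <- Mod(stats::fft(x))^2 / l^2
    p[1:(half + 1L)] * fold
  }, numeric(half + 1L)))
  dimnames(out) <- list(NULL, as.character(0:half))
  out
}

#' PSD complexity score of a deviation signal
#'
#' The score averages the squared windowed short-time Fourier transform
#' coefficients at each frequency across the local transforms and sums the
#' averages over the harmonics: low scores indicate a straight suture
#' outline, rising scores indicate progressively interdigitated outlines
#' with pronounced loops and amplitudes. The DC term is excluded unless
#' `include_dc`; the harmonic range can be truncated via `max_harmonic`.
#' The score is the raw harmonic-power sum, so only comparisons under
#' identical parameters are meaningful; an optional affine report transform
#' (`scale`, `offset`) is available for presentation but defaults to the
#' identity.
#'
#' @param signal Numeric deviation signal (see [curve_to_signal()]).
#' @param params A [complexity_params()] object.
#' @param specimen_id Optional id carried into the result.
#' @param scale,offset Optional affine report transform applied as
#'   `scale * score + offset` (defaults 1, 0: raw score).
#' @return An object of class `complexity_result`: `specimen_id`, `score`,
#'   `raw_score`, `params`, `n_windows`, `per_frequency_power`.
#' @export
psd_complexity <- function(signal, params = complexity_params(),
                           specimen_id = NA_character_, scale = 1, offset = 0) {
  pow <- stft(signal, params)
  pfp <- colMeans(pow)
  harm <- as.integer(colnames(pow))
  keep <- if (params$include_dc) rep(TRUE, length(harm)) else harm >= 1L
  if (!identical(params$max_harmonic, "all"))
    keep <- keep & harm <= params$max_harmonic
  raw <- sum(pfp[keep])
  structure(list(specimen_id = specimen_id,
                 score = scale * raw + offset, raw_score = raw,
                 params = params, n_windows = nrow(pow),
                 per_frequency_power = pfp),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat("<complexity_result> ", if (!is.na(x$specimen_id)) x$specimen_id else "",
      " score ", format(x$score, digits = 6), " (", x$n_windows, " windows, ",
      x$params$window_function, " ", x$params$window_length, ")\n", sep = "")
  invisible(x)
}

#' PSD complexity scores for a superimposed sample
#'
#' Runs [curve_to_signal()] then [psd_complexity()] for every specimen of an
#' aligned sample under one shared parameter set.
#'
#' @param sample An `aligned_sample` from [gpa()].
#' @param params A [complexity_params()] object applied to all specimens.
#' @param scale,offset Optional affine report transform (see
#'   [psd_complexity()]).
#' @return An object of class `complexity_set`: a list of
#'   `complexity_result` objects plus the shared `params`;
#'   `as.data.frame()` gives the specimen/score table.
#' @export
score_sample <- function(sample, params = complexity_params(),
                         scale = 1, offset = 0) {
  if (!inherits(sample, "aligned_sample")) stop("sample must be an aligned_sample")
  m <- dim(sample$aligned)[3L]
  if (m < 1L) stop("empty sample")
  ids <- dimnames(sample$aligned)[[3L]]
  results <- lapply(seq_len(m), function(i)
    psd_complexity(curve_to_signal(sample$aligned[, , i]), params,
                   specimen_id = ids[i], scale = scale, offset = offset))
  structure(list(results = results, params = params, info = sample$info),
            class = "complexity_set")
}

#' @export
as.data.frame.complexity_set <- function(x, ...) {
  data.frame(specimen_id = vapply(x$results, `[[`, character(1), "specimen_id"),
             score = vapply(x$results, `[[`, numeric(1), "score"),
             n_windows = vapply(x$results, `[[`, integer(1), "n_windows"),
             stringsAsFactors = FALSE)
}

#' @export
print.complexity_set <- function(x, ...) {
  s <- vapply(x$results, `[[`, numeric(1), "score")
  cat("<complexity_set> ", length(s), " specimens; score mean ",
      format(mean(s), digits = 6), ", sd ", format(stats::sd(s), digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Export complexity scores with a parameter sidecar
#'
#' Writes the specimen/score table as delimited text and the exact
#' [complexity_params()] used as a JSON sidecar (`<path>.params.json`) for
#' provenance, since scores are only comparable under identical parameters.
#'
#' @param scores A `complexity_set`.
#' @param path Output table path.
#' @return `path`, invisibly.
#' @export
write_complexity_scores <- function(scores, path) {
  if (!inherits(scores, "complexity_set")) stop("scores must be a complexity_set")
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(scores$params), paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
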