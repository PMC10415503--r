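# Independent oracles used across the suite. Each deliberately avoids the
# implementation path it checks.

# Naive O(n^2) DFT one-sided power, by direct quadratic cos/sin sums —
# no fft() anywhere.
naive_dft_power <- function(x) {
  n <- length(x)
  half <- n %/% 2L
  j <- 0:(n - 1L)
  vapply(0:half, function(f) {
    re <- sum(x * cos(2 * pi * f * j / n))
    im <- sum(x * sin(2 * pi * f * j / n))
    fold <- if (f == 0L || (n %% 2L == 0L && f == half)) 1 else 2
    fold * (re^2 + im^2) / n^2
  }, numeric(1))
}

# Brute-force search over a rotation grid: best summed squared distance of
# a onto b over proper rotations at the given angular step (radians).
grid_rotation_ss <- function(a, b, step_deg = 0.1) {
  angles <- seq(0, 2 * pi, by = step_deg * pi / 180)
  min(vapply(angles, function(th) {
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    sum((a %*% r - b)^2)
  }, numeric(1)))
}

# Exhaustive Holm step-down rejection set at level alpha, straight from the
# sequential-rejection definition.
holm_reject_oracle <- function(p, alpha) {
  ord <- order(p)
  m <- length(p)
  rejected <- logical(m)
  for (i in seq_len(m)) {
    if ((m - i + 1) * p[ord[i]] < alpha) rejected[ord[i]] <- TRUE else break
  }
  rejected
}

# Brute-force sliding: cyclic per-point grid search over arc offsets,
# minimising each curve's full Procrustes distance to the GPA consensus.
# Independent of the tangent-projection scheme in slide_semilandmarks().
slide_grid_oracle <- function(curves, grid_step = 1e-3, sweeps = 20) {
  n <- curves[[1L]]$n
  unit_shape <- function(coords) {
    c <- sweep(coords, 2L, colMeans(coords))
    c / sqrt(sum(c^2))
  }
  for (s in seq_len(sweeps)) {
    fit <- gpa(curves)
    cons <- fit$consensus / sqrt(sum(fit$consensus^2))
    moved <- FALSE
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      for (j in 2:(n - 1L)) {
        lo <- cv$arc_fractions[j - 1L]
        hi <- cv$arc_fractions[j + 1L]
        cand <- seq(lo + grid_step, hi - grid_step, by = grid_step)
        if (!length(cand)) next
        best <- cv$arc_fractions[j]
        best_d <- Inf
        for (u in unique(c(best, cand))) {
          uu <- cv$arc_fractions
          uu[j] <- u
          coords <- suturemorph:::.points_at_fraction(cv$trace_points, uu)
          d <- procrustes_distance(unit_shape(coords), cons)
          if (d < best_d - 1e-15) { best_d <- d; best <- u }
        }
        if (abs(best - cv$arc_fractions[j]) > grid_step / 2) moved <- TRUE
        cv$arc_fractions[j] <- best
      }
      coords <- suturemorph:::.points_at_fraction(cv$trace_points,
                                                  cv$arc_fractions)
      coords[1L, ] <- cv$trace_points[1L, ]
      coords[n, ] <- cv$trace_points[nrow(cv$trace_points), ]
      dimnames(coords) <- list(NULL, c("x", "y"))
      cv$coords <- coords
      curves[[i]] <- cv
    }
    if (!moved) break
  }
  fit <- gpa(curves)
  ss <- sum(vapply(seq_along(curves), function(i)
    procrustes_distance(fit$aligned[, , i], fit$consensus)^2, numeric(1)))
  list(curves = curves, total_ss = ss)
}

total_procrustes_ss <- function(curves) {
  fit <- gpa(curves)
  sum(vapply(seq_along(curves), function(i)
    procrustes_distance(fit$aligned[, , i], fit$consensus)^2, numeric(1)))
}
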