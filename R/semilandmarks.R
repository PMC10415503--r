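# Cumulative arc length of a polyline; strictly increasing because
# consecutive duplicate points are forbidden at trace construction.
.cumlen <- function(points) {
  c(0, cumsum(sqrt(rowSums(diff(points)^2))))
}

# Points on a polyline at given arc-length fractions u in [0, 1].
.points_at_fraction <- function(points, u, cl = .cumlen(points)) {
  total <- cl[length(cl)]
  s <- pmin(pmax(u, 0), 1) * total
  cbind(stats::approx(cl, points[, 1], xout = s, ties = "ordered")$y,
        stats::approx(cl, points[, 2], xout = s, ties = "ordered")$y)
}

#' Resample a trace to equidistant semi-landmarks
#'
#' Places `n` points at equal arc-length intervals along the piecewise-linear
#' trace, with linear interpolation within segments. The first and last
#' semi-landmarks coincide exactly with the raw trace endpoints. The default
#' of 500 semi-landmarks per suture is the pipeline's working density.
#'
#' @param trace A [raw_trace()].
#' @param n Number of semi-landmarks (>= 2), default 500.
#' @return An object of class `semilandmark_curve` carrying the resampled
#'   `coords`, the arc-length fractions of each point, the original polyline
#'   (needed for sliding re-projection), and the trace metadata.
#' @export
resample_equidistant <- function(trace, n = 500L) {
  if (!inherits(trace, "raw_trace")) stop("trace must be a raw_trace")
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  cl <- .cumlen(trace$points)
  total <- cl[length(cl)]
  if (!is.finite(total) || total <= 0)
    stop("degenerate geometry: trace '", trace$specimen_id,
         "' has zero total length")
  u <- seq(0, 1, length.out = n)
  coords <- .points_at_fraction(trace$points, u, cl)
  coords[1L, ] <- trace$points[1L, ]
  coords[n, ] <- trace$points[nrow(trace$points), ]
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(specimen_id = trace$specimen_id, coords = coords, n = n,
                 arc_fractions = u, trace_points = trace$points,
                 age = trace$age, sex = trace$sex, session = trace$session),
            class = "semilandmark_curve")
}

#' @export
print.semilandmark_curve <- function(x, ...) {
  cat("<semilandmark_curve> ", x$specimen_id, ": ", x$n, " semi-landmarks\n",
      sep = "")
  invisible(x)
}

# Map a specimen's raw polyline into its GPA-aligned frame using the exact
# similarity transform that carries its current coords onto the aligned ones.
.polyline_to_aligned <- function(curve, aligned_coords) {
  cs <- .centre_scale(curve$coords)
  r <- optimal_rotation(cs$coords, aligned_coords)
  sweep(curve$trace_points, 2L, cs$centre) %*% r / cs$size
}

#' Slide semi-landmarks to minimise Procrustes distance to the consensus
#'
#' Interior semi-landmarks are treated as deficient in the along-curve
#' direction: each iteration (1) superimposes the current curves by GPA,
#' (2) displaces every interior point of every specimen along the local unit
#' tangent by the least-squares projection of its residual to the consensus,
#' (3) re-projects the point onto the original polyline, keeping arc order
#' (offsets are clamped so points cannot cross), and (4) backtracks the step
#' whenever it would increase that specimen's Procrustes distance to the
#' current consensus, so the distance is non-increasing per iteration.
#' Endpoints never move. Iteration stops when the relative change of the
#' total Procrustes sum of squares falls below `tol` or after `max_iter`
#' sweeps.
#'
#' @param curves List of `semilandmark_curve` objects with a common `n >= 3`.
#' @param max_iter Maximum sliding sweeps (default 10).
#' @param tol Relative tolerance on the total Procrustes sum of squares
#'   (default 1e-6).
#' @return An object of class `sliding_result`: list with `curves` (the slid
#'   semi-landmark curves), `iterations`, `ss_path` (total Procrustes sum of
#'   squares after each sweep), and `converged`.
#' @export
slide_semilandmarks <- function(curves, max_iter = 10L, tol = 1e-6) {
  if (inherits(curves, "semilandmark_curve")) curves <- list(curves)
  if (!all(vapply(curves, inherits, logical(1), "semilandmark_curve")))
    stop("curves must be semilandmark_curve objects")
  n <- curves[[1L]]$n
  if (!all(vapply(curves, `[[`, integer(1), "n") == n))
    stop("all curves must share the same semi-landmark count")
  if (n < 3L) stop("sliding needs at least 3 semi-landmarks")

  # objective: summed squared full-Procrustes distance to the unit-size
  # consensus — the same target the per-point steps optimise, so every
  # stage of an iteration is non-increasing
  total_ss <- function(fit) {
    m <- dim(fit$aligned)[3L]
    cons <- fit$consensus / sqrt(sum(fit$consensus^2))
    sum(vapply(seq_len(m), function(i)
      procrustes_distance(fit$aligned[, , i], cons)^2, numeric(1)))
  }

  if (length(curves) == 1L) {
    fit <- gpa(curves)
    return(structure(list(curves = curves, iterations = 0L,
                          ss_path = total_ss(fit), converged = TRUE),
                     class = "sliding_result"))
  }

  fit <- gpa(curves)
  ss_path <- total_ss(fit)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cons <- fit$consensus / sqrt(sum(fit$consensus^2))
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      ali <- fit$aligned[, , i]
      poly <- .polyline_to_aligned(cv, ali)
      seg <- diff(poly)
      seg_len <- sqrt(rowSums(seg^2))
      cl <- c(0, cumsum(seg_len))
      arc_scale <- cl[length(cl)]
      idx <- 2:(n - 1L)
      # local direction of the polyline at each point's arc position — the
      # direction the point actually moves when its arc parameter changes
      seg_idx <- pmin(findInterval(cv$arc_fractions[idx] * arc_scale, cl,
                                   rightmost.closed = TRUE),
                      nrow(seg))
      tang <- seg[seg_idx, , drop = FALSE] / seg_len[seg_idx]
      # gradient of the full-Procrustes objective <a, c> through the
      # unit-size constraint: residual c_j - <a, c> a_j, not plain c_j - a_j
      kappa <- sum(ali * cons)
      resid <- cons[idx, ] - kappa * ali[idx, ]
      delta_u <- rowSums(resid * tang) / arc_scale
      gaps_lo <- cv$arc_fractions[idx] - cv$arc_fractions[idx - 1L]
      gaps_hi <- cv$arc_fractions[idx + 1L] - cv$arc_fractions[idx]
      delta_u <- pmax(pmin(delta_u, 0.45 * gaps_hi), -0.45 * gaps_lo)

      d_old <- procrustes_distance(.centre_scale(cv$coords)$coords, cons)
      step <- 1
      repeat {
        u_new <- cv$arc_fractions
        u_new[idx] <- u_new[idx] + step * delta_u
        coords_new <- .points_at_fraction(cv$trace_points, u_new)
        coords_new[1L, ] <- cv$trace_points[1L, ]
        coords_new[n, ] <- cv$trace_points[nrow(cv$trace_points), ]
        d_new <- procrustes_distance(.centre_scale(coords_new)$coords, cons)
        if (d_new <= d_old + 1e-15 || step < 1 / 128) break
        step <- step / 2
      }
      if (d_new <= d_old + 1e-15) {
        dimnames(coords_new) <- list(NULL, c("x", "y"))
        cv$arc_fractions <- u_new
        cv$coords <- coords_new
        curves[[i]] <- cv
      }
    }
    fit <- gpa(curves)
    ss_new <- total_ss(fit)
    prev <- ss_path[length(ss_path)]
    if (ss_new > prev + 1e-12 * max(prev, 1)) break  # numerical guard
    ss_path <- c(ss_path, ss_new)
    if (prev - ss_new < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  structure(list(curves = curves, iterations = iter, ss_path = ss_path,
                 converged = converged || iter < max_iter),
            class = "sliding_result")
}

#' @export
print.sliding_result <- function(x, ...) {
  cat("<sliding_result> ", length(x$curves), " curves, ", x$iterations,
      " sweeps; total Procrustes SS ",
      format(x$ss_path[length(x$ss_path)], digits = 6), "\n", sep = "")
  invisible(x)
}
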