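#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all points from their
#' centroid — the size measure removed by Procrustes scaling.
#'
#' @param coords Numeric n x 2 coordinate matrix, n >= 2.
#' @return Positive scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 points")
  cs <- sqrt(sum(scale(coords, scale = FALSE)^2))
  if (cs == 0) stop("degenerate configuration: all points identical")
  cs
}

.centre_scale <- function(coords) {
  ctr <- colMeans(coords)
  centred <- sweep(coords, 2L, ctr)
  size <- sqrt(sum(centred^2))
  if (size == 0) stop("degenerate configuration: all points identical")
  list(coords = centred / size, centre = ctr, size = size)
}

#' Optimal rotation between two centred configurations
#'
#' Closed-form orthogonal-Procrustes solution restricted to proper rotations
#' (determinant +1; reflections are disallowed because sutures have a fixed
#' anatomical orientation and a reflection would flip the looping direction).
#'
#' @param config,target Centred n x 2 coordinate matrices with equal n.
#' @return 2 x 2 rotation matrix `R` minimising `sum((config %*% R - target)^2)`.
#' @export
optimal_rotation <- function(config, target) {
  config <- as.matrix(config); target <- as.matrix(target)
  if (nrow(config) != nrow(target) || ncol(config) != 2L || ncol(target) != 2L)
    stop("configurations must be n x 2 with matching n")
  sv <- svd(crossprod(config, target))
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Procrustes distance between two shapes
#'
#' Root of the minimal summed squared point-wise distance over proper
#' rotations of `a` onto `b`. Both inputs are expected to be centred and of
#' unit centroid size (as produced by [gpa()]).
#'
#' @param a,b n x 2 shape coordinate matrices.
#' @return Nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("shapes must have the same number of landmarks")
  r <- optimal_rotation(a, b)
  sqrt(sum((a %*% r - b)^2))
}

# Proper rotation taking a centred shape onto its principal axes, with the
# major axis oriented along the shape's first-to-last chord. Pins the
# rotational gauge of the superimposition so aligned coordinates are
# invariant to rigid motion of the raw inputs.
.canonical_rotation <- function(shape) {
  ev <- eigen(crossprod(shape), symmetric = TRUE)
  major <- ev$vectors[, 1L]
  chord <- shape[nrow(shape), ] - shape[1L, ]
  if (sum(chord * major) < 0) major <- -major
  cbind(major, c(-major[2L], major[1L]))
}

#' Generalised Procrustes superimposition
#'
#' Iteratively removes translation, scale and rotation from a sample of
#' semi-landmark configurations: each configuration is centred and scaled to
#' unit centroid size, rotated to the current consensus, and the consensus
#' (renormalised to unit size) is recomputed until its root-mean-square
#' change falls below `tol` or `max_iter` is reached. Full Procrustes
#' convention: all aligned configurations have unit centroid size.
#'
#' @param curves List of `semilandmark_curve` objects (or bare n x 2
#'   matrices) sharing a common landmark count.
#' @param tol Convergence tolerance on consensus RMS change.
#' @param max_iter Iteration cap.
#' @return An object of class `aligned_sample`: list with `aligned`
#'   (p x 2 x m array), `consensus` (p x 2, unit size), `centroid_sizes`
#'   (pre-scaling sizes), `iterations`, `final_change`, and `info`
#'   (per-specimen metadata data frame).
#' @export
gpa <- function(curves, tol = 1e-10, max_iter = 100L) {
  if (inherits(curves, "semilandmark_curve")) curves <- list(curves)
  if (!length(curves)) stop("need at least one configuration")
  mats <- lapply(curves, function(cv) {
    if (inherits(cv, "semilandmark_curve")) cv$coords else as.matrix(cv)
  })
  ids <- vapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    if (inherits(cv, "semilandmark_curve") && !is.null(cv$specimen_id))
      cv$specimen_id else paste0("config_", i)
  }, character(1))
  p <- nrow(mats[[1L]])
  if (!all(vapply(mats, nrow, integer(1)) == p))
    stop("all configurations must share the same landmark count")

  norm <- vector("list", length(mats))
  sizes <- numeric(length(mats))
  for (i in seq_along(mats)) {
    cs <- tryCatch(.centre_scale(mats[[i]]),
                   error = function(e) stop("specimen '", ids[i], "': ",
                                            conditionMessage(e)))
    norm[[i]] <- cs$coords
    sizes[i] <- cs$size
  }

  aligned <- norm
  consensus <- Reduce(`+`, aligned) / length(aligned)
  if (sqrt(sum(consensus^2)) < 1e-6) consensus <- aligned[[1L]]
  else consensus <- consensus / sqrt(sum(consensus^2))
  iterations <- 0L
  change <- Inf
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    aligned <- lapply(aligned, function(m) m %*% optimal_rotation(m, consensus))
    new_cons <- Reduce(`+`, aligned) / length(aligned)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    # pin the rotational gauge to the previous consensus so the measured
    # change reflects shape convergence, not orientation drift
    new_cons <- new_cons %*% optimal_rotation(new_cons, consensus)
    change <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (change < tol) break
  }
  # canonical orientation (principal axes of the consensus) so the aligned
  # coordinates are invariant to rigid motion of the raw inputs
  rc <- .canonical_rotation(consensus)
  consensus <- consensus %*% rc
  aligned <- lapply(aligned, function(m)
    m %*% optimal_rotation(m, consensus))
  consensus_out <- Reduce(`+`, aligned) / length(aligned)
  dimnames(consensus_out) <- list(NULL, c("x", "y"))

  arr <- array(unlist(aligned), dim = c(p, 2L, length(aligned)),
               dimnames = list(NULL, c("x", "y"), ids))
  meta <- function(field, default) {
    vapply(curves, function(cv) {
      if (is.list(cv) && !is.null(cv[[field]])) cv[[field]] else default
    }, default)
  }
  info <- data.frame(
    specimen_id = ids,
    age = meta("age", NA_real_),
    sex = meta("sex", NA_character_),
    session = meta("session", 1L),
    stringsAsFactors = FALSE)
  structure(list(aligned = arr, consensus = consensus_out,
                 centroid_sizes = stats::setNames(sizes, ids),
                 iterations = iterations, final_change = change, info = info),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat("<aligned_sample> ", dim(x$aligned)[3L], " specimens x ",
      dim(x$aligned)[1L], " semi-landmarks; GPA converged in ",
      x$iterations, " iterations (final change ",
      format(x$final_change, digits = 3), ")\n", sep = "")
  invisible(x)
}
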