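# Flatten a p x 2 x m aligned array to an m x 2p matrix (x1,y1,x2,y2,...).
.flatten_shapes <- function(arr) {
  m <- dim(arr)[3L]
  t(vapply(seq_len(m), function(i) as.vector(t(arr[, , i])),
           numeric(dim(arr)[1L] * 2L)))
}

.unflatten_shape <- function(v) {
  matrix(v, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("x", "y")))
}

#' Principal component analysis of superimposed shapes
#'
#' Covariance-based PCA of the flattened aligned coordinates about the
#' consensus. Coordinates share units after Procrustes superimposition, so
#' no correlation scaling is applied. Eigenvector signs are fixed by forcing
#' the loading entry of largest magnitude to be positive, making component
#' orientations reproducible across runs.
#'
#' @param sample An `aligned_sample` from [gpa()] with >= 2 specimens.
#' @return An object of class `pca_shapes`: `mean_shape` (p x 2),
#'   `eigenvalues` (descending, clamped at 0), `loadings` (2p x rank,
#'   orthonormal columns), `scores` (m x rank, specimen ids as row names),
#'   `explained_fraction`, and `info` (metadata carried from the sample).
#' @export
pca_shapes <- function(sample) {
  if (!inherits(sample, "aligned_sample")) stop("sample must be an aligned_sample")
  m <- dim(sample$aligned)[3L]
  if (m < 2L) stop("insufficient sample: PCA needs at least 2 specimens")
  x <- .flatten_shapes(sample$aligned)
  rownames(x) <- dimnames(sample$aligned)[[3L]]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- min(m - 1L, ncol(x))
  eig <- pmax(pc$sdev^2, 0)[seq_len(rank)]
  load <- pc$rotation[, seq_len(rank), drop = FALSE]
  scores <- pc$x[, seq_len(rank), drop = FALSE]
  for (j in seq_len(rank)) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tot <- sum(eig)
  structure(list(mean_shape = .unflatten_shape(colMeans(x)),
                 eigenvalues = eig, loadings = load, scores = scores,
                 explained_fraction = if (tot > 0) eig / tot else eig,
                 info = sample$info),
            class = "pca_shapes")
}

#' @export
print.pca_shapes <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("<pca_shapes> ", nrow(x$scores), " specimens, rank ",
      length(x$eigenvalues), "\n", sep = "")
  cat("  explained: ",
      paste(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained_fraction[1:k]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of components needed to reach a variance threshold
#'
#' @param result A `pca_shapes` object.
#' @param threshold Fraction of total variance in (0, 1].
#' @return Smallest k whose cumulative explained fraction exceeds
#'   `threshold` (full rank when the threshold is 1).
#' @export
n_components_for_variance <- function(result, threshold) {
  if (!length(result$eigenvalues)) stop("empty eigenvalue vector")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (sum(result$eigenvalues) == 0)
    stop("undefined variance: all eigenvalues are zero")
  cum <- cumsum(result$explained_fraction)
  hit <- which(cum > threshold - 1e-12)
  if (length(hit)) hit[1L] else length(cum)
}

#' Reconstruct a shape along a principal component
#'
#' Returns `mean_shape + score * loading[component]` as coordinates — the
#' construction used to render extreme shapes at either end of a component
#' axis in morphospace figures.
#'
#' @param result A `pca_shapes` object.
#' @param component Component index (1-based).
#' @param score Position along the component, in score units.
#' @return p x 2 coordinate matrix.
#' @export
shape_along_pc <- function(result, component, score) {
  r <- length(result$eigenvalues)
  if (component < 1L || component > r)
    stop("component out of range (rank ", r, ")")
  v <- as.vector(t(result$mean_shape)) + score * result$loadings[, component]
  .unflatten_shape(v)
}

#' Morphospace table: PC scores joined to specimen metadata
#'
#' @param result A `pca_shapes` object.
#' @param cohort The [suture_cohort()] the scores came from; supplies age,
#'   sex and group labels. Every scored specimen must exist in the cohort.
#' @return Data frame with columns specimen_id, pc1, pc2, age, sex, group.
#' @export
morphospace_table <- function(result, cohort) {
  meta <- cohort_metadata(cohort)
  meta <- meta[!duplicated(meta$specimen_id), , drop = FALSE]
  ids <- rownames(result$scores)
  missing <- setdiff(ids, meta$specimen_id)
  if (length(missing))
    stop("specimens scored but absent from cohort: ",
         paste(missing, collapse = ", "))
  j <- match(ids, meta$specimen_id)
  data.frame(specimen_id = ids,
             pc1 = unname(result$scores[, 1L]),
             pc2 = if (ncol(result$scores) >= 2L)
               unname(result$scores[, 2L]) else NA_real_,
             age = meta$age[j], sex = meta$sex[j], group = meta$group[j],
             stringsAsFactors = FALSE)
}
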