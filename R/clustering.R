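# Profile clustering: PCA of a model's component-score matrix, retention of
# components explaining >= 5% of variance, then seeded k-means on the
# reduced coordinates, with per-cluster mean ToxPi profiles.

#' PCA reduction of a slice-score matrix
#'
#' Columns are centered (not scaled: component scores already share the
#' `[0, weight]` scale) and decomposed with [stats::prcomp()]. Components
#' explaining at least `threshold` of the total variance are retained, in
#' decreasing-variance order, and the chemicals are projected onto them.
#'
#' @param slice_scores numeric matrix (chemicals x slices) of component
#'   scores, e.g. the slice columns of [toxpi_scores()].
#' @param threshold minimum explained-variance fraction for retention
#'   (default 0.05).
#' @return list of class `pca_basis`: `loadings`, `explained` (variance
#'   fractions), `retained` (indices), `coords` (chemicals x retained PCs).
#' @export
pca_reduce <- function(slice_scores, threshold = 0.05) {
  stopifnot(is.matrix(slice_scores))
  if (nrow(slice_scores) < 2 || ncol(slice_scores) < 2)
    stop("need at least 2 chemicals and 2 slices", call. = FALSE)
  p <- stats::prcomp(slice_scores, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  if (sum(v) <= 0) stop("slice-score matrix has zero variance", call. = FALSE)
  frac <- v / sum(v)
  retained <- which(frac >= threshold)
  if (!length(retained))
    stop("no principal component reaches the ", threshold,
         " variance threshold", call. = FALSE)
  structure(list(loadings = p$rotation, explained = frac, retained = retained,
                 center = p$center,
                 coords = p$x[, retained, drop = FALSE]),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("pca_basis: %d of %d components retained (explained: %s)\n",
              length(x$retained), length(x$explained),
              paste(sprintf("%.1f%%", 100 * x$explained[x$retained]),
                    collapse = ", ")))
  invisible(x)
}

#' Seeded k-means clustering of reduced coordinates
#'
#' Lloyd's algorithm from a seeded random initialization (k distinct rows),
#' run to an assignment fixed point or `max_iterations`. An emptied cluster
#' is re-seeded from the point farthest from its centroid. `restarts`
#' independent starts are derived deterministically from `seed` and the
#' solution with the lowest within-cluster sum of squares is kept, so the
#' result is reproducible bit-for-bit given the seed.
#'
#' @param coords numeric matrix (points x dims), e.g. `pca_reduce(...)$coords`.
#' @param k_max number of clusters; defaults to `ncol(coords)` (the
#'   dimension of the reduced PC matrix) and must not exceed the number of
#'   points.
#' @param max_iterations Lloyd iteration cap per start (default 10000).
#' @param seed integer seed (required; no hidden global randomness).
#' @param restarts number of seeded restarts (default 10).
#' @return list of class `cluster_result`: `assignments` (named integer
#'   labels), `centroids`, `tot_withinss`, `n_iterations_used`, `k`, `seed`.
#' @export
kmeans_cluster <- function(coords, k_max = ncol(coords),
                           max_iterations = 10000, seed, restarts = 10) {
  stopifnot(is.matrix(coords))
  if (missing(seed)) stop("kmeans_cluster requires a seed", call. = FALSE)
  n <- nrow(coords)
  if (k_max < 1 || k_max > n)
    stop("k_max must be between 1 and the number of points (", n, ")",
         call. = FALSE)
  best <- NULL
  for (s in seq_len(restarts)) {
    set.seed((as.integer(seed) + 104729L * s) %% .Machine$integer.max)
    fit <- lloyd_once(coords, k_max, max_iterations)
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  best$seed <- as.integer(seed)
  best$k <- as.integer(k_max)
  names(best$assignments) <- rownames(coords)
  class(best) <- "cluster_result"
  best
}

lloyd_once <- function(x, k, max_iter) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  assign_prev <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- point_center_dist2(x, centers)
    assign_cur <- max.col(-d, ties.method = "first")
    # re-seed emptied clusters from the point farthest from its centroid
    empty <- setdiff(seq_len(k), unique(assign_cur))
    for (e in empty) {
      far <- which.max(d[cbind(seq_len(n), assign_cur)])
      assign_cur[far] <- e
      centers[e, ] <- x[far, ]
      d <- point_center_dist2(x, centers)
      assign_cur <- max.col(-d, ties.method = "first")
      assign_cur[far] <- e
    }
    for (j in unique(assign_cur))
      centers[j, ] <- colMeans(x[assign_cur == j, , drop = FALSE])
    if (identical(assign_cur, assign_prev) || iter >= max_iter) break
    assign_prev <- assign_cur
  }
  d <- point_center_dist2(x, centers)
  list(assignments = assign_cur, centroids = centers,
       tot_withinss = sum(d[cbind(seq_len(n), assign_cur)]),
       n_iterations_used = iter)
}

point_center_dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) - 2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d, %d points, total within-SS = %.4g (%d iterations)\n",
              x$k, length(x$assignments), x$tot_withinss, x$n_iterations_used))
  invisible(x)
}

#' Mean ToxPi profile per cluster
#'
#' Per-cluster arithmetic mean of the slice-score vectors, cluster sizes,
#' and mean overall score, ordered by mean overall score descending (the
#' top clusters are the high-activity profiles; an all-zero cluster is the
#' "negligible activity" bulk of the library).
#'
#' @param result a [kmeans_cluster()] result.
#' @param slice_scores the matrix the clustering was derived from
#'   (chemicals x slices, same row order/names as the clustered coords).
#' @return data.frame `cluster`, `size`, `mean_overall`, then one mean
#'   component-score column per slice.
#' @export
cluster_profiles <- function(result, slice_scores) {
  stopifnot(inherits(result, "cluster_result"), is.matrix(slice_scores))
  if (length(result$assignments) != nrow(slice_scores))
    stop("assignments do not cover the slice-score matrix", call. = FALSE)
  labs <- sort(unique(result$assignments))
  prof <- t(vapply(labs, function(l)
    colMeans(slice_scores[result$assignments == l, , drop = FALSE]),
    numeric(ncol(slice_scores))))
  out <- data.frame(cluster = labs,
                    size = as.integer(table(factor(result$assignments, labs))),
                    mean_overall = rowSums(prof), row.names = NULL)
  out <- cbind(out, as.data.frame(prof, row.names = NULL))
  out <- out[order(-out$mean_overall, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
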