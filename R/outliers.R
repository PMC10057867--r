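#' Local Outlier Factor scores
#'
#' Classical LOF: for each point, the k-distance is the distance to its k-th
#' nearest neighbour; the neighbourhood is every other point within the
#' k-distance (ties included). The reachability distance of `a` from
#' neighbour `b` is `max(k-distance(b), d(a, b))`; the local reachability
#' density is the reciprocal of the mean reachability distance over the
#' neighbourhood; the LOF score is the mean ratio of neighbour density to
#' own density. Scores near 1 mark inliers, scores well above 1 isolated
#' points. Distances are Minkowski of order `p`.
#'
#' Duplicate points can give a zero mean reachability distance; their density
#' is then infinite. Density ratios between two infinite densities count as
#' 1, so a stack of ties scores as perfect inliers; a point whose neighbours
#' include such a stack gets a score of `Inf` — it genuinely is infinitely
#' less dense than its neighbourhood, and any finite threshold flags it.
#'
#' @param X Numeric matrix, one row per observation.
#' @param n_neighbors Neighbourhood size k (>= 1, < nrow(X)).
#' @param p Minkowski order (>= 1).
#' @return Numeric LOF score per row.
#' @export
lof_scores <- function(X, n_neighbors = 10L, p = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(n_neighbors)
  stopifnot(k >= 1L, k < n, p >= 1)
  D <- as.matrix(stats::dist(X, method = "minkowski", p = p))
  diag(D) <- Inf

  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- D[i, ]
    kdist[i] <- sort(di, partial = k)[k]
    nbrs[[i]] <- which(di <= kdist[i])
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    m <- mean(reach)
    lrd[i] <- if (m == 0) Inf else 1 / m
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    ratio <- lrd[nbrs[[i]]] / lrd[i]
    ratio[is.nan(ratio)] <- 1  # Inf / Inf: both densities degenerate
    scores[i] <- mean(ratio)
  }
  scores
}

#' Mean silhouette of a partition
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`. Members of singleton clusters
#' contribute 0. Returns the mean over all points.
#'
#' @param X Numeric matrix (rows = observations), or a `dist` object.
#' @param labels Cluster labels (>= 2 distinct values).
#' @param p Minkowski order used when `X` is a matrix.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(X, labels, p = 2) {
  D <- if (inherits(X, "dist")) as.matrix(X)
       else as.matrix(stats::dist(as.matrix(X), method = "minkowski", p = p))
  labels <- as.vector(labels)
  n <- nrow(D)
  stopifnot(length(labels) == n)
  lev <- unique(labels)
  if (length(lev) < 2L) stop("silhouette needs at least two clusters", call. = FALSE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1L)
    b <- min(vapply(lev[lev != labels[i]],
                    function(l) mean(D[i, labels == l]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Tune the LOF filter by silhouette grid search
#'
#' For every parameter combination, the rows are repeatedly subsampled; on
#' each subsample the LOF scores partition the rows into inliers and
#' outliers at the score threshold and the two-way partition is scored by
#' its mean silhouette. The combination with the best mean silhouette across
#' subsamples wins; ties go to the smallest neighbourhood, then the smallest
#' Minkowski order. All-inlier or all-outlier partitions score -1 so that a
#' degenerate cut can never win against a real one.
#'
#' @param X Numeric matrix of rows to filter.
#' @param n_neighbors_grid Candidate neighbourhood sizes.
#' @param p_grid Candidate Minkowski orders.
#' @param threshold LOF score above which a row is an outlier.
#' @param folds Number of random subsamples.
#' @param subsample Fraction of rows per subsample.
#' @param seed Integer seed.
#' @return List with `n_neighbors`, `p`, `threshold`, `silhouette` (the
#'   winning mean silhouette) and `grid` (a data.frame of every combination
#'   tried with its score).
#' @export
tune_lof <- function(X, n_neighbors_grid = c(5L, 10L, 20L, 35L),
                     p_grid = c(1, 2), threshold = 1.5,
                     folds = 5L, subsample = 0.8, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(n_neighbors_grid) >= 1L, length(p_grid) >= 1L)
  grid <- expand.grid(n_neighbors = sort(n_neighbors_grid), p = sort(p_grid))
  grid <- grid[grid$n_neighbors < n, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no grid point has n_neighbors < nrow(X)", call. = FALSE)

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- max(2L, round(subsample * n))
  subs <- lapply(seq_len(folds), function(f) sample(n, m))

  score_one <- function(k, p) {
    vals <- vapply(subs, function(idx) {
      Xi <- X[idx, , drop = FALSE]
      if (k >= nrow(Xi)) return(-1)
      out <- lof_scores(Xi, k, p) > threshold
      if (all(out) || !any(out)) return(-1)
      silhouette_score(Xi, as.integer(out), p = p)
    }, 0)
    mean(vals)
  }
  grid$silhouette <- mapply(score_one, grid$n_neighbors, grid$p)
  best <- grid[order(-grid$silhouette, grid$n_neighbors, grid$p), ][1L, ]
  list(n_neighbors = as.integer(best$n_neighbors), p = best$p,
       threshold = threshold, silhouette = best$silhouette, grid = grid)
}

#' Flag outlier rows with a tuned LOF filter
#'
#' @param X Numeric matrix of rows.
#' @param params A [tune_lof()] result, or a list with `n_neighbors`, `p`,
#'   `threshold`.
#' @return Logical vector: `TRUE` for inliers.
#' @export
filter_outliers <- function(X, params) {
  scores <- lof_scores(X, params$n_neighbors, params$p)
  scores <= params$threshold
}
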