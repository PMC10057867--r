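#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbour distances of uniformly placed probe points
#' (within the data's bounding box) with those of sampled real points:
#' `H = sum(u) / (sum(u) + sum(w))`, where `u` are probe-to-nearest-data
#' distances and `w` sampled-point-to-nearest-other-point distances.
#' Spatially random data give H near 0.5; strongly clustered data push H
#' towards 1.
#'
#' @param X Numeric matrix (rows = observations).
#' @param sample_fraction Fraction of rows sampled (minimum 10 points).
#' @param seed Integer seed.
#' @return H in \[0, 1\].
#' @export
hopkins_statistic <- function(X, sample_fraction = 0.1, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 10L)
  m <- min(n - 1L, max(10L, round(sample_fraction * n)))

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  U <- matrix(stats::runif(m * ncol(X)), m) %*% diag(hi - lo, ncol(X)) +
    matrix(lo, m, ncol(X), byrow = TRUE)
  idx <- sample.int(n, m)

  nn_dist <- function(P, Q) {
    # nearest neighbour in Q for each row of P
    vapply(seq_len(nrow(P)), function(i) {
      d2 <- colSums((t(Q) - P[i, ])^2)
      sqrt(min(d2))
    }, 0)
  }
  u <- nn_dist(U, X)
  w <- vapply(seq_len(m), function(j) {
    i <- idx[j]
    d2 <- colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2)
    sqrt(min(d2))
  }, 0)
  sum(u) / (sum(u) + sum(w))
}

# ---- internal validity indices ---------------------------------------------

within_ss <- function(X, labels) {
  sum(vapply(unique(labels), function(l) {
    Xi <- X[labels == l, , drop = FALSE]
    sum(scale(Xi, scale = FALSE)^2)
  }, 0))
}

centroids_of <- function(X, labels) {
  lev <- sort(unique(labels))
  t(vapply(lev, function(l) colMeans(X[labels == l, , drop = FALSE]),
           numeric(ncol(X))))
}

index_ch <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  W <- within_ss(X, labels)
  Tot <- sum(scale(X, scale = FALSE)^2)
  B <- Tot - W
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

index_db <- function(X, labels) {
  lev <- sort(unique(labels)); k <- length(lev)
  cen <- centroids_of(X, labels)
  S <- vapply(seq_len(k), function(i) {
    Xi <- X[labels == lev[i], , drop = FALSE]
    mean(sqrt(colSums((t(Xi) - cen[i, ])^2)))
  }, 0)
  M <- as.matrix(stats::dist(cen))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(seq_len(k)[-i], function(j) (S[i] + S[j]) / M[i, j], 0))
  }, 0))
}

index_dunn <- function(D, labels) {
  lev <- sort(unique(labels))
  Dm <- as.matrix(D)
  intra <- max(vapply(lev, function(l) {
    idx <- which(labels == l)
    if (length(idx) < 2L) 0 else max(Dm[idx, idx])
  }, 0))
  inter <- min(vapply(seq_along(lev)[-1], function(i) {
    min(vapply(seq_len(i - 1L), function(j) {
      min(Dm[labels == lev[i], labels == lev[j], drop = FALSE])
    }, 0))
  }, 0))
  if (intra == 0) Inf else inter / intra
}

index_cindex <- function(D, labels) {
  d <- as.vector(D)
  Dm <- as.matrix(D)
  within <- unlist(lapply(unique(labels), function(l) {
    idx <- which(labels == l)
    if (length(idx) < 2L) return(numeric(0))
    Dm[idx, idx][upper.tri(diag(length(idx)))]
  }))
  nw <- length(within)
  if (nw == 0L) return(NA_real_)
  ds <- sort(d)
  smin <- sum(ds[seq_len(nw)])
  smax <- sum(ds[seq.int(length(ds) - nw + 1L, length(ds))])
  if (smax == smin) return(NA_real_)
  (sum(within) - smin) / (smax - smin)
}

index_mcclain <- function(D, labels) {
  Dm <- as.matrix(D)
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(Dm)
  wd <- Dm[ut & same]; bd <- Dm[ut & !same]
  if (length(wd) == 0L || length(bd) == 0L || mean(bd) == 0) return(NA_real_)
  mean(wd) / mean(bd)
}

index_xb <- function(X, labels) {
  cen <- centroids_of(X, labels)
  lev <- sort(unique(labels))
  W <- sum(vapply(seq_along(lev), function(i) {
    Xi <- X[labels == lev[i], , drop = FALSE]
    sum(colSums((t(Xi) - cen[i, ])^2))
  }, 0))
  sep <- min(stats::dist(cen))^2
  if (sep == 0) return(Inf)
  W / (nrow(X) * sep)
}

gap_statistic <- function(X, k_range, cut_fun, B = 10L, seed = 1L) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  logW <- vapply(k_range, function(k) log(within_ss(X, cut_fun(X, k))), 0)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  ref <- matrix(0, B, length(k_range))
  for (b in seq_len(B)) {
    Xb <- matrix(stats::runif(nrow(X) * ncol(X)), nrow(X)) %*%
      diag(hi - lo, ncol(X)) + matrix(lo, nrow(X), ncol(X), byrow = TRUE)
    ref[b, ] <- vapply(k_range, function(k) {
      log(within_ss(Xb, cut_fun(Xb, k)))
    }, 0)
  }
  gap <- colMeans(ref) - logW
  se <- apply(ref, 2, stats::sd) * sqrt(1 + 1 / B)
  list(gap = gap, se = se)
}

#' Select the cluster count by validity-index voting
#'
#' Cuts the hierarchical tree at every k in `k_range` and scores each
#' partition with a fixed set of ten internal validity indices (silhouette,
#' Calinski-Harabasz, Davies-Bouldin, Dunn, C-index, McClain-Rao, gap
#' statistic, Ball-Hall, Hartigan, Xie-Beni). Each index votes for the k its
#' own rule prefers (maximum, minimum, largest successive drop, or the gap
#' one-standard-error rule); the majority wins, with ties broken towards the
#' smaller k. Indices undefined on a degenerate partition abstain.
#'
#' @param X Numeric matrix of rows to cluster.
#' @param k_range Candidate cluster counts (subset of 2..n-1).
#' @param metric Distance metric for the tree (default Euclidean).
#' @param linkage Linkage (default complete).
#' @param seed Integer seed (gap-statistic reference sets).
#' @return List with `k` (winner), `votes` (named integer vector of votes
#'   per k), `ballots` (named vector: the k each index voted for).
#' @export
optimal_k_vote <- function(X, k_range = 2:8, metric = "euclidean",
                           linkage = "complete", seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  stopifnot(length(k_range) >= 1L)
  D <- stats::dist(X, method = metric)
  hc <- stats::hclust(D, method = linkage)
  cuts <- lapply(k_range, function(k) stats::cutree(hc, k))
  names(cuts) <- k_range
  cut_fun <- function(Xb, k) {
    stats::cutree(stats::hclust(stats::dist(Xb, method = metric),
                                method = linkage), k)
  }

  per_k <- function(f) vapply(cuts, f, 0)
  sil  <- per_k(function(l) silhouette_score(D, l))
  ch   <- per_k(function(l) index_ch(X, l))
  db   <- per_k(function(l) index_db(X, l))
  dunn <- per_k(function(l) index_dunn(D, l))
  cidx <- per_k(function(l) index_cindex(D, l))
  mcr  <- per_k(function(l) index_mcclain(D, l))
  xb   <- per_k(function(l) index_xb(X, l))

  W <- vapply(cuts, function(l) within_ss(X, l), 0)
  W1 <- sum(scale(X, scale = FALSE)^2)            # k = 1 dispersion
  Wext <- c(W1, W)                                 # aligned to c(1, k_range)
  ball_hall <- W / as.numeric(k_range)
  bh_prev <- Wext[-length(Wext)] / c(1, k_range[-length(k_range)])
  bh_drop <- bh_prev - ball_hall                   # successive decrease
  hart <- vapply(seq_along(k_range), function(i) {
    if (i == length(k_range)) return(NA_real_)
    if (W[i + 1L] == 0) return(Inf)
    (W[i] / W[i + 1L] - 1) * (n - k_range[i] - 1L)
  }, 0)
  gp <- gap_statistic(X, k_range, cut_fun, seed = seed)

  vote_max <- function(v) if (all(is.na(v))) NA_integer_ else k_range[which.max(v)]
  vote_min <- function(v) if (all(is.na(v))) NA_integer_ else k_range[which.min(v)]

  gap_vote <- {
    g <- gp$gap; s <- gp$se
    ok <- which(g[-length(g)] >= g[-1] - s[-1])
    if (length(ok)) k_range[min(ok)] else k_range[which.max(g)]
  }
  hart_vote <- {
    ok <- which(hart <= 10)
    if (length(ok)) k_range[min(ok)]
    else if (all(is.na(hart[-length(hart)]))) NA_integer_
    else k_range[which.max(-hart)]
  }

  ballots <- c(silhouette = vote_max(sil),
               calinski_harabasz = vote_max(ch),
               davies_bouldin = vote_min(db),
               dunn = vote_max(dunn),
               c_index = vote_min(cidx),
               mcclain_rao = vote_min(mcr),
               gap = gap_vote,
               ball_hall = vote_max(bh_drop),
               hartigan = hart_vote,
               xie_beni = vote_min(xb))
  ballots <- ballots[!is.na(ballots)]
  votes <- table(factor(ballots, levels = k_range))
  k <- as.integer(names(votes)[which.max(votes)])  # which.max: first = smallest k
  list(k = k, votes = votes, ballots = ballots)
}

#' Agglomerative hierarchical clustering of size distributions
#'
#' Standard agglomerative clustering (complete linkage, Euclidean distance
#' by default) with a cut at `k` clusters, plus the per-species majority
#' cluster when row labels are supplied.
#'
#' @param X Numeric matrix of rows to cluster.
#' @param k Number of clusters.
#' @param metric Distance metric.
#' @param linkage Linkage method.
#' @param species Optional row labels.
#' @return An object of class `cluster_model`: list with `tree` (hclust),
#'   `k`, `labels`, `species`, `majority` (named vector: majority cluster
#'   per species, when labels given).
#' @export
hierarchical_cluster <- function(X, k, metric = "euclidean",
                                 linkage = "complete", species = NULL) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of rows", call. = FALSE)
  hc <- stats::hclust(stats::dist(X, method = metric), method = linkage)
  labels <- stats::cutree(hc, k)
  majority <- NULL
  if (!is.null(species)) {
    stopifnot(length(species) == nrow(X))
    majority <- vapply(split(labels, species), function(l) {
      as.integer(names(which.max(table(l))))
    }, 0L)
  }
  structure(list(tree = hc, k = as.integer(k), labels = labels,
                 species = species, majority = majority),
            class = "cluster_model")
}

#' Centred PCA projection
#'
#' Centred (not rescaled) principal-component scores, with each component's
#' sign fixed so that the largest-magnitude loading entry is positive, making
#' projections reproducible across platforms.
#'
#' @param X Numeric matrix.
#' @param n_components Number of components.
#' @return List with `scores` (n x n_components), `loadings`,
#'   `explained_variance` (shares of total variance, sum <= 1).
#' @export
pca_project <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- vapply(seq_len(n_components), function(j) {
    v <- rot[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  list(scores = scores, loadings = rot,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)])
}
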