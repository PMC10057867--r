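# Independent brute-force oracles, written from the textbook definitions as
# plain loops so they share no code path with the package implementations.

# LOF straight from the definition: k-distance, reachability, lrd, score.
lof_brute <- function(X, k, p = 2) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sum(abs(X[i, ] - X[j, ])^p)^(1 / p)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- d(i, j)
  kdist <- numeric(n)
  nbr <- vector("list", n)
  for (i in 1:n) {
    others <- sort(D[i, -i])
    kdist[i] <- others[k]
    nbr[[i]] <- setdiff(which(D[i, ] <= kdist[i]), i)
  }
  lrd <- numeric(n)
  for (i in 1:n) {
    r <- sapply(nbr[[i]], function(j) max(kdist[j], D[i, j]))
    lrd[i] <- if (mean(r) == 0) Inf else 1 / mean(r)
  }
  sapply(1:n, function(i) {
    ratios <- lrd[nbr[[i]]] / lrd[i]
    ratios[is.nan(ratios)] <- 1
    mean(ratios)
  })
}

# Complete-linkage agglomeration by exhaustive pair search.
hclust_brute_complete <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(1:n)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      cd <- max(D[clusters[[i]], clusters[[j]]])
      if (cd < best_d) { best_d <- cd; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    merges[[length(merges) + 1L]] <-
      list(a = clusters[[best[1]]], b = clusters[[best[2]]])
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  list(heights = heights, merges = merges)
}

# Speciation inversion on a dense grid in log-log space, matching the
# concentration per log-intensity interval F * dN/dF. The grid includes the
# polyline kink points themselves, so the piecewise-linear curves are
# represented exactly and the crossing is exact up to float precision. The
# polyline is extended at the outer slopes to the outermost populated bin
# edges, mirroring the curve definition under test but through independent
# grid-scan code.
speciation_brute <- function(edges1, counts1, edges_c, counts_c, F1,
                             n_grid = 1e5) {
  centres <- function(e) sqrt(e[-length(e)] * e[-1])
  pts <- function(e, cts) {
    s <- centres(e); y <- (cts / diff(e)) * s
    keep <- y > 0
    lx <- log(s[keep]); ly <- log(y[keep])
    lo <- log(e[which(keep)[1]])
    hi <- log(e[which(keep)[sum(keep)] + 1])
    n <- length(lx)
    list(lx = c(lo, lx, hi),
         ly = c(ly[1] + (ly[2] - ly[1]) / (lx[2] - lx[1]) * (lo - lx[1]),
                ly,
                ly[n] + (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1]) *
                  (hi - lx[n])))
  }
  p1 <- pts(edges1, counts1)
  ly_star <- approx(p1$lx, p1$ly, xout = log(F1))$y
  pc <- pts(edges_c, counts_c)
  grid <- sort(unique(c(seq(min(pc$lx), max(pc$lx), length.out = n_grid),
                        pc$lx)))
  vals <- approx(pc$lx, pc$ly, xout = grid)$y
  if (ly_star > max(vals) + 1e-9 || ly_star < min(vals) - 1e-9) return(NA_real_)
  ly_star <- min(max(ly_star, min(vals)), max(vals))
  sgn <- vals - ly_star
  hit <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  t <- if (vals[i + 1] == vals[i]) 0 else
    (ly_star - vals[i]) / (vals[i + 1] - vals[i])
  Fc <- exp(grid[i] + t * (grid[i + 1] - grid[i]))
  F1 / Fc
}

# Gaussian blobs for clustering tests.
make_blobs <- function(centers, n_per, sd = 0.05, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
}

# Synthetic optical-signature rows: lognormal features around class centres.
sig_blobs <- function(centres_log, n_per, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centres_log)), function(i) {
    exp(matrix(rnorm(n_per * 6, 0, sd), n_per) +
          matrix(centres_log[i, ], n_per, 6, byrow = TRUE))
  }))
  colnames(X) <- c("S2", "S3", "S4", "S2_over_S3", "S2_over_S4", "S3_over_S4")
  list(X = X,
       labels = rep(paste0("class", seq_len(nrow(centres_log))), each = n_per))
}

# A tiny instrument with intensity-bin edge ratio exactly 2 so that integer
# gain factors shift counts by whole bins.
octave_config <- function(n_bins = 19L) {
  # diameters 5..100 fixed; choose b so intensity edge ratio is 2
  b <- 19 * log(2) / log(20)
  instrument_config(n_bins = n_bins,
                    calibration = power_law_calibration(a = 1, b = b))
}
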