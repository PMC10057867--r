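test_that("Hopkins statistic separates random from clustered data", {
  set.seed(4)
  U <- matrix(runif(600), ncol = 2)
  h_rand <- mean(sapply(1:5, function(s) hopkins_statistic(U, seed = s)))
  expect_lt(abs(h_rand - 0.5), 0.1)

  K <- make_blobs(rbind(c(0, 0), c(10, 10), c(-10, 10)), 100, sd = 0.05,
                  seed = 8)
  h_clust <- hopkins_statistic(K, seed = 1)
  expect_gt(h_clust, 0.9)

  # near-duplicates: real nearest-neighbour distances vanish, H -> 1
  Dup <- matrix(rnorm(40), ncol = 2)[rep(1:20, each = 3), ] +
    matrix(rnorm(120, 0, 1e-9), ncol = 2)
  expect_gt(hopkins_statistic(Dup, seed = 2), 0.99)
})

test_that("validity-index voting finds planted cluster counts", {
  B3 <- make_blobs(rbind(c(0, 0), c(8, 0), c(4, 7)), 30, sd = 0.3, seed = 5)
  v3 <- optimal_k_vote(B3, k_range = 2:6, seed = 1)
  expect_equal(v3$k, 3L)
  B2 <- make_blobs(rbind(c(0, 0), c(6, 6)), 40, sd = 0.4, seed = 6)
  v2 <- optimal_k_vote(B2, k_range = 2:6, seed = 1)
  expect_equal(v2$k, 2L)
  expect_gte(length(v2$ballots), 8L)  # nearly every index gets a vote
})

test_that("hierarchical clustering matches a brute-force agglomeration", {
  set.seed(12)
  for (rep in 1:4) {
    X <- matrix(rnorm(12 * 3), ncol = 3)
    cm <- hierarchical_cluster(X, k = 2)
    oracle <- hclust_brute_complete(X)
    expect_equal(sort(cm$tree$height), sort(oracle$heights),
                 tolerance = 1e-9)
    # the final brute-force merge splits the rows exactly as the k = 2 cut
    last <- oracle$merges[[length(oracle$merges)]]
    expect_setequal(split(seq_len(12), cm$labels),
                    list(sort(last$a), sort(last$b)))
  }
})

test_that("trivial cuts and majority labelling behave", {
  X <- make_blobs(rbind(c(0, 0), c(5, 5)), 5, sd = 0.1, seed = 3)
  cm_n <- hierarchical_cluster(X, k = nrow(X))
  expect_equal(sort(unique(cm_n$labels)), 1:nrow(X))  # singletons
  expect_error(hierarchical_cluster(X, k = nrow(X) + 1), "exceeds")
  sp <- rep(c("a", "b"), each = 5)
  cm <- hierarchical_cluster(X, k = 2, species = sp)
  expect_length(cm$majority, 2L)
  expect_false(cm$majority[["a"]] == cm$majority[["b"]])
  expect_equal(stats::cutree(cm$tree, cm$k), cm$labels)
})

test_that("PCA projection is centred, sign-fixed, and matches eigen", {
  line <- cbind(1:20, 2 * (1:20) + 3)
  p <- pca_project(line, 2)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-9)
  set.seed(10)
  X <- matrix(rnorm(40 * 5), ncol = 5)
  p2 <- pca_project(X, 3)
  expect_lte(sum(p2$explained_variance), 1 + 1e-12)
  # oracle: full eigendecomposition of the covariance
  ev <- eigen(cov(X))
  expect_equal(p2$explained_variance,
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-9)
  for (j in 1:3) {
    expect_equal(abs(p2$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-7)
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  }
  # scores reproduce centred data distances (isometry)
  expect_equal(as.vector(dist(pca_project(X, 5)$scores)),
               as.vector(dist(X)), tolerance = 1e-9)
})

test_that("Hopkins drops toward 0.5 when structure is destroyed by shuffling", {
  pr <- builtin_profiles()
  sessions <- lapply(pr[c("Parietaria officinalis", "Olea euopaea",
                          "Festuca pratensis")], function(p) {
    simulate_session(p, contamination_model(), 60,
                     seed = derive_seed(77, p$name))
  })
  cum <- build_cumulative_dataset(sessions, n_draws = 10, seed = 77)
  h <- hopkins_statistic(cum$size, seed = 1)
  set.seed(42)
  shuffled <- t(apply(cum$size, 1, sample))
  h_shuf <- mean(sapply(1:5, function(s) hopkins_statistic(shuffled, seed = s)))
  expect_gt(h, 0.85)
  expect_lt(h_shuf, h - 0.1)
})
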