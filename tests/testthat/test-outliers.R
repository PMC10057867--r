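test_that("LOF scores 1 on perfectly homogeneous configurations", {
  # vertices of a regular simplex: every point sees identical geometry
  X <- diag(5)
  expect_equal(lof_scores(X, n_neighbors = 2), rep(1, 5), tolerance = 1e-12)
})

test_that("LOF matches the brute-force definition, with an extreme outlier", {
  X <- matrix(c(0, 1, 2, 3, 100), ncol = 1)
  got <- lof_scores(X, n_neighbors = 2)
  want <- lof_brute(X, k = 2)
  expect_equal(got, want, tolerance = 1e-9)
  expect_gt(got[5], 10 * max(got[1:4]))

  set.seed(21)
  for (p in c(1, 2)) {
    Y <- matrix(rnorm(24), ncol = 2)
    expect_equal(lof_scores(Y, 3, p), lof_brute(Y, 3, p), tolerance = 1e-9)
  }
})

test_that("LOF stays near 1 inside dense blobs and handles duplicates", {
  set.seed(7)
  X <- rbind(matrix(runif(100), ncol = 2),
             matrix(runif(100) + 5, ncol = 2))
  s <- lof_scores(X, 10)
  expect_equal(s, lof_brute(X, 10), tolerance = 1e-9)
  expect_lt(median(abs(s - 1)), 0.1)
  expect_lt(max(s), 1.6)           # edge points only mildly elevated
  # exact duplicates: the stack scores as perfect inliers, a point right
  # next to the stack is infinitely less dense; neither is a failure
  D <- rbind(matrix(1, 4, 2), matrix(c(0, 0, 5, 5), 2, 2))
  sD <- lof_scores(D, 2)
  expect_equal(sD[1:4], rep(1, 4))
  expect_false(any(is.nan(sD)))
})

test_that("silhouette agrees with the closed-form value and the reference", {
  X <- matrix(c(0, 1, 5, 6), ncol = 1)
  lab <- c("A", "A", "B", "B")
  # by hand: a = 1 for all; b = 5.5, 4.5, 4.5, 5.5
  expect_equal(silhouette_score(X, lab),
               mean(c(4.5 / 5.5, 3.5 / 4.5, 3.5 / 4.5, 4.5 / 5.5)),
               tolerance = 1e-12)
  set.seed(13)
  Y <- matrix(rnorm(60), ncol = 3)
  lab2 <- sample(1:3, 20, replace = TRUE)
  ref <- mean(cluster::silhouette(lab2, dist(Y))[, "sil_width"])
  expect_equal(silhouette_score(Y, lab2), ref, tolerance = 1e-9)
})

test_that("silhouette behaves at the separation limit and under random labels", {
  X <- rbind(c(0, 0), c(0.01, 0), c(100, 0), c(100.01, 0))
  expect_gt(silhouette_score(X, c(1, 1, 2, 2)), 0.99)
  set.seed(3)
  blob <- matrix(rnorm(200), ncol = 2)
  s <- silhouette_score(blob, sample(1:2, 100, replace = TRUE))
  expect_lt(abs(s), 0.1)
  expect_error(silhouette_score(blob, rep(1, 100)), "two clusters")
})

test_that("tuned LOF recovers planted outliers", {
  set.seed(17)
  X <- rbind(matrix(runif(190), ncol = 2),
             matrix(runif(10, 20, 30), ncol = 2))
  params <- tune_lof(X, n_neighbors_grid = c(5L, 10L, 20L), p_grid = c(1, 2),
                     seed = 2)
  inlier <- filter_outliers(X, params)
  expect_equal(which(!inlier), 96:100)
})

test_that("a one-element grid is returned as-is", {
  set.seed(2)
  X <- matrix(rnorm(60), ncol = 2)
  params <- tune_lof(X, n_neighbors_grid = 7L, p_grid = 2, seed = 1)
  expect_equal(params$n_neighbors, 7L)
  expect_equal(params$p, 2)
  expect_equal(nrow(params$grid), 1L)
})

test_that("outlier filtering shrinks the aggregate peak of a contaminated session", {
  cfg <- instrument_config()
  pr <- builtin_profiles()[["Olea euopaea"]]
  ses <- simulate_session(pr, contamination_model(), 240, cfg, seed = 19)
  X <- session_matrix(ses, 1L)
  params <- tune_lof(X, seed = 5)
  keep <- filter_outliers(X, params)
  centres <- bin_centres(cfg)
  agg_bins <- which(abs(log(centres / 40)) < 0.2)
  before <- session_size_distribution(ses, cfg, mode = "volume")$counts
  after <- session_size_distribution(ses, cfg, keep = keep, mode = "volume")$counts
  # mass near the 40-micron aggregate mode, relative to total, must drop
  expect_lt(sum(after[agg_bins]) / sum(after),
            sum(before[agg_bins]) / sum(before))
  expect_true(any(!keep))
})
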