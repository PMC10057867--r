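test_that("separable classes are learned perfectly, with sane thresholds", {
  b <- sig_blobs(rbind(rep(0, 6), rep(3, 6)), 30, sd = 0.1, seed = 2)
  m <- train_ovo(b$X, b$labels, seed = 1)
  expect_length(m$fits, 1L)
  expect_true(all(vapply(m$fits, function(f) f$threshold, 0) > 0 &
                    vapply(m$fits, function(f) f$threshold, 0) < 1))
  pred <- predict(m, b$X)
  expect_equal(pred, b$labels)
})

test_that("a {0.5} threshold grid reduces to plain argmax voting", {
  b <- sig_blobs(rbind(rep(0, 6), c(2, rep(0, 5)), c(0, 2, rep(0, 4))),
                 25, sd = 0.4, seed = 3)
  m <- train_ovo(b$X, b$labels, seed = 1, threshold_grid = 0.5)
  expect_true(all(vapply(m$fits, function(f) f$threshold, 0) == 0.5))
  # plain OvO baseline computed directly from the fitted pair models
  Z <- scale(log(b$X), m$center, m$scale)
  votes <- matrix(0L, nrow(Z), 3, dimnames = list(NULL, m$classes))
  for (f in m$fits) {
    p <- plogis(cbind(1, Z) %*% f$coef)
    w <- ifelse(p >= 0.5, f$pair[2], f$pair[1])
    for (i in seq_len(nrow(Z))) votes[i, w[i]] <- votes[i, w[i]] + 1L
  }
  base <- m$classes[apply(votes, 1, which.max)]
  pred <- predict(m, b$X)
  # rows without a 1-1-1 cycle: the plain argmax is unambiguous
  agree <- votes[cbind(seq_len(nrow(Z)), match(base, m$classes))] == 2L
  expect_equal(pred[agree], base[agree])
})

test_that("recall approaches the Gaussian Bayes optimum on overlapping classes", {
  # equal spherical covariance in log-feature space, centres 2 sd apart:
  # optimal rule accepts at the midpoint, per-class accuracy pnorm(1)
  delta <- 2
  b <- sig_blobs(rbind(rep(0, 6), rep(delta / sqrt(6), 6)), 1000, sd = 1,
                 seed = 4)
  rep_cv <- evaluate_cv(b$X, b$labels, folds = 5, repeats = 1, seed = 9)
  bayes <- pnorm(delta / 2)
  for (r in rep_cv$recall) expect_lt(abs(r - bayes), 0.05)
})

test_that("prediction agrees with an exhaustive vote-count oracle", {
  cen <- matrix(rnorm(5 * 6, sd = 2), 5)
  b <- sig_blobs(cen, 20, sd = 0.5, seed = 6)
  m <- train_ovo(b$X, b$labels, seed = 2)
  pred <- predict(m, b$X)
  Z <- scale(log(b$X), m$center, m$scale)
  oracle <- character(nrow(Z))
  for (i in seq_len(nrow(Z))) {
    v <- setNames(numeric(5), m$classes)
    s <- setNames(numeric(5), m$classes)
    for (f in m$fits) {
      p <- plogis(sum(c(1, Z[i, ]) * f$coef))
      if (p >= f$threshold) { v[f$pair[2]] <- v[f$pair[2]] + 1; s[f$pair[2]] <- s[f$pair[2]] + p }
      else { v[f$pair[1]] <- v[f$pair[1]] + 1; s[f$pair[1]] <- s[f$pair[1]] + 1 - p }
    }
    top <- names(v)[v == max(v)]
    if (length(top) > 1L) top <- top[s[top] == max(s[top])]
    oracle[i] <- sort(top)[1]
  }
  expect_equal(pred, oracle)
})

test_that("ties fall back to probability mass, then lexicographic order", {
  # a hand-built 3-class model with a symmetric cycle: A beats B, B beats C,
  # C beats A, so every class gets one vote and probabilities decide
  model <- structure(list(
    classes = c("A", "B", "C"),
    fits = list(
      list(pair = c("A", "B"), coef = c(-10, rep(0, 6)), threshold = 0.5),
      list(pair = c("B", "C"), coef = c(-10, rep(0, 6)), threshold = 0.5),
      list(pair = c("A", "C"), coef = c(10, rep(0, 6)), threshold = 0.5)),
    center = rep(0, 6), scale = rep(1, 6)), class = "ovo_model")
  x <- matrix(1, 1, 6,
              dimnames = list(NULL, c("S2", "S3", "S4", "S2_over_S3",
                                      "S2_over_S4", "S3_over_S4")))
  # winning probabilities: A 1-plogis(-10) ~ 1 from pair AB... all ~equal 1;
  # strengths tie at ~1 each, so the lexicographic rule returns "A"
  expect_equal(predict(model, x), "A")
  bad <- matrix(c(-1, 1, 1, 1, 1, 1), 1)  # negative entry -> log is NaN
  colnames(bad) <- colnames(x)
  expect_equal(predict(model, bad), "unclassified")
})

test_that("label-shuffled data scores at chance level", {
  b <- sig_blobs(rbind(rep(0, 6), rep(0.2, 6), rep(0.4, 6)), 60, sd = 1,
                 seed = 7)
  set.seed(5)
  shuffled <- sample(b$labels)
  rep_cv <- evaluate_cv(b$X, shuffled, folds = 5, repeats = 2, seed = 3)
  expect_lt(abs(mean(rep_cv$recall) - 1 / 3), 0.10)
})

test_that("confusion bookkeeping is exact over repeats", {
  b <- sig_blobs(rbind(rep(0, 6), rep(1, 6)), 20, sd = 0.8, seed = 8)
  rep_cv <- evaluate_cv(b$X, b$labels, folds = 4, repeats = 3, seed = 2)
  conf <- rep_cv$confusion
  expect_equal(unname(rowSums(conf)), rep_cv$support * 3L)
  expect_true(all(rep_cv$recall >= 0 & rep_cv$recall <= 1))
  # determinism under the same seed
  rep2 <- evaluate_cv(b$X, b$labels, folds = 4, repeats = 3, seed = 2)
  expect_identical(rep_cv$confusion, rep2$confusion)
  expect_error(evaluate_cv(b$X, b$labels, folds = 25), "fewer folds")
})

test_that("per-cluster classification respects rosters and skips degenerates", {
  b1 <- sig_blobs(rbind(rep(0, 6), rep(2, 6)), 15, sd = 0.3, seed = 10)
  sig <- data.frame(b1$X,
                    species = rep(c("pollenA", "droplet"), each = 15),
                    valid = TRUE)
  cluster_map <- c(pollenA = 1L, lonely = 2L)
  reports <- suppressWarnings(per_cluster_classify(
    sig, cluster_map, rosters = list("1" = "droplet"),
    folds = 5, repeats = 1, seed = 1))
  expect_named(reports, "1")
  expect_setequal(rownames(reports[["1"]]$confusion), c("pollenA", "droplet"))
  w <- capture_warnings(per_cluster_classify(sig, cluster_map,
                                             folds = 5, repeats = 1, seed = 1))
  expect_match(w, "fewer than two classes", all = TRUE)
  expect_length(w, 2L)  # both single-class clusters are skipped
})

test_that("species with identical gain triples confuse mainly each other", {
  cfg <- instrument_config()
  cont <- contamination_model()
  twinA <- species_profile("twinA", 28, c(1.1, 0.75, 0.55), mean_rate = 12)
  twinB <- species_profile("twinB", 28, c(1.1, 0.75, 0.55), mean_rate = 12)
  far   <- species_profile("far",   28, c(0.45, 0.20, 0.12), mean_rate = 12)
  tabs <- lapply(list(twinA, twinB, far), function(p) {
    ses <- simulate_session(p, cont, 100, cfg, seed = derive_seed(55, p$name))
    ov <- oversample_cumulative(ses$frames, n_draws = 15,
                                seed = derive_seed(56, p$name))
    signature_table(ov$counts, cfg$bin_edges,
                    species = rep(p$name, 15))
  })
  sig <- do.call(rbind, tabs)
  sig <- sig[sig$valid, ]
  rep_cv <- evaluate_cv(sig, sig$species, folds = 5, repeats = 2, seed = 4)
  conf <- rep_cv$confusion
  # twins: off-diagonal mass lands overwhelmingly on the other twin
  expect_gt(conf["twinA", "twinB"] + conf["twinA", "twinA"],
            0.9 * sum(conf["twinA", ]))
  expect_gt(conf["twinB", "twinA"] + conf["twinB", "twinB"],
            0.9 * sum(conf["twinB", ]))
  # the optically distinct class is recovered
  expect_gt(rep_cv$recall[["far"]], 0.95)
})
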