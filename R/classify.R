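#' One-vs-one logistic classifier over optical signatures
#'
#' Trains one binary logistic regression per unordered class pair on the
#' 6-element optical signatures (log-transformed, then standardised: the
#' entries are positive ratios spanning decades). Each pair's decision
#' threshold is tuned on inner held-out folds to maximise the macro-averaged
#' F1 score over a fixed probability grid, so that an imbalanced or
#' overlapping pair is not stuck with the default 0.5 cut.
#'
#' @param signatures Matrix or data.frame with the six signature columns
#'   (S2, S3, S4, S2_over_S3, S2_over_S4, S3_over_S4).
#' @param labels Class label per row.
#' @param seed Integer seed (fold assignment).
#' @param threshold_grid Candidate decision thresholds in (0, 1).
#' @param inner_folds Folds of the inner threshold-tuning split.
#' @return An object of class `ovo_model`.
#' @export
train_ovo <- function(signatures, labels,
                      seed = 1L,
                      threshold_grid = seq(0.05, 0.95, by = 0.05),
                      inner_folds = 3L) {
  X <- signature_features(signatures)
  labels <- as.character(labels)
  keep <- stats::complete.cases(X) & apply(is.finite(X), 1, all)
  if (!all(keep)) {
    message(sum(!keep), " rows with non-finite features dropped")
    X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  counts <- table(labels)
  # ten or more rows per class are recommended for stable thresholds; three
  # is the mechanical minimum for the inner tuning split to see both classes
  if (any(counts < 3L)) {
    stop("every class needs at least 3 samples", call. = FALSE)
  }

  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, ctr, scl)

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- labels %in% pr
    Zi <- Z[idx, , drop = FALSE]
    y <- as.integer(labels[idx] == pr[2L])   # positive class = second of pair
    thr <- tune_threshold(Zi, y, threshold_grid, inner_folds)
    list(pair = pr, coef = fit_logistic(Zi, y), threshold = thr)
  })
  structure(list(classes = classes, fits = fits,
                 center = ctr, scale = scl, seed = seed),
            class = "ovo_model")
}

signature_features <- function(signatures) {
  cols <- c("S2", "S3", "S4", "S2_over_S3", "S2_over_S4", "S3_over_S4")
  if (is.data.frame(signatures) && all(cols %in% names(signatures))) {
    signatures <- signatures[, cols]
  }
  X <- as.matrix(signatures)
  stopifnot(ncol(X) == 6L)
  suppressWarnings(log(X))
}

fit_logistic <- function(Z, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Z), y, family = stats::binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

pair_prob <- function(cf, Z) {
  as.vector(stats::plogis(cbind(1, Z) %*% cf))
}

macro_f1 <- function(truth, pred) {
  f1 <- function(pos) {
    tp <- sum(truth == pos & pred == pos)
    fp <- sum(truth != pos & pred == pos)
    fn <- sum(truth == pos & pred != pos)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  (f1(0L) + f1(1L)) / 2
}

tune_threshold <- function(Z, y, grid, inner_folds) {
  if (length(grid) == 1L) return(grid)
  fold <- stratified_folds(y, inner_folds)
  prob <- numeric(length(y))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) { prob[!tr] <- mean(y[tr]); next }
    cf <- fit_logistic(Z[tr, , drop = FALSE], y[tr])
    prob[!tr] <- pair_prob(cf, Z[!tr, , drop = FALSE])
  }
  scores <- vapply(grid, function(t) macro_f1(y, as.integer(prob >= t)), 0)
  best <- which(scores == max(scores))
  grid[best[which.min(abs(grid[best] - 0.5))]]  # ties: closest to 0.5
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- which(labels == l)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Predict class labels from a one-vs-one model
#'
#' Every pairwise classifier casts a vote using its tuned threshold; the
#' majority label wins. Ties are broken by the largest sum of winning-pair
#' probabilities, then by lexicographic class order. Rows with invalid
#' (non-finite) signatures are labelled `"unclassified"`.
#'
#' @param object An `ovo_model`.
#' @param signatures New signature rows.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.ovo_model <- function(object, signatures, ...) {
  X <- signature_features(signatures)
  valid <- stats::complete.cases(X) & apply(is.finite(X), 1, all)
  out <- rep("unclassified", nrow(X))
  if (!any(valid)) return(out)
  Z <- scale(X[valid, , drop = FALSE], object$center, object$scale)
  n <- nrow(Z)
  classes <- object$classes
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  strength <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (f in object$fits) {
    p <- pair_prob(f$coef, Z)            # P(second class of pair)
    win2 <- p >= f$threshold
    w <- ifelse(win2, f$pair[2L], f$pair[1L])
    for (i in seq_len(n)) {
      votes[i, w[i]] <- votes[i, w[i]] + 1L
      strength[i, w[i]] <- strength[i, w[i]] + if (win2[i]) p[i] else 1 - p[i]
    }
  }
  pred <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) {
      s <- strength[i, top]
      top <- top[s == max(s)]
    }
    classes[min(top)]                    # lexicographic (classes sorted)
  }, "")
  out[valid] <- pred
  out
}

#' Repeated stratified cross-validated evaluation
#'
#' Splits the rows into stratified folds, trains the one-vs-one model on
#' the training folds only (decision thresholds are tuned inside the
#' training data), predicts the held-out fold, and accumulates the confusion
#' counts over all repeats.
#'
#' @param signatures Signature rows (six feature columns).
#' @param labels Class label per row.
#' @param folds Number of folds (default 10).
#' @param repeats Number of repetitions of the whole CV (default 5).
#' @param seed Integer seed.
#' @param ... Passed to [train_ovo()].
#' @return An object of class `classifier_report`: list with `confusion`
#'   (true x predicted counts, predictions may include "unclassified"),
#'   `recall` (named per-class), `protocol` (folds, repeats, seed),
#'   `support` (per-class row counts).
#' @export
evaluate_cv <- function(signatures, labels, folds = 10L, repeats = 5L,
                        seed = 1L, ...) {
  X <- signature_features(signatures)
  labels <- as.character(labels)
  keep <- stats::complete.cases(X) & apply(is.finite(X), 1, all)
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < folds)) {
    stop("class '", names(counts)[which.min(counts)], "' has fewer members (",
         min(counts), ") than folds (", folds, "); use fewer folds",
         call. = FALSE)
  }
  Xexp <- exp(X)  # train_ovo re-applies the log transform

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  pred_levels <- c(classes, "unclassified")
  conf <- matrix(0L, length(classes), length(pred_levels),
                 dimnames = list(true = classes, predicted = pred_levels))
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, paste0("cv:", r)))
    fold <- stratified_folds(labels, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- train_ovo(Xexp[tr, , drop = FALSE], labels[tr],
                         seed = derive_seed(seed, paste0("cv:", r, ":", f)),
                         ...)
      p <- predict(model, Xexp[!tr, , drop = FALSE])
      conf <- conf + table(factor(labels[!tr], classes),
                           factor(p, pred_levels))
    }
  }
  if (all(conf[, "unclassified"] == 0L)) {
    conf <- conf[, classes, drop = FALSE]
  }
  recall <- diag(conf[, classes, drop = FALSE]) / rowSums(conf)
  structure(list(confusion = conf,
                 recall = recall,
                 support = as.integer(counts[classes]),
                 protocol = list(folds = folds, repeats = repeats,
                                 seed = seed)),
            class = "classifier_report")
}

#' Per-size-cluster classification
#'
#' Trains and evaluates one one-vs-one model per size cluster, over the
#' pollen species the clustering assigned to that cluster plus the
#' configured non-pollen classes. A non-pollen class list per cluster is
#' part of the configuration because some contaminants never co-occur with
#' some size classes (strongly absorbing carbonaceous particles are rarely
#' found at large-pollen sizes in ambient air).
#'
#' @param signatures Signature data.frame from [signature_table()] (needs
#'   `species` and `valid` columns).
#' @param cluster_map Named integer vector: majority size cluster per pollen
#'   species (from [hierarchical_cluster()]).
#' @param rosters Named list: for each cluster id (as character), the
#'   non-pollen class names to include.
#' @param folds,repeats,seed See [evaluate_cv()].
#' @param ... Passed to [train_ovo()].
#' @return Named list of `classifier_report` objects, one per cluster;
#'   clusters with fewer than two available classes are skipped with a
#'   warning.
#' @export
per_cluster_classify <- function(signatures, cluster_map, rosters = list(),
                                 folds = 10L, repeats = 5L, seed = 1L, ...) {
  stopifnot(!is.null(signatures$species), !is.null(signatures$valid))
  reports <- list()
  for (cl in sort(unique(cluster_map))) {
    members <- c(names(cluster_map)[cluster_map == cl],
                 rosters[[as.character(cl)]])
    sub <- signatures[signatures$valid & signatures$species %in% members, ]
    support <- table(sub$species)
    thin <- names(support)[support < folds]
    if (length(thin)) {
      warning("cluster ", cl, ": dropping classes with fewer valid ",
              "signatures than folds: ", paste(thin, collapse = ", "))
      sub <- sub[!sub$species %in% thin, ]
    }
    if (length(unique(sub$species)) < 2L) {
      warning("cluster ", cl, " has fewer than two classes; skipped")
      next
    }
    reports[[as.character(cl)]] <-
      evaluate_cv(sub, sub$species, folds = folds, repeats = repeats,
                  seed = derive_seed(seed, paste0("cluster:", cl)), ...)
  }
  reports
}
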