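#' Oversample frames into cumulative distributions
#'
#' Scattering statistics per size bin only stabilise once a bin holds enough
#' particles, so single 10-s frames are too sparse to characterise a species.
#' Each draw sums frames sampled with replacement until every sizing-channel
#' bin that is occupied session-wide holds at least `min_per_bin` counts, or
#' the frame budget is hit (the draw is then flagged rather than silently
#' returned short). Counts are conserved: a cumulative row is exactly the sum
#' of its constituent frames, on all four channels.
#'
#' @param frames n_frames x (4 * n_bins) numeric matrix of flattened frames
#'   (channel-major), or a list of [new_frame()] objects.
#' @param n_draws Number of cumulative rows to build (default 30).
#' @param min_per_bin Minimum counts per occupied sizing bin (default 20).
#' @param seed Integer seed.
#' @param budget_factor Frame budget per draw, as a multiple of the session
#'   length.
#' @param n_bins Bins per channel.
#' @return List with `counts` (n_draws x 4*n_bins matrix), `size` (n_draws x
#'   n_bins sizing-channel sub-matrix), `flagged` (logical per draw),
#'   `frames_used` (integer per draw).
#' @export
oversample_cumulative <- function(frames, n_draws = 30L, min_per_bin = 20L,
                                  seed = 1L, budget_factor = 10,
                                  n_bins = 19L) {
  if (is.list(frames)) {
    frames <- t(vapply(frames, flatten_frame, numeric(4L * n_bins)))
  }
  frames <- as.matrix(frames)
  n <- nrow(frames)
  if (n == 0L) stop("no frames to oversample", call. = FALSE)
  stopifnot(ncol(frames) %% 4L == 0L)
  n_bins <- ncol(frames) %/% 4L

  occupied <- colSums(frames[, seq_len(n_bins), drop = FALSE]) > 0
  budget <- ceiling(budget_factor * n)

  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  counts <- matrix(0, n_draws, ncol(frames))
  flagged <- logical(n_draws)
  used <- integer(n_draws)
  for (j in seq_len(n_draws)) {
    acc <- numeric(ncol(frames))
    k <- 0L
    repeat {
      k <- k + 1L
      acc <- acc + frames[sample.int(n, 1L), ]
      if (all(acc[seq_len(n_bins)][occupied] >= min_per_bin)) break
      if (k >= budget) { flagged[j] <- TRUE; break }
    }
    counts[j, ] <- acc
    used[j] <- k
  }
  list(counts = counts,
       size = counts[, seq_len(n_bins), drop = FALSE],
       flagged = flagged,
       frames_used = used)
}

#' Row-normalise a non-negative matrix
#'
#' Divides every non-zero row by its sum; zero rows are left at zero and
#' flagged in the `zero_rows` attribute.
#'
#' @param M Non-negative numeric matrix.
#' @return Matrix whose non-zero rows sum to 1, with attribute `zero_rows`.
#' @export
row_normalize <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("rows must be non-negative", call. = FALSE)
  s <- rowSums(M)
  zero <- s == 0
  out <- M
  out[!zero, ] <- M[!zero, , drop = FALSE] / s[!zero]
  structure(out, zero_rows = which(zero))
}

#' Build the multi-species cumulative dataset
#'
#' Runs the LOF filter and the cumulative oversampling on each session, then
#' concatenates and row-normalises the sizing-channel rows: with 12 species
#' and 30 draws each this is the 360 x 19 matrix the size clustering runs
#' on. The full four-channel cumulative counts are kept alongside for the
#' optical-signature stage.
#'
#' @param sessions Named list of `session` objects (names = species).
#' @param n_draws Draws per species.
#' @param min_per_bin Minimum counts per occupied sizing bin.
#' @param lof_grid,lof_p_grid,lof_threshold LOF tuning grid, see [tune_lof()].
#' @param seed Integer seed.
#' @return List with `size` (normalised rows x n_bins matrix), `counts`
#'   (rows x 4*n_bins raw cumulative counts), `species` (row labels),
#'   `flagged`, `inliers` (named list of per-session inlier masks), `lof`
#'   (named list of tuned parameters per session).
#' @export
build_cumulative_dataset <- function(sessions, n_draws = 30L,
                                     min_per_bin = 20L,
                                     lof_grid = c(5L, 10L, 20L, 35L),
                                     lof_p_grid = c(1, 2),
                                     lof_threshold = 1.5,
                                     seed = 1L) {
  stopifnot(length(sessions) >= 1L)
  if (is.null(names(sessions))) {
    names(sessions) <- vapply(sessions, `[[`, "", "species")
  }
  size_rows <- list(); count_rows <- list(); flagged <- list()
  inliers <- list(); lof <- list()
  for (sp in names(sessions)) {
    ses <- sessions[[sp]]
    X <- session_matrix(ses, 1L)
    s_seed <- derive_seed(seed, paste0("lof:", sp))
    params <- tune_lof(X, lof_grid, lof_p_grid, lof_threshold, seed = s_seed)
    keep <- filter_outliers(X, params)
    if (!any(keep)) keep <- rep(TRUE, nrow(X))  # refuse to drop a whole session
    fr <- t(vapply(ses$frames[keep], flatten_frame,
                   numeric(4L * ncol(ses$frames[[1]]))))
    ov <- oversample_cumulative(fr, n_draws, min_per_bin,
                                seed = derive_seed(seed, paste0("ov:", sp)))
    size_rows[[sp]] <- ov$size
    count_rows[[sp]] <- ov$counts
    flagged[[sp]] <- ov$flagged
    inliers[[sp]] <- keep
    lof[[sp]] <- params[c("n_neighbors", "p", "threshold", "silhouette")]
  }
  size <- do.call(rbind, size_rows)
  species <- rep(names(sessions), each = n_draws)
  list(size = row_normalize(size),
       counts = do.call(rbind, count_rows),
       species = species,
       flagged = unlist(flagged, use.names = FALSE),
       inliers = inliers,
       lof = lof)
}

#' Derive a stage seed from a top-level seed
#'
#' One top-level seed reproduces a whole run: each stage gets a seed derived
#' deterministically from the top-level seed and a stage tag, kept inside
#' the 32-bit integer range.
#'
#' @param seed Top-level integer seed.
#' @param tag Stage tag string.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
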