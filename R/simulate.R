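#' Simulate one measurement frame
#'
#' Draws a Poisson number of particles at the profile's mean rate, gives each
#' a lognormal optical diameter (inflated by the aggregate factor for the
#' aggregate fraction), maps diameters to sizing-channel intensities through
#' the calibration with a multiplicative lognormal sizing noise (irregular,
#' randomly oriented grains do not scatter like the equivalent sphere), and
#' derives the speciation-channel intensities as gain times the sizing
#' intensity times lognormal channel noise. All four intensity vectors are
#' binned into the frame.
#'
#' Contamination adds ambient particles to a fraction of frames and a trickle
#' of broad-size debris. A frame simulated with `outlier = TRUE` is generated
#' from a corrupted mixture in which ambient particles, debris and aggregates
#' dominate the true grains.
#'
#' @param profile A [species_profile()].
#' @param contamination A [contamination_model()].
#' @param cfg An [instrument_config()].
#' @param timestamp Frame timestamp, seconds.
#' @param outlier Simulate a grossly contaminated frame.
#' @param sizing_noise Lognormal sigma (log scale) of the sizing-channel
#'   intensity response.
#' @param channel_noise Lognormal sigma (log scale) of the speciation-channel
#'   gains.
#' @return A [new_frame()] with attribute `true_diameters` (micrometres, all
#'   particles including contaminants).
#' @export
simulate_frame <- function(profile, contamination = no_contamination(),
                           cfg = instrument_config(), timestamp = 0,
                           outlier = FALSE,
                           sizing_noise = 0.15, channel_noise = 0.15) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(contamination, "contamination_model"))
  agg_frac <- contamination$aggregate_fraction

  n <- stats::rpois(1L, profile$mean_rate)
  d <- stats::rlnorm(n, log(profile$median_diameter), log(profile$gsd))
  gains <- if (n > 0) matrix(profile$gains, nrow = n, ncol = 3L, byrow = TRUE)
           else matrix(numeric(0), 0L, 3L)

  # ambient burst: occasional in normal frames, dominant in outlier frames
  amb_rate <- if (outlier) {
    2 * profile$mean_rate + 5
  } else if (stats::runif(1) < contamination$ambient_fraction) {
    2
  } else 0
  n_amb <- if (amb_rate > 0) stats::rpois(1L, amb_rate) else 0L
  if (n_amb > 0) {
    d_amb <- stats::rlnorm(n_amb, log(contamination$ambient_diameter), log(1.5))
    d <- c(d, d_amb)
    gains <- rbind(gains, matrix(c(0.8, 0.6, 0.5), n_amb, 3L, byrow = TRUE))
  }

  deb_rate <- contamination$debris_fraction * profile$mean_rate *
    if (outlier) 25 else 1
  n_deb <- if (deb_rate > 0) stats::rpois(1L, deb_rate) else 0L
  if (n_deb > 0) {
    d_deb <- stats::rlnorm(n_deb, log(20), log(2))
    d <- c(d, d_deb)
    gains <- rbind(gains, matrix(c(0.6, 0.5, 0.45), n_deb, 3L, byrow = TRUE))
  }

  if (outlier) agg_frac <- max(agg_frac, 0.5)
  n_tot <- length(d)
  if (n_tot > 0 && agg_frac > 0) {
    is_agg <- stats::runif(n_tot) < agg_frac & seq_len(n_tot) <= n
    d[is_agg] <- d[is_agg] * contamination$aggregate_factor
  }

  counts <- matrix(0L, 4L, cfg$n_bins)
  if (n_tot > 0) {
    i1 <- diameter_to_intensity(d, cfg$calibration) *
      stats::rlnorm(n_tot, 0, sizing_noise)
    counts[1L, ] <- bin_intensities(i1, cfg$bin_edges)
    for (c in 2:4) {
      ic <- gains[, c - 1L] * i1 * stats::rlnorm(n_tot, 0, channel_noise)
      counts[c, ] <- bin_intensities(ic, cfg$bin_edges)
    }
  }
  out <- new_frame(counts, timestamp = timestamp)
  attr(out, "true_diameters") <- d
  out
}

#' Simulate a measurement session
#'
#' Generates an ordered sequence of frames for one particle class, flagging
#' a configured fraction of them as grossly contaminated (ground-truth
#' outliers). Reproducible: the same seed yields an identical session.
#'
#' @param profile A [species_profile()].
#' @param contamination A [contamination_model()].
#' @param n_frames Number of frames; laboratory sessions run 30--50 min at a
#'   10-s cadence, i.e. roughly 180--300 frames.
#' @param cfg An [instrument_config()].
#' @param seed Integer seed.
#' @param ... Passed to [simulate_frame()] (noise levels).
#' @return An object of class `session`: list with `species`, `frames`
#'   (list of frames), `outlier` (ground-truth logical per frame),
#'   `diameters` (list of per-particle true diameters per frame), `seed`.
#' @export
simulate_session <- function(profile, contamination = contamination_model(),
                             n_frames = 240L, cfg = instrument_config(),
                             seed = 1L, ...) {
  stopifnot(n_frames >= 1L)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  flags <- stats::runif(n_frames) < contamination$outlier_frame_fraction
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    frames[[i]] <- simulate_frame(profile, contamination, cfg,
                                  timestamp = (i - 1L) * cfg$frame_period,
                                  outlier = flags[i], ...)
  }
  structure(list(species = profile$name,
                 frames = frames,
                 outlier = flags,
                 diameters = lapply(frames, attr, "true_diameters"),
                 seed = seed),
            class = "session")
}

#' Stack a session's sizing-channel counts into a matrix
#'
#' @param session A [simulate_session()] result.
#' @param channel Channel index (1 = sizing channel).
#' @return n_frames x n_bins numeric matrix.
#' @export
session_matrix <- function(session, channel = 1L) {
  t(vapply(session$frames,
           function(f) as.numeric(unclass(f)[channel, ]),
           numeric(ncol(session$frames[[1]]))))
}

#' Session-level size distribution
#'
#' Sums the sizing-channel counts over the (optionally subset) frames.
#'
#' @param session A [simulate_session()] result.
#' @param cfg An [instrument_config()].
#' @param keep Logical vector of frames to include (default all).
#' @param mode `"number"` or `"volume"`.
#' @return A `size_distribution`.
#' @export
session_size_distribution <- function(session, cfg = instrument_config(),
                                      keep = NULL, mode = "number") {
  m <- session_matrix(session, 1L)
  if (!is.null(keep)) m <- m[keep, , drop = FALSE]
  frame_to_size_distribution(colSums(m), cfg, mode = mode)
}
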