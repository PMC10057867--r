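#' Intensity histogram to density curve
#'
#' Converts binned counts into a number density over scattered intensity,
#' `dN/dF`: counts divided by bin width, attached to the bin's geometric
#' centre (intensity bins span decades, so the geometric centre is the
#' natural support point).
#'
#' @param counts Counts per bin (length `n_bins`).
#' @param edges Strictly increasing bin edges (length `n_bins + 1`).
#' @return An object of class `density_curve`: list with `support`
#'   (geometric bin centres), `density` (`counts / bin width`), `edges`,
#'   `counts`.
#' @export
histogram_to_density <- function(counts, edges) {
  stopifnot(length(edges) == length(counts) + 1L, all(diff(edges) > 0),
            all(counts >= 0))
  structure(list(support = sqrt(edges[-length(edges)] * edges[-1]),
                 density = as.numeric(counts) / diff(edges),
                 edges = edges,
                 counts = as.numeric(counts)),
            class = "density_curve")
}

spec_error <- function(msg, class) {
  stop(structure(class = c(class, "speciation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Log-log polyline of the matching quantity F * dN/dF (counts per
# logarithmic intensity interval) over the populated bins, extended at the
# outer segments' slopes to the outermost populated bin edges: the reference
# intensity is a bin lower bound, which can sit below the first bin centre.
# Zero-density bins between populated ones are bridged linearly in log space.
loglog_points <- function(curve) {
  keep <- curve$density > 0
  if (sum(keep) < 2L) {
    spec_error("density curve has fewer than two populated bins",
               "speciation_no_signal")
  }
  lx <- log(curve$support[keep])
  ly <- log(curve$density[keep] * curve$support[keep])
  lo <- log(curve$edges[which(keep)[1]])
  hi <- log(curve$edges[which(keep)[sum(keep)] + 1L])
  n <- length(lx)
  s_lo <- (ly[2] - ly[1]) / (lx[2] - lx[1])
  s_hi <- (ly[n] - ly[n - 1]) / (lx[n] - lx[n - 1])
  list(lx = c(lo, lx, hi),
       ly = c(ly[1] + s_lo * (lo - lx[1]), ly, ly[n] + s_hi * (hi - lx[n])))
}

#' Speciation index of one channel
#'
#' The speciation index compares a speciation channel with the sizing
#' channel at equal number concentration, `(dN/dF1) F1 = (dN/dFc) Fc`: given
#' a reference intensity `F1` on the sizing channel (the lower bound of the
#' intensity bin holding the particles of interest), the concentration per
#' logarithmic intensity interval `F * dN/dF` of the sizing channel is
#' evaluated at `F1`, the speciation channel's curve is scanned from low
#' intensity upwards for the first intensity `Fc` at which it reaches the
#' same value, and the index is `S_c = F1 / Fc`. Transparent particles that
#' scatter strongly sideways give small indices; absorbing particles give
#' large ones. On the geometric bin grid a pure channel gain `g` translates
#' the matching curve horizontally, so `S_c = 1/g` up to interpolation.
#'
#' Both curves are interpolated linearly in log-intensity / log-value space,
#' the natural scale for scattering data spanning decades. Inversions
#' outside the speciation curve's value range are errors, not
#' extrapolations: an extrapolated index would fabricate optical contrast.
#'
#' @param d1 Sizing-channel [histogram_to_density()] curve.
#' @param dc Speciation-channel [histogram_to_density()] curve.
#' @param F1 Reference intensity on the sizing channel.
#' @return `S_c` (numeric), with attributes `Fc` and `n_crossings` (when
#'   the speciation curve is non-monotone the level can be reached several
#'   times; the first crossing is used and the count is reported).
#' @export
speciation_index <- function(d1, dc, F1) {
  stopifnot(inherits(d1, "density_curve"), inherits(dc, "density_curve"),
            is.numeric(F1), length(F1) == 1L, F1 > 0)
  p1 <- loglog_points(d1)
  lF1 <- log(F1)
  if (lF1 < min(p1$lx) || lF1 > max(p1$lx)) {
    spec_error("F1 outside the populated sizing-channel support",
               "speciation_out_of_range")
  }
  ly_star <- stats::approx(p1$lx, p1$ly, xout = lF1)$y

  pc <- loglog_points(dc)
  eps <- 1e-9  # tolerate float round-off at the curve's extremes
  if (ly_star > max(pc$ly) + eps || ly_star < min(pc$ly) - eps) {
    spec_error("matched density outside the speciation-channel range",
               "speciation_out_of_range")
  }
  ly_star <- min(max(ly_star, min(pc$ly)), max(pc$ly))
  lx <- pc$lx; ly <- pc$ly
  crossings <- numeric(0)
  for (i in seq_len(length(lx) - 1L)) {
    y0 <- ly[i]; y1 <- ly[i + 1L]
    if ((ly_star - y0) * (ly_star - y1) <= 0) {
      t <- if (y1 == y0) 0 else (ly_star - y0) / (y1 - y0)
      x <- lx[i] + t * (lx[i + 1L] - lx[i])
      if (length(crossings) == 0L || x > crossings[length(crossings)] + 1e-12) {
        crossings <- c(crossings, x)
      }
    }
  }
  if (length(crossings) == 0L) {
    spec_error("no crossing found on the speciation channel",
               "speciation_out_of_range")
  }
  Fc <- exp(crossings[1L])
  structure(F1 / Fc, Fc = Fc, n_crossings = length(crossings))
}

#' Optical signature of a four-channel histogram
#'
#' Computes the three speciation indices S2, S3, S4 and their pairwise
#' ratios, yielding the 6-element optical signature
#' `(S2, S3, S4, S2/S3, S2/S4, S3/S4)` used as the classification features.
#' By default the reference intensity `F1` is the lower bound of the
#' populated sizing-channel bin just below the modal bin (the modal bin
#' itself when it is the lowest populated one). Particles of interest are
#' counted throughout the peak; anchoring on the rising flank rather than
#' at the very top keeps the matched concentration well inside every
#' speciation channel's range, where the inversion is well conditioned --
#' at the peak itself the level is reachable only if the other channel's
#' peak straddles the bin grid the same way.
#'
#' @param counts 4 x n_bins count matrix (rows = channels), a [new_frame()],
#'   or a flat channel-major vector.
#' @param edges Intensity-bin edges shared by the channels.
#' @param F1 Reference intensity; overrides the modal-bin policy when given.
#' @return An object of class `optical_signature`: list with `signature`
#'   (named length-6 numeric), `valid`, `failed_channel` (NA or 2:4),
#'   `F1`.
#' @export
optical_signature <- function(counts, edges, F1 = NULL) {
  if (inherits(counts, "frame")) counts <- unclass(counts)
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 4L, byrow = TRUE)
  stopifnot(nrow(counts) == 4L, ncol(counts) == length(edges) - 1L)
  if (is.null(F1)) {
    if (all(counts[1L, ] == 0)) {
      return(invalid_signature(NA_real_, 1L))
    }
    modal <- which.max(counts[1L, ])
    below <- which(counts[1L, ] > 0 & seq_along(counts[1L, ]) < modal)
    F1 <- edges[if (length(below)) max(below) else modal]
  }
  d1 <- histogram_to_density(counts[1L, ], edges)
  S <- c(S2 = NA_real_, S3 = NA_real_, S4 = NA_real_)
  for (c in 2:4) {
    res <- tryCatch(
      speciation_index(d1, histogram_to_density(counts[c, ], edges), F1),
      speciation_error = function(e) NULL)
    if (is.null(res)) return(invalid_signature(F1, c))
    S[c - 1L] <- as.numeric(res)
  }
  sig <- c(S, S2_over_S3 = unname(S[1] / S[2]),
           S2_over_S4 = unname(S[1] / S[3]),
           S3_over_S4 = unname(S[2] / S[3]))
  structure(list(signature = sig, valid = TRUE,
                 failed_channel = NA_integer_, F1 = F1),
            class = "optical_signature")
}

invalid_signature <- function(F1, channel) {
  structure(list(signature = stats::setNames(rep(NA_real_, 6),
                                             c("S2", "S3", "S4", "S2_over_S3",
                                               "S2_over_S4", "S3_over_S4")),
                 valid = FALSE, failed_channel = as.integer(channel), F1 = F1),
            class = "optical_signature")
}

#' Signature table from cumulative four-channel histograms
#'
#' Computes one optical signature per cumulative row (the oversampled
#' distributions carry enough counts per bin for stable densities). With
#' `f1_policy = "all_bins"` one signature is computed per populated
#' sizing-channel bin instead of only at the modal bin, enriching the
#' feature set.
#'
#' @param counts Rows x (4 * n_bins) matrix of cumulative counts
#'   (channel-major), e.g. from [build_cumulative_dataset()].
#' @param edges Intensity-bin edges.
#' @param species Optional row labels.
#' @param f1_policy `"modal"` or `"all_bins"`.
#' @param min_bin_count With `"all_bins"`, only bins holding at least this
#'   many counts get a signature.
#' @return data.frame with columns S2, S3, S4, S2_over_S3, S2_over_S4,
#'   S3_over_S4, species, F1, valid, row (source row index).
#' @export
signature_table <- function(counts, edges, species = NULL,
                            f1_policy = c("modal", "all_bins"),
                            min_bin_count = 20) {
  f1_policy <- match.arg(f1_policy)
  counts <- as.matrix(counts)
  n_bins <- length(edges) - 1L
  stopifnot(ncol(counts) == 4L * n_bins)
  if (is.null(species)) species <- rep(NA_character_, nrow(counts))
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    m <- matrix(counts[i, ], nrow = 4L, byrow = TRUE)
    f1s <- if (f1_policy == "modal") NA else
      edges[which(m[1L, ] >= min_bin_count)]
    sig_list <- if (f1_policy == "modal") list(optical_signature(m, edges))
                else lapply(f1s, function(f) optical_signature(m, edges, F1 = f))
    for (s in sig_list) {
      rows[[length(rows) + 1L]] <- data.frame(
        t(s$signature), species = species[i], F1 = s$F1, valid = s$valid,
        row = i)
    }
  }
  do.call(rbind, rows)
}
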