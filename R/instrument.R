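#' Power-law intensity/diameter calibration
#'
#' The sizing channel of an airflow cytometer records forward-scattered light
#' whose intensity grows as a power law of the optical diameter of the
#' particle, `F = a * d^b`. In the geometric-optics regime the scattering
#' cross-section scales with the projected area, hence the default exponent
#' `b = 2`.
#'
#' @param a Scale factor (intensity units at d = 1 micrometre). Must be > 0.
#' @param b Exponent (dimensionless). Must be > 0.
#' @return An object of class `power_law_calibration`.
#' @export
power_law_calibration <- function(a = 1, b = 2) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L, b > 0)
  structure(list(a = a, b = b), class = "power_law_calibration")
}

#' Convert optical diameter to scattered intensity
#'
#' @param d Diameter in micrometres (> 0).
#' @param calib A [power_law_calibration()].
#' @return Intensity `a * d^b`.
#' @export
diameter_to_intensity <- function(d, calib) {
  stopifnot(inherits(calib, "power_law_calibration"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("diameters must be positive and finite", call. = FALSE)
  }
  calib$a * d^calib$b
}

#' Convert scattered intensity to optical diameter
#'
#' Inverts the power-law calibration: `d = (F / a)^(1/b)`.
#'
#' @param F Scattered intensity (> 0).
#' @param calib A [power_law_calibration()].
#' @return Diameter in micrometres.
#' @export
intensity_to_diameter <- function(F, calib) {
  stopifnot(inherits(calib, "power_law_calibration"))
  if (any(!is.finite(F)) || any(F <= 0)) {
    stop("intensities must be positive and finite", call. = FALSE)
  }
  (F / calib$a)^(1 / calib$b)
}

#' Instrument configuration
#'
#' Describes the four-channel optical particle counter: one sizing channel at
#' a small scattering angle and three speciation channels at larger angles,
#' each counting particles into 19 intensity bins. The sizing channel spans
#' optical diameters from `size_range[1]` to `size_range[2]` micrometres;
#' its intensity-bin edges are the images, under the calibration, of
#' geometrically spaced diameter edges. The speciation channels reuse the
#' same intensity-bin layout so that a pure gain factor shifts counts by a
#' whole number of bins.
#'
#' @param n_bins Number of intensity bins per channel (19).
#' @param size_range Sizing span in micrometres, default `c(5, 100)`.
#' @param angles Scattering angles in degrees, one per channel.
#' @param calibration A [power_law_calibration()].
#' @param frame_period Acquisition period per frame, seconds.
#' @param flow_rate Sample flow in L/min (metadata only).
#' @return An object of class `instrument_config` with components
#'   `diameter_edges` (length `n_bins + 1`) and `bin_edges` (intensity edges,
#'   shared by all channels).
#' @export
instrument_config <- function(n_bins = 19L,
                              size_range = c(5, 100),
                              angles = c(15, 60, 125, 160),
                              calibration = power_law_calibration(),
                              frame_period = 10,
                              flow_rate = 10) {
  stopifnot(length(size_range) == 2L, size_range[1] > 0,
            size_range[2] > size_range[1],
            length(angles) == 4L, n_bins >= 1L)
  n_bins <- as.integer(n_bins)
  d_edges <- exp(seq(log(size_range[1]), log(size_range[2]),
                     length.out = n_bins + 1L))
  i_edges <- diameter_to_intensity(d_edges, calibration)
  structure(list(
    n_channels     = 4L,
    angles         = angles,
    n_bins         = n_bins,
    size_range     = size_range,
    calibration    = calibration,
    frame_period   = frame_period,
    flow_rate      = flow_rate,
    diameter_edges = d_edges,
    bin_edges      = i_edges
  ), class = "instrument_config")
}

#' Geometric centres of the size bins
#'
#' @param cfg An [instrument_config()].
#' @return Vector of length `n_bins`, micrometres.
#' @export
bin_centres <- function(cfg) {
  e <- cfg$diameter_edges
  sqrt(e[-length(e)] * e[-1])
}

#' Bin intensities into the channel histogram
#'
#' Bins are half-open `[edge_i, edge_{i+1})`; the last bin is closed at the
#' top edge. Intensities outside the range are counted in an overflow tally,
#' never silently dropped.
#'
#' @param x Intensities.
#' @param edges Strictly increasing bin edges (length `n_bins + 1`).
#' @return Integer counts of length `n_bins` with attribute `overflow`
#'   (number of intensities outside the range).
#' @export
bin_intensities <- function(x, edges) {
  stopifnot(all(diff(edges) > 0))
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  n_bins <- length(edges) - 1L
  inside <- idx >= 1L & idx <= n_bins
  counts <- tabulate(idx[inside], nbins = n_bins)
  structure(counts, overflow = sum(!inside))
}

#' Construct a measurement frame
#'
#' One frame is a single acquisition period: four count vectors of length
#' `n_bins`, one per channel, channel-major.
#'
#' @param counts 4 x n_bins matrix of non-negative counts (rows = channels),
#'   or a flat channel-major vector of length `4 * n_bins`.
#' @param timestamp Seconds since session start.
#' @param n_bins Bins per channel.
#' @return An object of class `frame`: integer matrix 4 x n_bins with a
#'   `timestamp` attribute.
#' @export
new_frame <- function(counts, timestamp = 0, n_bins = 19L) {
  if (is.matrix(counts)) {
    stopifnot(nrow(counts) == 4L)
    n_bins <- ncol(counts)
  } else {
    stopifnot(length(counts) == 4L * n_bins)
    counts <- matrix(counts, nrow = 4L, byrow = TRUE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("frame counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- paste0("ch", 1:4)
  structure(counts, timestamp = timestamp, class = "frame")
}

#' Flatten a frame to the 76-column channel-major layout
#'
#' @param frame A [new_frame()].
#' @return Numeric vector of length `4 * n_bins`.
#' @export
flatten_frame <- function(frame) {
  as.vector(t(unclass(frame)))
}

#' Size distribution from a frame
#'
#' Maps the sizing-channel counts bin-for-bin onto the diameter bins. The
#' mapping is bijective because the intensity-bin edges are the calibration
#' images of the diameter edges, so total counts are conserved.
#'
#' @param frame A [new_frame()] or a numeric vector of sizing-channel counts.
#' @param cfg An [instrument_config()].
#' @param mode `"number"` or `"volume"`.
#' @return An object of class `size_distribution`: list with `bin_edges`
#'   (micrometres), `counts`, `mode`.
#' @export
frame_to_size_distribution <- function(frame, cfg, mode = c("number", "volume")) {
  mode <- match.arg(mode)
  counts <- if (inherits(frame, "frame")) unclass(frame)[1L, ] else as.numeric(frame)
  stopifnot(length(counts) == cfg$n_bins)
  sd <- structure(list(bin_edges = cfg$diameter_edges,
                       counts = as.numeric(counts),
                       mode = "number"),
                  class = "size_distribution")
  if (mode == "volume") sd <- to_volume(sd) else sd
}

#' Convert a number size distribution to volume form
#'
#' Each bin is weighted by the sphere volume `(pi/6) d^3` at the bin's
#' geometric-centre diameter, emphasising large particles and aggregates.
#'
#' @param sd A `size_distribution` in number mode.
#' @return A `size_distribution` in volume mode.
#' @export
to_volume <- function(sd) {
  stopifnot(inherits(sd, "size_distribution"))
  if (sd$mode == "volume") return(sd)
  e <- sd$bin_edges
  centres <- sqrt(e[-length(e)] * e[-1])
  sd$counts <- sd$counts * (pi / 6) * centres^3
  sd$mode <- "volume"
  sd
}

#' Modal diameter of a size distribution
#'
#' @param sd A `size_distribution`.
#' @return The geometric-centre diameter (micrometres) of the fullest bin.
#' @export
modal_diameter <- function(sd) {
  e <- sd$bin_edges
  centres <- sqrt(e[-length(e)] * e[-1])
  centres[which.max(sd$counts)]
}
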