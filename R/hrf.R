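#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma shape (response peak near 5 s, undershoot near
#' 15 s): `dgamma(t, 6, 1) - dgamma(t, 16, 1)/6`, scaled to unit peak.
#'
#' @param t time in seconds (vector).
#' @param peak_shape,peak_rate gamma parameters of the positive lobe.
#' @param under_shape,under_rate gamma parameters of the undershoot.
#' @param under_ratio undershoot amplitude relative to the positive lobe.
#' @return HRF values at `t`, unit peak.
#' @export
canonical_hrf <- function(t, peak_shape = 6, peak_rate = 1,
                          under_shape = 16, under_rate = 1,
                          under_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = peak_rate) -
    under_ratio * stats::dgamma(t, shape = under_shape, rate = under_rate)
  h / max(stats::dgamma((peak_shape - 1) / peak_rate, shape = peak_shape,
                        rate = peak_rate))
}

#' HRF-convolved task regressor
#'
#' Builds a boxcar from the event list on a fine time grid, convolves it with
#' the canonical HRF, samples the result at the frame times, and scales to
#' unit peak (so a voxel with a k% response has regression coefficient k
#' against the percent-change signal).
#'
#' @param events event data frame (`onset`, `duration` in seconds).
#' @param n_frames number of frames.
#' @param frame_interval_s frame interval (s).
#' @param fine_dt internal convolution grid (s).
#' @param ... passed to [canonical_hrf()].
#' @return Numeric regressor of length `n_frames`, unit peak.
#' @export
hrf_regressor <- function(events, n_frames, frame_interval_s, fine_dt = 0.1, ...) {
  events <- validate_events(events)
  dur <- (n_frames - 1) * frame_interval_s
  if (any(events$onset > dur))
    stop("event onsets extend beyond the scan duration")
  tf <- seq(0, dur + 32, by = fine_dt)
  box <- numeric(length(tf))
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    off <- on + max(events$duration[i], fine_dt)  # point events span one sample
    box[tf >= on & tf < off] <- 1
  }
  h <- canonical_hrf(seq(0, 32, by = fine_dt), ...)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tf)] * fine_dt
  reg <- stats::approx(tf, conv, xout = (seq_len(n_frames) - 1) * frame_interval_s)$y
  if (max(abs(reg)) == 0) stop("regressor is identically zero")
  reg / max(reg)
}
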