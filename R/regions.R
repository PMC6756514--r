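#' Partition the vasculature by lag into inlet / center / outlet
#'
#' Thresholds the lag map under the project sign convention: inlet
#' (arterial side) = lag > +halfwidth, outlet (venous side) =
#' lag < -halfwidth, center = |lag| <= halfwidth. The three masks are
#' mutually exclusive and cover the tracked support.
#'
#' @param ls a [track_lags()] result (hole-filled or not).
#' @param center_halfwidth_s center half-width in seconds (2.5 for the
#'   +/-7 s structure; use [equal_bin_halfwidth()] for rBTT-style splits).
#' @return A `vascular_regions` list of 3D logical masks `inlet`, `center`,
#'   `outlet` plus `center_halfwidth_s`. Empty regions trigger a warning.
#' @export
partition_regions <- function(ls, center_halfwidth_s = 2.5) {
  stopifnot(inherits(ls, "lag_structure"))
  lm <- ls$lag_map
  hw <- center_halfwidth_s
  inlet <- !is.na(lm) & lm > hw
  outlet <- !is.na(lm) & lm < -hw
  center <- !is.na(lm) & abs(lm) <= hw
  for (nm in c("inlet", "center", "outlet"))
    if (sum(get(nm)) == 0) warning("region '", nm, "' is empty")
  structure(list(inlet = inlet, center = center, outlet = outlet,
                 center_halfwidth_s = hw),
            class = "vascular_regions")
}

#' Half-width giving three equal bin-count regions
#'
#' For the narrower rBTT-style regional split the center half-width is
#' chosen so inlet, center, and outlet hold (as nearly as possible) equal
#' numbers of lag bins.
#'
#' @param ls a [track_lags()] result.
#' @param range_s bin range considered.
#' @return Half-width in seconds (midway between bin lags).
#' @export
equal_bin_halfwidth <- function(ls, range_s = 4) {
  lags <- sort(ls$lags[abs(ls$lags) <= range_s + 1e-9])
  k <- floor(length(lags) / 3)
  if (k == 0) stop("too few bins for a three-way split")
  # boundary midway between the k-th outermost bin and the next one inward
  (abs(lags[k]) + abs(lags[k + 1])) / 2
}

#' Regional mean time courses
#'
#' @param vol a [ts_volume()].
#' @param regions a [partition_regions()] result.
#' @return Data frame with `time` and one column per non-empty region
#'   (unweighted voxel means); empty regions are omitted.
#' @export
regional_series <- function(vol, regions) {
  stopifnot(inherits(regions, "vascular_regions"))
  d <- dim(vol$data)
  flat <- matrix(vol$data, prod(d[1:3]), d[4])
  out <- data.frame(time = frame_times(vol))
  for (nm in c("inlet", "center", "outlet")) {
    msk <- as.vector(regions[[nm]])
    if (sum(msk) > 0)
      out[[nm]] <- colMeans(flat[msk, , drop = FALSE])
  }
  out
}

#' sLFO magnitude of a series
#'
#' The sample SD of a (band-passed, percent-signal-change) series — the
#' regional sLFO magnitude measure.
#'
#' @param series numeric series.
#' @return Sample standard deviation (0 for a constant series).
#' @export
slfo_magnitude <- function(series) stats::sd(series)

#' Phase delay between two series
#'
#' Cross-correlogram peak abscissa with parabolic sub-sample refinement;
#' positive = `a` leads `b`. The result is flagged ambiguous when a second,
#' non-adjacent correlogram peak comes within 2% of the maximum (periodic
#' signals).
#'
#' @param a,b numeric series.
#' @param frame_interval_s sampling interval (s).
#' @param max_lag_s correlogram half-range (s).
#' @param floor_r minimum acceptable peak correlation.
#' @return Delay in seconds with attribute `ambiguous` (logical).
#' @export
phase_delay <- function(a, b, frame_interval_s, max_lag_s = 7,
                        floor_r = 0.2) {
  cg <- xcorrelogram(a, b, max_lag_s, frame_interval_s)
  if (cg$peak_r < floor_r) stop("no correlogram peak above floor")
  j <- which.max(cg$r)
  delay <- cg$peak_lag
  if (j > 1 && j < length(cg$r)) {
    denom <- cg$r[j - 1] - 2 * cg$r[j] + cg$r[j + 1]
    if (denom < 0)
      delay <- delay + 0.5 * (cg$r[j - 1] - cg$r[j + 1]) / denom *
        frame_interval_s
  }
  near <- which(cg$r >= cg$peak_r * 0.98)
  ambiguous <- any(abs(near - j) > 1)
  structure(delay, ambiguous = ambiguous)
}

#' Intraclass correlation ICC(2,1) between two maps
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC over
#' voxels as "subjects" and maps as "raters", from the standard two-way
#' ANOVA mean squares:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with `MSR` the between-voxel, `MSC` the between-map, and `MSE` the
#' residual mean square (`n` voxels, `k = 2` maps). Absolute agreement
#' penalizes additive offsets between maps.
#'
#' @param map_a,map_b numeric arrays/vectors of equal length.
#' @param mask optional logical array restricting the comparison; NA voxels
#'   are excluded pairwise.
#' @return Scalar in `[-1, 1]`.
#' @export
icc_2_1 <- function(map_a, map_b, mask = NULL) {
  a <- as.vector(map_a); b <- as.vector(map_b)
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  if (!is.null(mask)) keep <- keep & as.vector(mask)
  a <- a[keep]; b <- b[keep]
  n <- length(a); k <- 2
  if (n < 3) stop("fewer than 3 common voxels")
  Y <- cbind(a, b)
  gm <- mean(Y)
  rowm <- rowMeans(Y)
  colm <- colMeans(Y)
  MSR <- k * sum((rowm - gm)^2) / (n - 1)
  MSC <- n * sum((colm - gm)^2) / (k - 1)
  MSE <- sum((Y - outer(rowm, rep(1, k)) -
                matrix(colm, n, k, byrow = TRUE) + gm)^2) /
    ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Regional sLFO summary table
#'
#' The per-dataset magnitude/phase summary consumed by group-level
#' statistics: per region, the sLFO magnitude (SD of the band-passed
#' percent-change regional series) and the phase delay relative to the
#' center region.
#'
#' @param vol a percent-change [ts_volume()] (full band).
#' @param regions a [partition_regions()] result.
#' @param band sLFO band (Hz).
#' @return Data frame with `region`, `n_voxels`, `magnitude_pct`,
#'   `phase_vs_center_s`.
#' @export
regional_summary <- function(vol, regions, band = c(0.008, 0.07)) {
  rs <- regional_series(bandpass(vol, band[1], band[2]), regions)
  nm <- setdiff(names(rs), "time")
  mag <- vapply(nm, function(r) slfo_magnitude(rs[[r]]), numeric(1))
  ph <- vapply(nm, function(r) {
    if (!"center" %in% nm) return(NA_real_)
    as.numeric(phase_delay(rs[[r]], rs$center, vol$frame_interval_s))
  }, numeric(1))
  nvox <- vapply(nm, function(r) sum(regions[[r]]), numeric(1))
  data.frame(region = nm, n_voxels = nvox, magnitude_pct = mag,
             phase_vs_center_s = ph, row.names = NULL)
}
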