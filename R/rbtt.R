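#' Adjacent lag-bin seed pairs
#'
#' Orders the tracked bins from most upstream (+range) to most downstream
#' (-range) and forms all adjacent pairs with both seed series present; with
#' a full +/-4-s structure at 0.5-s steps this yields the canonical 16 pairs.
#' The first member of each pair is the upstream (leading) bin.
#'
#' @param ls a [track_lags()] result.
#' @param range_s restrict to bins with `|lag| <= range_s`.
#' @return Data frame with `pair` (id), `lag_lead`, `lag_follow` (s); pairs
#'   with missing bins are dropped with a warning, an empty structure yields
#'   an empty list with a warning.
#' @export
neighbor_pairs <- function(ls, range_s = 4) {
  stopifnot(inherits(ls, "lag_structure"))
  lags <- sort(ls$lags[abs(ls$lags) <= range_s + 1e-9], decreasing = TRUE)
  if (length(lags) < 2) {
    warning("fewer than 2 bins within +/-", range_s, " s; no pairs")
    return(data.frame(pair = integer(0), lag_lead = numeric(0),
                      lag_follow = numeric(0)))
  }
  out <- data.frame(pair = seq_len(length(lags) - 1),
                    lag_lead = lags[-length(lags)], lag_follow = lags[-1])
  gap <- out$lag_lead - out$lag_follow
  drop <- abs(gap - ls$step_s) > 1e-9
  if (any(drop)) {
    warning(sum(drop), " non-adjacent pair(s) dropped (missing bins)")
    out <- out[!drop, , drop = FALSE]
    out$pair <- seq_len(nrow(out))
  }
  out
}

# Centered "same" convolution of x with kernel k (odd length) via FFT.
.conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  half <- (m - 1L) %/% 2L
  N <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, numeric(N - n)))
  K <- stats::fft(c(k, numeric(N - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / N
  full[half + seq_len(n)]
}

#' Instantaneous phase difference between two series
#'
#' Sliding-window estimate of the time-resolved delay by which `x` leads
#' `y`. Both series are resampled to `resample_dt`; at each output time a
#' Kaiser-tapered segment centred there is cross-correlated over a search
#' span around the nominal 0.5-s bin step, and the peak abscissa (with
#' parabolic sub-sample refinement) is the instantaneous phase difference.
#' The windowed correlation is computed for all centres at once by FFT
#' convolution. Centres whose window leaves the series, has zero variance,
#' peaks on the search boundary, or peaks below `min_r` return NA.
#'
#' @param x,y numeric series; `x` is the upstream member (leads by ~0.5 s).
#' @param frame_interval_s sampling interval of the inputs (s).
#' @param window_s sliding-window length (s).
#' @param kaiser_beta Kaiser taper shape parameter.
#' @param resample_dt output/search resolution (s).
#' @param center,halfwidth peak-search span `center +/- halfwidth` (s);
#'   the restriction prevents cycle hopping.
#' @param min_r minimum windowed correlation for a stable peak.
#' @return Data frame with `time` (s) and `phase_diff` (s, NA where
#'   unstable).
#' @export
instantaneous_phase_diff <- function(x, y, frame_interval_s,
                                     window_s = 30, kaiser_beta = 4,
                                     resample_dt = 0.02,
                                     center = 0.5, halfwidth = 0.25,
                                     min_r = 0.3) {
  n0 <- length(x)
  stopifnot(length(y) == n0)
  dur <- (n0 - 1) * frame_interval_s
  if (window_s >= dur) stop("window exceeds series duration")
  t0 <- (seq_len(n0) - 1) * frame_interval_s
  tt <- seq(0, dur, by = resample_dt)
  xs <- stats::splinefun(t0, x, method = "fmm")(tt)
  ys <- stats::splinefun(t0, y, method = "fmm")(tt)
  n <- length(tt)

  wlen <- 2L * (round(window_s / resample_dt) %/% 2L) + 1L
  k <- signal::kaiser(wlen, kaiser_beta)
  W <- sum(k)
  half <- (wlen - 1L) %/% 2L

  shifts <- seq(round((center - halfwidth) / resample_dt),
                round((center + halfwidth) / resample_dt))
  # windowed first/second moments; those of shifted x are shifts of x's
  A1 <- .conv_same(xs, k);  A2 <- .conv_same(xs^2, k)
  B1 <- .conv_same(ys, k);  B2 <- .conv_same(ys^2, k)
  vy <- B2 - B1^2 / W

  R <- matrix(NA_real_, n, length(shifts))
  for (j in seq_along(shifts)) {
    L <- shifts[j]
    # pair x delayed by L with y: x_L[i] = xs[i - L]
    xl <- c(rep(NA_real_, L), xs[seq_len(n - L)])
    prod_ <- xl * ys
    prod_[is.na(prod_)] <- 0
    C <- .conv_same(prod_, k)
    a1 <- c(rep(NA_real_, L), A1[seq_len(n - L)])
    a2 <- c(rep(NA_real_, L), A2[seq_len(n - L)])
    vx <- a2 - a1^2 / W
    den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
    R[, j] <- ifelse(is.finite(den) & den > 0, (C - a1 * B1 / W) / den,
                     NA_real_)
  }
  # valid centres: full window inside both series including the largest shift
  valid <- rep(FALSE, n)
  lo <- half + max(shifts) + 1L
  hi <- n - half
  if (lo <= hi) valid[lo:hi] <- TRUE

  pd <- rep(NA_real_, n)
  for (i in which(valid)) {
    r <- R[i, ]
    if (anyNA(r)) next
    j <- which.max(r)
    if (j == 1L || j == length(shifts) || r[j] < min_r) next
    denom <- r[j - 1] - 2 * r[j] + r[j + 1]
    delta <- if (denom < 0) 0.5 * (r[j - 1] - r[j + 1]) / denom else 0
    pd[i] <- (shifts[j] + delta) * resample_dt
  }
  data.frame(time = tt, phase_diff = pd)
}

#' Relative BOLD transit time and instantaneous velocity
#'
#' Computes the instantaneous phase difference for each adjacent seed pair,
#' averages across the requested pairs, divides by the 0.5-s tracking step to
#' obtain the rBTT, and takes the reciprocal as relative velocity. With an
#' event list, the phase-difference series is first averaged over peri-event
#' epochs (baseline = pre-event mean restored around the nominal step).
#'
#' @param ls a [track_lags()] result (tracked with `step_s = 0.5`).
#' @param pairs pair table from [neighbor_pairs()]; defaults to all pairs
#'   within `range_s`.
#' @param range_s bin range used for the default pair set.
#' @param events optional event data frame for event-locked averaging.
#' @param epoch peri-event window `c(pre, post)` in seconds.
#' @param label trace label (e.g. a region name).
#' @param ... passed to [instantaneous_phase_diff()].
#' @return An `rbtt_trace` data frame: `time` (s; peri-event time when
#'   `events` is given), `phase_diff` (s), `rbtt` (dimensionless),
#'   `velocity` (= 1/rbtt), `label`. Per-pair series are kept in
#'   `attr(, "pairs")`.
#' @export
rbtt_trace <- function(ls, pairs = NULL, range_s = 4, events = NULL,
                       epoch = c(-10, 60), label = "global", ...) {
  if (is.null(pairs)) pairs <- neighbor_pairs(ls, range_s)
  if (nrow(pairs) == 0) stop("no valid seed pairs")
  step <- ls$step_s
  per_pair <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sx <- ls$seed_series[, format(pairs$lag_lead[i])]
    sy <- ls$seed_series[, format(pairs$lag_follow[i])]
    per_pair[[i]] <- instantaneous_phase_diff(
      sx, sy, ls$frame_interval_s, center = step, ...)
  }
  tt <- per_pair[[1]]$time
  pd_mat <- sapply(per_pair, function(p) p$phase_diff)
  pd <- rowMeans(pd_mat, na.rm = TRUE)
  pd[!is.finite(pd)] <- NA_real_

  if (!is.null(events)) {
    events <- validate_events(events)
    ep <- .epoch_average(tt, pd, events$onset, epoch, baseline_to = step)
    tt <- ep$time; pd <- ep$value
  }
  out <- data.frame(time = tt, phase_diff = pd, rbtt = pd / step,
                    velocity = step / pd, label = label)
  attr(out, "pairs") <- pairs
  attr(out, "per_pair") <- pd_mat
  class(out) <- c("rbtt_trace", "data.frame")
  out
}

# Event-locked average of a series: epochs at each onset, per-epoch pre-event
# mean removed and re-anchored at `baseline_to`.
.epoch_average <- function(time, value, onsets, epoch = c(-10, 60),
                           baseline_to = 0) {
  dt <- time[2] - time[1]
  rel <- seq(epoch[1], epoch[2], by = dt)
  acc <- matrix(NA_real_, length(rel), length(onsets))
  for (e in seq_along(onsets)) {
    v <- stats::approx(time, value, xout = onsets[e] + rel)$y
    bl <- mean(v[rel < 0], na.rm = TRUE)
    if (is.finite(bl)) acc[, e] <- v - bl + baseline_to
  }
  list(time = rel, value = rowMeans(acc, na.rm = TRUE))
}
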