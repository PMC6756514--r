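#' Cross-correlogram between two series
#'
#' Normalized correlation at integer-frame shifts in
#' `[-max_lag_s, +max_lag_s]`. Sign convention (project-wide): a positive
#' `peak_lag` means `x` LEADS `y` — features of `x` occur earlier. Values are
#' signed; the peak is the signed maximum (anti-correlated series are not
#' treated as matches).
#'
#' @param x,y numeric series of equal length (>= 2 * max lag in frames).
#' @param max_lag_s maximum |lag| in seconds.
#' @param frame_interval_s sampling interval (s).
#' @return A `correlogram`: list with `lags` (s), `r`, `peak_lag`, `peak_r`,
#'   and `n_ties` (number of lags attaining the maximum).
#' @export
xcorrelogram <- function(x, y, max_lag_s, frame_interval_s) {
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  m <- round(max_lag_s / frame_interval_s)
  if (n < 2 * m + 2) stop("series too short for requested max lag")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  r <- .xcorr_mat(matrix(x, ncol = 1), y, m)[, 1]
  lags <- (-m:m) * frame_interval_s
  mx <- max(r, na.rm = TRUE)
  at <- which(r >= mx - 1e-12)
  structure(list(lags = lags, r = r, peak_lag = lags[at[1]], peak_r = mx,
                 n_ties = length(at)),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> peak r = %.3f at lag %+.3g s (%d lags)\n",
              x$peak_r, x$peak_lag, length(x$lags)))
  invisible(x)
}

# Correlation of every column of X against series s at shifts -m..m frames.
# Row L+m+1 holds c(L) = cor(x[t-L], y[t]); positive L = column leads s.
# Returns a (2m+1) x ncol(X) matrix.
.xcorr_mat <- function(X, s, m) {
  n <- nrow(X)
  out <- matrix(NA_real_, 2 * m + 1, ncol(X))
  for (L in -m:m) {
    if (L >= 0) { xi <- 1:(n - L); yi <- (1 + L):n }
    else { xi <- (1 - L):n; yi <- 1:(n + L) }
    k <- length(xi)
    Xs <- X[xi, , drop = FALSE]
    sv <- s[yi]
    sx <- colSums(Xs); sxx <- colSums(Xs^2)
    sy <- sum(sv); syy <- sum(sv^2)
    num <- colSums(Xs * sv) - sx * sy / k
    den <- sqrt(pmax(sxx - sx^2 / k, 0) * max(syy - sy^2 / k, 0))
    out[L + m + 1, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

# Per-column signed peak with uniqueness bookkeeping.
# Returns list(idx = argmax row index, r = max value, unique = logical).
.peak_info <- function(R) {
  mx <- apply(R, 2, max, na.rm = TRUE)
  idx <- max.col(t(replace(R, is.na(R), -Inf)), ties.method = "first")
  nt <- colSums(sweep(R, 2, mx - 1e-12, ">="), na.rm = TRUE)
  list(idx = idx, r = mx, unique = nt == 1L)
}

#' Initial lag-zero seed
#'
#' Selects the voxels whose cross-correlogram against the global mean signal
#' peaks at lag 0 with peak correlation at or above `corr_threshold`; their
#' mean time course defines the reference phase (lag = 0).
#'
#' @param vol a band-passed [ts_volume()].
#' @param corr_threshold minimum peak correlation.
#' @param max_search_s correlogram half-range for peak finding (s).
#' @return List with `voxels` (indices into the in-mask voxel matrix) and
#'   `reference` (their mean series).
#' @export
initial_seed <- function(vol, corr_threshold = 0.3, max_search_s = 7) {
  X <- vox_matrix(vol)
  gs <- rowMeans(X)
  m <- round(max_search_s / vol$frame_interval_s)
  ok <- apply(X, 2, stats::sd) > 0
  R <- matrix(NA_real_, 2 * m + 1, ncol(X))
  R[, ok] <- .xcorr_mat(X[, ok, drop = FALSE], gs, m)
  pk <- .peak_info(R)
  sel <- which(ok & pk$idx == m + 1 & pk$unique & pk$r >= corr_threshold)
  if (length(sel) == 0)
    stop("initial seed is empty: no voxel peaks at lag 0 with r >= ",
         corr_threshold)
  list(voxels = sel, reference = rowMeans(X[, sel, drop = FALSE]))
}

#' Recursive lag tracking
#'
#' Builds the lag structure: starting from the lag-zero seed, the recursion
#' proceeds independently upstream and downstream. At each step, every
#' still-undetermined voxel whose correlogram against the previous seed's
#' mean series peaks at exactly +step (upstream) or -step (downstream) with
#' peak r at or above `corr_threshold` is assigned the next lag, and the mean
#' series of the newly assigned voxels becomes the new seed. A direction
#' stops at `range_s` or when a step yields no voxels. Voxels are never
#' reassigned; a voxel whose correlogram peak ties between lags is left
#' for the hole-filling passes.
#'
#' Positive lag = the voxel leads the global phase (arterial/"upstream").
#'
#' @param vol a band-passed [ts_volume()] (band upper edge must keep the
#'   phase unique within the correlogram range).
#' @param corr_threshold minimum peak correlation (paper default 0.3).
#' @param step_s tracking step in seconds.
#' @param range_s maximum |lag| tracked (7 s for lag maps; 4 s for rBTT runs).
#' @param max_search_s correlogram half-range for peak finding; defaults to
#'   `range_s`.
#' @return A `lag_structure`: `lag_map` (3D, seconds, NA where untracked),
#'   `lags` (bin lags, descending), `seed_series` (frames x bins matrix),
#'   `bins` (voxel-index list per bin), plus the parameters used.
#' @export
track_lags <- function(vol, corr_threshold = 0.3, step_s = 0.5, range_s = 7,
                       max_search_s = range_s) {
  dt <- vol$frame_interval_s
  step_f <- round(step_s / dt)
  if (abs(step_f * dt - step_s) > 1e-9)
    stop("step_s must be an integer multiple of the frame interval; ",
         "resample the data first")
  m <- round(max_search_s / dt)
  X <- vox_matrix(vol)
  nv <- ncol(X)
  lag_vox <- rep(NA_real_, nv)
  variant <- apply(X, 2, stats::sd) > 0

  seed0 <- initial_seed(vol, corr_threshold, max_search_s)
  lag_vox[seed0$voxels] <- 0
  series <- list("0" = rowMeans(X[, seed0$voxels, drop = FALSE]))

  run_direction <- function(dir) {
    seed <- series[["0"]]
    lag <- 0
    repeat {
      lag_next <- lag + dir * step_s
      if (abs(lag_next) > range_s + 1e-9) break
      und <- which(is.na(lag_vox) & variant)
      if (length(und) == 0) break
      R <- .xcorr_mat(X[, und, drop = FALSE], seed, m)
      pk <- .peak_info(R)
      target <- m + 1 + dir * step_f
      pick <- und[pk$idx == target & pk$unique & pk$r >= corr_threshold]
      if (length(pick) == 0) break
      lag_vox[pick] <<- lag_next
      seed <- rowMeans(X[, pick, drop = FALSE])
      series[[format(lag_next)]] <<- seed
      lag <- lag_next
    }
  }
  run_direction(+1)
  run_direction(-1)

  lags <- sort(as.numeric(names(series)), decreasing = TRUE)
  keys <- vapply(lags, format, character(1))
  seed_series <- vapply(keys, function(k) series[[k]],
                        numeric(length(series[[1]])))
  colnames(seed_series) <- keys
  bins <- lapply(lags, function(l) which(!is.na(lag_vox) &
                                           abs(lag_vox - l) < 1e-9))
  names(bins) <- keys

  lag_map <- array(NA_real_, dim(vol$data)[1:3])
  lag_map[vol$mask] <- lag_vox
  structure(list(lag_map = lag_map, lags = lags, seed_series = seed_series,
                 bins = bins, step_s = step_s, range_s = range_s,
                 corr_threshold = corr_threshold, max_search_s = max_search_s,
                 mask = vol$mask, frame_interval_s = dt,
                 fill = array(NA_integer_, dim(vol$data)[1:3])),
            class = "lag_structure")
}

#' @export
print.lag_structure <- function(x, ...) {
  cat(sprintf("<lag_structure> %d bins, lags %+.3g .. %+.3g s (step %.3g s)\n",
              length(x$lags), max(x$lags), min(x$lags), x$step_s))
  cat(sprintf("  tracked %d / %d masked voxels (r >= %.2g)\n",
              sum(!is.na(x$lag_map[x$mask])), sum(x$mask), x$corr_threshold))
  invisible(x)
}

#' Fill untracked voxels of a lag map
#'
#' Two passes. Pass 1: each untracked voxel, one at a time, receives the
#' correlation-weighted mean lag of the lag-bearing voxels with a *similar
#' time course*: correlation above `corr_threshold` at zero shift, and not
#' exceeded at a one-frame shift in either direction (so only in-phase
#' voxels contribute — sLFO-band signals correlate appreciably across lags,
#' and unrestricted averaging would drag estimates toward the global mean
#' lag). Lags live on a bounded linear axis, so a weighted linear mean
#' stands in for circular phase averaging; voxels filled earlier in the pass
#' are available as sources. Pass 2: any remaining voxel whose 6
#' face-neighbours all have lags receives their mean. Voxels still
#' unresolved stay NA.
#'
#' @param ls a [track_lags()] result.
#' @param vol the same band-passed volume the structure was tracked on.
#' @param corr_threshold minimum source correlation for pass 1.
#' @return The `lag_structure` with `lag_map` filled; `fill` records the
#'   pass that resolved each voxel (0 = tracked, 1, 2).
#' @export
fill_holes <- function(ls, vol, corr_threshold = 0.3) {
  stopifnot(inherits(ls, "lag_structure"))
  X <- vox_matrix(vol)
  n <- nrow(X)
  lag_vox <- ls$lag_map[ls$mask]
  fill <- ifelse(is.na(lag_vox), NA_integer_, 0L)
  sdv <- apply(X, 2, stats::sd)
  Z <- sweep(X, 2, colMeans(X), "-")
  Z <- sweep(Z, 2, ifelse(sdv > 0, sdv, 1), "/")

  holes <- which(is.na(lag_vox))
  for (i in holes) {
    if (sdv[i] == 0) next
    src <- which(!is.na(lag_vox))
    Zs <- Z[, src, drop = FALSE]
    r0 <- as.vector(crossprod(Z[, i], Zs)) / (n - 1)
    # in-phase check: correlation must not improve at a one-frame shift
    rp <- as.vector(crossprod(Z[-1, i], Zs[-n, ])) / (n - 2)
    rm <- as.vector(crossprod(Z[-n, i], Zs[-1, ])) / (n - 2)
    use <- r0 > corr_threshold & r0 >= rp & r0 >= rm
    if (any(use)) {
      lag_vox[i] <- sum(r0[use] * lag_vox[src[use]]) / sum(r0[use])
      fill[i] <- 1L
    }
  }

  d <- dim(ls$lag_map)
  map <- array(NA_real_, d)
  map[ls$mask] <- lag_vox
  fill_map <- array(NA_integer_, d)
  fill_map[ls$mask] <- fill

  remaining <- which(ls$mask & is.na(map), arr.ind = TRUE)
  base <- map   # pass 2 reads pre-pass-2 values only ("single isolated holes")
  for (k in seq_len(nrow(remaining))) {
    v <- remaining[k, ]
    if (any(v == 1L) || any(v == d)) next   # needs all 6 face neighbours
    nb <- c(base[v[1] - 1, v[2], v[3]], base[v[1] + 1, v[2], v[3]],
            base[v[1], v[2] - 1, v[3]], base[v[1], v[2] + 1, v[3]],
            base[v[1], v[2], v[3] - 1], base[v[1], v[2], v[3] + 1])
    if (all(!is.na(nb))) {
      map[v[1], v[2], v[3]] <- mean(nb)
      fill_map[v[1], v[2], v[3]] <- 2L
    }
  }
  ls$lag_map <- map
  ls$fill <- fill_map
  ls
}
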