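#' Global signal regression
#'
#' Regresses the brain-mean time course (optionally band-limited to the sLFO
#' band, `lowpass_only`) out of every voxel with an intercept; voxel means
#' are preserved.
#'
#' @param vol a [ts_volume()].
#' @param lowpass_only regress only the sLFO-band component of the global
#'   signal (so frequencies outside the band are untouched).
#' @param band band used when `lowpass_only = TRUE` (Hz).
#' @return The cleaned `ts_volume`.
#' @export
gsr <- function(vol, lowpass_only = FALSE, band = c(0.008, 0.07)) {
  g <- global_signal(vol)
  if (lowpass_only)
    g <- bandpass(g, band[1], band[2], frame_interval_s = vol$frame_interval_s)
  .regress_series_out(vol, g)
}

# Remove the per-voxel OLS fit of one centred regressor (means preserved).
.regress_series_out <- function(vol, s) {
  sc <- s - mean(s)
  v <- sum(sc^2)
  if (v == 0) return(vol)
  M <- vox_matrix(vol)
  beta <- as.vector(crossprod(M, sc)) / v
  set_vox_matrix(vol, M - outer(sc, beta))
}

#' Global scaling
#'
#' Divides each frame by its own global mean instead of the constant session
#' mean, then rescales to the session grand mean. Removes spatially uniform
#' multiplicative fluctuations exactly (where GSR removes additive ones).
#'
#' @param vol a [ts_volume()]; frame-wise global means must be positive.
#' @return The scaled `ts_volume`.
#' @export
global_scaling <- function(vol) {
  g <- global_signal(vol)
  if (any(g <= 0)) stop("global_scaling: non-positive frame mean")
  M <- vox_matrix(vol)
  set_vox_matrix(vol, sweep(M, 1, mean(g) / g, "*"))
}

#' Remove the lag structure ("deperfusioning", dynamic GSR)
#'
#' For every voxel in lag bin b, the bin-b seed series is regressed out
#' (with intercept). The seed series are band-limited by construction (they
#' come from the band-passed tracking input), so only the sLFO band is
#' affected; the fitted low-frequency component is subtracted from the
#' full-band voxel series. Voxels with a lag but no bin membership (hole
#' fills) use the seed of the nearest bin; voxels without any lag fall back
#' to low-pass GSR. Both counts are reported via a message.
#'
#' @param vol a [ts_volume()] (full-band; typically percent change).
#' @param ls a [track_lags()] (optionally [fill_holes()]-completed)
#'   lag structure computed from the band-passed version of the same data.
#' @param band sLFO band for the GSR fallback (Hz).
#' @return The cleaned `ts_volume`.
#' @export
deperfusion <- function(vol, ls, band = c(0.008, 0.07)) {
  stopifnot(inherits(ls, "lag_structure"))
  if (!identical(dim(ls$lag_map), dim(vol$data)[1:3]))
    stop("lag structure geometry does not match the volume")
  M <- vox_matrix(vol)
  lag_vox <- ls$lag_map[vol$mask]
  member <- rep(NA_integer_, ncol(M))
  for (b in seq_along(ls$lags)) member[ls$bins[[b]]] <- b

  # hole-filled voxels: nearest bin by lag value
  nearest <- !is.na(lag_vox) & is.na(member)
  if (any(nearest)) {
    bi <- vapply(lag_vox[nearest],
                 function(l) which.min(abs(ls$lags - l)), integer(1))
    member[nearest] <- bi
  }
  for (b in seq_along(ls$lags)) {
    vox <- which(member == b)
    if (length(vox) == 0) next
    s <- ls$seed_series[, b] - mean(ls$seed_series[, b])
    v <- sum(s^2)
    if (v == 0) next
    beta <- as.vector(crossprod(M[, vox, drop = FALSE], s)) / v
    M[, vox] <- M[, vox, drop = FALSE] - outer(s, beta)
  }
  out <- set_vox_matrix(vol, M)
  orphan <- which(is.na(member))
  if (length(orphan) > 0) {
    g <- bandpass(global_signal(vol), band[1], band[2],
                  frame_interval_s = vol$frame_interval_s)
    gc <- g - mean(g)
    v <- sum(gc^2)
    if (v > 0) {
      beta <- as.vector(crossprod(M[, orphan, drop = FALSE], gc)) / v
      M[, orphan] <- M[, orphan, drop = FALSE] - outer(gc, beta)
      out <- set_vox_matrix(vol, M)
    }
  }
  message(sprintf(
    "deperfusion: %d binned, %d nearest-bin (hole-filled), %d GSR-fallback voxels",
    sum(!is.na(member)) - sum(nearest), sum(nearest), length(orphan)))
  out
}

#' Single-run event-related GLM
#'
#' Ordinary least squares fit, per voxel, of the HRF-convolved task
#' regressor plus an intercept and a linear drift term.
#'
#' @param vol a [ts_volume()].
#' @param events event data frame (`onset`, `duration` in seconds).
#' @param drift include a linear drift column.
#' @param ... passed to [hrf_regressor()].
#' @return A `glm_result`: 3D `beta` and `tstat` maps for the task regressor,
#'   3D `sigma2` residual-variance map, residual `df`, and the design matrix.
#' @export
fit_glm <- function(vol, events, drift = TRUE, ...) {
  events <- validate_events(events)
  if (nrow(events) == 0) stop("event list is empty")
  nt <- n_frames(vol)
  reg <- hrf_regressor(events, nt, vol$frame_interval_s, ...)
  X <- cbind(intercept = 1,
             if (drift) seq_len(nt) / nt - 0.5 else NULL,
             task = reg)
  colnames(X)[ncol(X)] <- "task"
  qx <- qr(X)
  M <- vox_matrix(vol)
  coef <- qr.coef(qx, M)
  res <- qr.resid(qx, M)
  df <- nt - qx$rank
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtxinv[ncol(X), ncol(X)])
  beta <- coef[ncol(X), ]
  d3 <- dim(vol$data)[1:3]
  to_map <- function(v) { a <- array(NA_real_, d3); a[vol$mask] <- v; a }
  structure(list(beta = to_map(beta),
                 tstat = to_map(ifelse(se > 0, beta / se, NA_real_)),
                 sigma2 = to_map(sigma2), df = df, design = X,
                 regressor = reg, mask = vol$mask),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d voxels, df = %d, mean beta = %.4g\n",
              sum(x$mask), x$df, mean(x$beta[x$mask], na.rm = TRUE)))
  invisible(x)
}

#' sLFO-band variance per voxel
#'
#' Convenience measure used to score cleaning methods: the temporal variance
#' of the band-passed voxel series.
#'
#' @param vol a [ts_volume()].
#' @param band band edges (Hz).
#' @return Numeric vector, one variance per in-mask voxel.
#' @export
band_variance <- function(vol, band = c(0.008, 0.07)) {
  M <- vox_matrix(bandpass(vol, band[1], band[2]))
  colSums(sweep(M, 2, colMeans(M), "-")^2) / (nrow(M) - 1)
}
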