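# Shared fixtures: small, fast synthetic datasets built in code.

small_spec <- function(..., grid = c(10, 10, 4), n_frames = 480,
                       noise_sd_pct = 0, s0_amp_pct = 0, rng_seed = 42) {
  synth_spec(grid = grid, n_frames = n_frames, noise_sd_pct = noise_sd_pct,
             s0_amp_pct = s0_amp_pct, rng_seed = rng_seed, ...)
}

# percent-change + band-pass, the standard lag-mapping input
prep_bp <- function(vol, band = c(0.008, 0.07)) {
  bandpass(percent_change(vol), band[1], band[2])
}

# a ts_volume directly from a frames x voxels matrix (1 x V x 1 grid)
vol_from_matrix <- function(M, dt = 0.5) {
  ts_volume(array(t(M), c(ncol(M), 1, 1, nrow(M))), dt,
            mask = array(TRUE, c(ncol(M), 1, 1)))
}

# fabricate a lag structure straight from generator truth: seed series are
# the true bin waveforms; used to test rBTT/regions independently of tracking
truth_lag_structure <- function(sim, range_s = 4, step_s = 0.5) {
  tt <- frame_times(sim$volume)
  lags <- seq(range_s, -range_s, by = -step_s)
  keys <- vapply(lags, format, character(1))
  vr <- sim$truth$vrel
  S <- sapply(lags, function(l) sim$truth$w_fun(tt + l / vr))
  colnames(S) <- keys
  tau <- sim$truth$delay_field
  lag_map <- array(NA_real_, dim(tau))
  lag_map[] <- round(tau / step_s) * step_s
  lag_map[abs(lag_map) > range_s] <- NA
  bins <- lapply(lags, function(l)
    which(abs(lag_map[sim$volume$mask] - l) < 1e-9))
  names(bins) <- keys
  structure(list(lag_map = lag_map, lags = lags, seed_series = S,
                 bins = bins, step_s = step_s, range_s = range_s,
                 corr_threshold = NA_real_, max_search_s = range_s,
                 mask = sim$volume$mask,
                 frame_interval_s = sim$volume$frame_interval_s,
                 fill = array(NA_integer_, dim(tau))),
            class = "lag_structure")
}
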