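#' Band-limited sLFO waveform
#'
#' Generates a zero-mean, unit-variance random waveform whose spectral power
#' lies (almost) entirely inside the requested band, by band-pass filtering
#' Gaussian white noise with the package's zero-phase spectral filter.
#'
#' @param n_frames number of samples.
#' @param frame_interval_s sampling interval (s).
#' @param band_lo,band_hi band edges in Hz (`0 < band_lo < band_hi <` Nyquist).
#' @param seed optional RNG seed for reproducibility.
#' @param taper_frac fractional width of the spectral transition bands.
#' @return Numeric waveform of length `n_frames`, zero mean, unit variance.
#' @details The waveform is synthesized directly in the frequency domain
#'   (random phases on the in-band Fourier grid with raised-cosine edges), so
#'   the periodogram is exactly zero outside the tapered band — no filter
#'   leakage.
#' @export
make_slfo <- function(n_frames, frame_interval_s,
                      band_lo = 0.008, band_hi = 0.07, seed = NULL,
                      taper_frac = 0.05) {
  if (band_lo <= 0) stop("band_lo must be positive")
  .check_band(band_lo, band_hi, frame_interval_s)
  if (!is.null(seed)) set.seed(seed)
  n <- n_frames
  f <- (seq_len(n) - 1) / (n * frame_interval_s)
  f <- pmin(f, 1 / frame_interval_s - f)
  g <- .band_gain(f, band_lo, band_hi, taper_frac)
  ph <- stats::rnorm(n) + 1i * stats::rnorm(n)
  X <- g * ph
  # enforce conjugate symmetry so the inverse transform is real
  half <- seq(2, ceiling(n / 2))
  X[n + 2 - half] <- Conj(X[half])
  X[1] <- 0
  if (n %% 2 == 0) X[n / 2 + 1] <- Re(X[n / 2 + 1])
  w <- Re(stats::fft(X, inverse = TRUE)) / n
  w <- w - mean(w)
  w / stats::sd(w)
}

#' Synthetic dataset specification
#'
#' Declares the ground-truth structure of a synthetic 4D BOLD dataset: a
#' common band-limited sLFO arriving at each voxel with a voxel-specific
#' delay (positive delay = the voxel leads the global phase = arterial side,
#' the project-wide sign convention), slow multiplicative velocity modulation
#' of that delay field, HRF-convolved task responses in an active region,
#' independent S0 and T2* fluctuation channels for dual-echo synthesis,
#' Gaussian thermal noise, and injected single-frame motion/intensity spikes.
#'
#' Defaults are the package's reference study conditions: a 20 x 20 x 10 grid
#' at TR 0.5 s for 1080 frames, an axial delay gradient spanning +4 ... -4 s
#' (artery-to-vein ordering), sLFO amplitude 2% of baseline in the
#' 0.008-0.07 Hz band, NVC amplitude 1%, thermal noise 0.5%, baseline
#' T2* 40 ms read out at TE 35 ms, and a 0.5% respiration-locked S0 channel
#' at 0.2 Hz with an anterior/posterior sign flip.
#'
#' @param grid spatial dimensions (3-vector).
#' @param frame_interval_s frame interval (s).
#' @param n_frames number of frames.
#' @param delay_field 3D array of voxel delays tau(v) in seconds, or NULL for
#'   the default linear gradient `+delay_range_s .. -delay_range_s` along the
#'   first axis.
#' @param delay_range_s half-range of the default gradient field (s).
#' @param band sLFO band (Hz, length 2).
#' @param slfo_amp_pct sLFO amplitude in percent of baseline; scalar or a 3D
#'   array for spatially varying amplitude.
#' @param vrel relative-velocity profile: a function of time (s) returning
#'   values > 0 with baseline 1, or NULL for constant 1. Delays scale
#'   quasi-statically as `tau / vrel(t)`.
#' @param vrel_mask optional 3D logical array restricting the velocity
#'   modulation to a subset of voxels (e.g. the inlet); others keep vrel = 1.
#' @param active_mask 3D logical array of task-responsive voxels, or NULL for
#'   a central box when `nvc_amp_pct > 0`.
#' @param nvc_amp_pct peak task-response amplitude in percent of baseline.
#' @param events event data frame (`onset`, `duration`), or NULL for a
#'   default sparse event schedule when `nvc_amp_pct > 0`.
#' @param slfo_nvc_corr target correlation between the sLFO waveform and the
#'   HRF-convolved task regressor (the mechanism behind spurious
#'   deactivations under uniform GSR); 0 keeps them independent.
#' @param s0_amp_pct amplitude of the S0 (non-BOLD) channel, percent.
#' @param s0_freq_hz frequency of the respiration-locked S0 waveform.
#' @param t2s0_ms baseline T2* (ms).
#' @param te_ms readout echo time for single-echo synthesis (ms).
#' @param te1_ms,te2_ms echo times for dual-echo synthesis (ms); both set
#'   implies `dual_echo = TRUE`.
#' @param dual_echo synthesize a two-echo pair instead of one volume.
#' @param baseline S0 baseline signal level (arbitrary units).
#' @param noise_sd_pct thermal noise SD in percent of the baseline signal.
#' @param spike_frames integer frame indices receiving a transient global
#'   intensity deflection and a motion spike.
#' @param spike_pct global intensity deflection at spike frames (percent).
#' @param spike_motion_mm translation excursion at spike frames (mm).
#' @param rng_seed RNG seed; the realization is a pure function of the spec.
#' @return A `synth_spec` object for [simulate_bold()].
#' @export
synth_spec <- function(grid = c(20, 20, 10), frame_interval_s = 0.5,
                       n_frames = 1080, delay_field = NULL, delay_range_s = 4,
                       band = c(0.008, 0.07), slfo_amp_pct = 2,
                       vrel = NULL, vrel_mask = NULL,
                       active_mask = NULL, nvc_amp_pct = 0, events = NULL,
                       slfo_nvc_corr = 0,
                       s0_amp_pct = 0.5, s0_freq_hz = 0.2,
                       t2s0_ms = 40, te_ms = 35,
                       te1_ms = NULL, te2_ms = NULL, dual_echo = FALSE,
                       baseline = 1000, noise_sd_pct = 0.5,
                       spike_frames = integer(0), spike_pct = 2,
                       spike_motion_mm = 1.5, rng_seed = 1) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 1), n_frames >= 2,
            frame_interval_s > 0)
  if (is.null(delay_field)) {
    # smooth axial gradient (artery-to-vein ordering) with a small oblique
    # secondary gradient: vascular territories are not planar, and the
    # obliquity gives each 0.5-s lag bin a continuous spread of delays
    # instead of degenerate single-valued plates
    obl <- min(0.25, delay_range_s / 2)
    ax <- seq(delay_range_s - obl, -(delay_range_s - obl),
              length.out = grid[1])
    cx <- if (grid[2] > 1) seq(obl, -obl, length.out = grid[2]) else 0
    delay_field <- array(outer(ax, cx, "+"), grid)
  }
  stopifnot(identical(dim(delay_field), grid), all(is.finite(delay_field)))
  if (!is.null(te1_ms) && !is.null(te2_ms)) dual_echo <- TRUE
  if (dual_echo) {
    if (is.null(te1_ms)) te1_ms <- 11.2
    if (is.null(te2_ms)) te2_ms <- 32.78
    stopifnot(te1_ms > 0, te1_ms < te2_ms)
  }
  if (nvc_amp_pct > 0) {
    if (is.null(events)) {
      dur <- (n_frames - 1) * frame_interval_s
      on <- seq(20, max(21, dur - 40), by = 40)
      events <- data.frame(onset = on, duration = 0.5, label = "task")
    }
    if (is.null(active_mask)) {
      active_mask <- array(FALSE, grid)
      ctr <- pmax(1, round(grid / 2))
      sel <- lapply(seq_len(3), function(k)
        max(1, ctr[k] - 1):min(grid[k], ctr[k] + 1))
      active_mask[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
    }
  }
  if (!is.null(events)) events <- validate_events(events)
  if (is.array(slfo_amp_pct)) stopifnot(identical(dim(slfo_amp_pct), grid))
  stopifnot(all(slfo_amp_pct >= 0), nvc_amp_pct >= 0, s0_amp_pct >= 0,
            noise_sd_pct >= 0)
  spike_frames <- sort(unique(as.integer(spike_frames)))
  stopifnot(all(spike_frames >= 2 & spike_frames <= n_frames))
  structure(list(
    grid = grid, frame_interval_s = frame_interval_s, n_frames = n_frames,
    delay_field = delay_field, band = band, slfo_amp_pct = slfo_amp_pct,
    vrel = vrel, vrel_mask = vrel_mask,
    active_mask = active_mask, nvc_amp_pct = nvc_amp_pct, events = events,
    slfo_nvc_corr = slfo_nvc_corr,
    s0_amp_pct = s0_amp_pct, s0_freq_hz = s0_freq_hz,
    t2s0_ms = t2s0_ms, te_ms = te_ms, te1_ms = te1_ms, te2_ms = te2_ms,
    dual_echo = dual_echo, baseline = baseline, noise_sd_pct = noise_sd_pct,
    spike_frames = spike_frames, spike_pct = spike_pct,
    spike_motion_mm = spike_motion_mm, rng_seed = as.integer(rng_seed)),
    class = "synth_spec")
}

# Fine-grid band-limited waveform spanning [t0, t1]; returns times + values.
.slfo_fine <- function(t0, t1, dt, band) {
  n <- ceiling((t1 - t0) / dt) + 1
  w <- bandpass(stats::rnorm(n), band[1], band[2], frame_interval_s = dt)
  w <- w - mean(w)
  list(t = t0 + (seq_len(n) - 1) * dt, w = w / stats::sd(w))
}

#' Simulate a synthetic BOLD dataset with ground truth
#'
#' Realizes a [synth_spec()]: each voxel's signal is
#' `S0(v,t) * exp(-TE / T2*(v,t))`, where `1/T2*` carries the advected sLFO
#' term `a * w(t + tau_v / vrel(t))` (positive delay leads, per the project
#' sign convention) plus the HRF-convolved task response in the active
#' region, `S0` carries the respiration-locked non-BOLD channel, thermal
#' noise is added, and spike frames receive a global intensity deflection
#' plus a >1 mm entry in the emitted motion table. The returned `truth`
#' records every channel for downstream scoring.
#'
#' @param spec a [synth_spec()].
#' @return A list of class `synth_data` with elements `volume` (a
#'   [ts_volume()]; for dual-echo specs `me`, a [me_pair()], plus `volume`
#'   pointing at the second echo), `motion` (frame-wise rigid-body table),
#'   `events`, `truth` (ground-truth ledger) and `spec`.
#' @export
simulate_bold <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$rng_seed)
  g <- spec$grid; nt <- spec$n_frames; dt <- spec$frame_interval_s
  nv <- prod(g)
  t_f <- (seq_len(nt) - 1) * dt
  tau <- as.vector(spec$delay_field)

  vrel_t <- if (is.null(spec$vrel)) rep(1, nt) else spec$vrel(t_f)
  if (any(vrel_t <= 0)) stop("vrel(t) must be positive")
  pad <- max(abs(tau)) / min(min(vrel_t), 1) + 5
  fine <- .slfo_fine(-pad, max(t_f) + pad, 0.1, spec$band)

  # Task regressor (and optional tilt of the sLFO toward it).
  reg <- NULL
  if (!is.null(spec$events) && spec$nvc_amp_pct > 0) {
    reg <- hrf_regressor(spec$events, nt, dt)
    # set the sLFO/NVC-regressor correlation by construction: project the
    # band-limited regressor out of the waveform, then mix the target
    # correlation back in (rho = 0 gives exactly orthogonal channels)
    rho <- spec$slfo_nvc_corr
    nh <- numeric(length(fine$t))
    inside <- fine$t >= 0 & fine$t <= max(t_f)
    nh[inside] <- stats::approx(t_f, reg, xout = fine$t[inside])$y
    nh <- bandpass(nh, spec$band[1], spec$band[2], frame_interval_s = 0.1)
    nh <- (nh - mean(nh)) / stats::sd(nh)
    w <- fine$w
    w_perp <- w - sum(w * nh) / sum(nh * nh) * nh
    w_perp <- w_perp / stats::sd(w_perp)
    fine$w <- sqrt(1 - rho^2) * w_perp + rho * nh
    fine$w <- (fine$w - mean(fine$w)) / stats::sd(fine$w)
  }
  wfun <- stats::splinefun(fine$t, fine$w, method = "fmm")

  # Advected sLFO: delay scales quasi-statically with 1/vrel where modulated.
  vmask <- if (is.null(spec$vrel_mask)) rep(TRUE, nv) else as.vector(spec$vrel_mask)
  arg <- matrix(t_f, nt, nv) +
    outer(rep(1, nt), tau) / ifelse(matrix(vmask, nt, nv, byrow = TRUE),
                                    matrix(vrel_t, nt, nv), 1)
  amp <- if (is.array(spec$slfo_amp_pct)) as.vector(spec$slfo_amp_pct) else
    rep(spec$slfo_amp_pct, nv)
  b <- wfun(arg) * matrix(amp / 100, nt, nv, byrow = TRUE)
  if (!is.null(reg)) {
    act <- as.vector(spec$active_mask)
    b <- b + outer(reg, ifelse(act, spec$nvc_amp_pct / 100, 0))
  }

  # Decay fields: 1/T2* modulated so the fractional signal change at the
  # readout TE equals b; S0 carries the non-BOLD channel.
  te_ref <- if (spec$dual_echo) spec$te2_ms else spec$te_ms
  r2s <- 1 / spec$t2s0_ms - b / te_ref
  s0wave <- sin(2 * pi * spec$s0_freq_hz * t_f)
  signv <- rep(ifelse(seq_len(g[2]) <= g[2] / 2, 1, -1), each = g[1])
  signv <- rep(signv, g[3])
  S0 <- spec$baseline * (1 + (spec$s0_amp_pct / 100) * outer(s0wave, signv))

  synth_echo <- function(te) {
    y <- S0 * exp(-te * r2s)
    if (spec$noise_sd_pct > 0) {
      lvl <- spec$baseline * exp(-te / spec$t2s0_ms)
      y <- y + stats::rnorm(length(y), sd = spec$noise_sd_pct / 100 * lvl)
    }
    if (length(spec$spike_frames)) {
      y[spec$spike_frames, ] <- y[spec$spike_frames, , drop = FALSE] *
        (1 + spec$spike_pct / 100)
    }
    ts_volume(array(t(y), c(g, nt)), dt, mask = array(TRUE, g))
  }

  # Motion table: tiny background tremor plus transient spike excursions.
  steps <- matrix(stats::rnorm(nt * 6, sd = 0.002), nt, 6)
  steps[1, ] <- 0
  motion <- as.data.frame(apply(steps, 2, cumsum))
  names(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (length(spec$spike_frames))
    motion$tx[spec$spike_frames] <- motion$tx[spec$spike_frames] +
      spec$spike_motion_mm

  truth <- list(w = wfun(t_f), w_fun = wfun, delay_field = spec$delay_field,
                vrel = vrel_t, vrel_mask = spec$vrel_mask,
                active_mask = spec$active_mask, nvc_beta = spec$nvc_amp_pct,
                regressor = reg, slfo_amp_pct = spec$slfo_amp_pct,
                s0_series = s0wave, s0_sign = array(signv, g),
                t2s0_ms = spec$t2s0_ms, spike_frames = spec$spike_frames)

  out <- list(motion = motion, events = spec$events, truth = truth, spec = spec)
  if (spec$dual_echo) {
    out$me <- me_pair(synth_echo(spec$te1_ms), synth_echo(spec$te2_ms),
                      spec$te1_ms, spec$te2_ms)
    out$volume <- out$me$S2
  } else {
    out$volume <- synth_echo(spec$te_ms)
  }
  class(out) <- "synth_data"
  out
}

#' @export
print.synth_data <- function(x, ...) {
  cat("<synth_data>\n")
  print(x$volume)
  cat(sprintf("  delay field: %+.2f .. %+.2f s; sLFO %s%%; noise %.2g%%\n",
              max(x$truth$delay_field), min(x$truth$delay_field),
              paste(range(x$truth$slfo_amp_pct), collapse = ".."),
              x$spec$noise_sd_pct))
  invisible(x)
}
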