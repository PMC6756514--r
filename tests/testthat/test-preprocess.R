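make_const_vol <- function(value = 100, nv = 8, nt = 50) {
  ts_volume(array(value, c(nv, 1, 1, nt)), 0.5, mask = array(TRUE, c(nv, 1, 1)))
}

test_that("detect_spikes flags nothing on clean data, exactly the injected spikes otherwise", {
  vol <- make_const_vol()
  motion <- as.data.frame(matrix(0, 50, 6))
  expect_equal(nrow(detect_spikes(vol, motion)), 0)

  spec <- small_spec(grid = c(6, 6, 3), n_frames = 240, noise_sd_pct = 0.2,
                     spike_frames = c(40, 41, 150))
  sim <- simulate_bold(spec)
  rep <- detect_spikes(sim$volume, sim$motion)
  expect_identical(rep$frame, c(40L, 41L, 150L))
  expect_true(all(rep$global_change))
  expect_true(all(rep$displacement))
})

test_that("sub-threshold excursions are not flagged; criteria reported separately", {
  # 0.9% global jump at frame 10 and a 0.5 mm translation step: below both rules
  M <- matrix(100, 30, 4)
  M[10, ] <- 100.9
  vol <- vol_from_matrix(M)
  motion <- as.data.frame(matrix(0, 30, 6))
  motion[10, 1] <- 0.5
  expect_equal(nrow(detect_spikes(vol, motion)), 0)
  # 1.5% jump with no motion: only the global criterion fires
  M[10, ] <- 101.5
  rep <- detect_spikes(vol_from_matrix(M), motion)
  expect_identical(rep$frame, 10L)
  expect_true(rep$global_change)
  expect_false(rep$displacement)
  # pure rotation step over 1 degree fires the displacement criterion
  motion[10, 5] <- 1.4
  rep2 <- detect_spikes(vol, motion)
  expect_identical(rep2$frame, 10L)
  expect_true(rep2$displacement)
  expect_error(detect_spikes(vol, motion[1:10, ]), "match")
})

test_that("repair interpolates linearly between nearest good neighbours", {
  M <- matrix(c(10, 20, 999, 40), 4, 3)
  vol <- vol_from_matrix(M)
  rep <- data.frame(frame = 3L)
  out <- vox_matrix(repair_frames(vol, rep))
  expect_equal(out[3, ], rep(30, 3))
  # no flags -> identity
  expect_identical(repair_frames(vol, data.frame(frame = integer(0)))$data,
                   vol$data)
  # two consecutive flags lie on the straight line between flanking frames
  M2 <- matrix(c(0, 999, 999, 30, 40), 5, 2)
  out2 <- vox_matrix(repair_frames(vol_from_matrix(M2),
                                   data.frame(frame = c(2L, 3L))))
  expect_equal(out2[2, ], rep(10, 2))
  expect_equal(out2[3, ], rep(20, 2))
  # leading/trailing flags take the nearest good value
  M3 <- matrix(c(999, 5, 7, 999), 4, 2)
  out3 <- vox_matrix(repair_frames(vol_from_matrix(M3),
                                   data.frame(frame = c(1L, 4L))))
  expect_equal(out3[1, ], rep(5, 2))
  expect_equal(out3[4, ], rep(7, 2))
  expect_error(repair_frames(vol_from_matrix(M3),
                             data.frame(frame = 1:4)), "all frames")
})

test_that("repair-then-detect is idempotent on generator spikes", {
  spec <- small_spec(grid = c(6, 6, 3), n_frames = 240, noise_sd_pct = 0.2,
                     spike_frames = c(60, 200))
  sim <- simulate_bold(spec)
  rep <- detect_spikes(sim$volume, sim$motion)
  fixed <- repair_frames(sim$volume, rep)
  expect_equal(nrow(detect_spikes(fixed)), 0)
})

test_that("motion_design builds the 24 regressors from differences", {
  n <- 40
  m <- as.data.frame(matrix(stats::rnorm(n * 6), n, 6))
  names(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  X <- motion_design(m)
  expect_equal(dim(X), c(n, 24L))
  expect_equal(X[, 13:24], X[, 1:12]^2, ignore_attr = TRUE)
  expect_equal(X[-1, 1:6], diff(as.matrix(m)), ignore_attr = TRUE)
  expect_equal(X[-1, 7:12], X[-n, 1:6], ignore_attr = TRUE)  # 1-frame delay
  # constant motion -> all zero; linear drift -> constant derivative column
  expect_true(all(motion_design(as.data.frame(matrix(3, 10, 6))) == 0))
  drift <- as.data.frame(matrix(0, 10, 6)); drift[, 2] <- 0.7 * (1:10)
  Xd <- motion_design(drift)
  expect_equal(Xd[-1, 2], rep(0.7, 9))
  expect_error(motion_design(m[1:2, ]), "3 frames")
})

test_that("regress_out removes fitted nuisance, preserves means, never adds variance", {
  set.seed(1)
  n <- 60
  design <- matrix(stats::rnorm(n * 3), n, 3)
  M <- cbind(design[, 1] * 2 + 5,              # equals a design column
             stats::rnorm(n) + 10,             # unrelated
             design %*% c(1, -1, 0.5) + stats::rnorm(n, sd = 0.1))
  vol <- vol_from_matrix(M)
  out <- vox_matrix(regress_out(vol, design))
  expect_equal(stats::sd(out[, 1]), 0, tolerance = 1e-10)   # perfect fit
  expect_equal(colMeans(out), colMeans(M), tolerance = 1e-10)
  v_in <- apply(vox_matrix(vol), 2, stats::var)
  expect_true(all(apply(out, 2, stats::var) <= v_in + 1e-12))
  # orthogonal design leaves a voxel unchanged
  x <- stats::rnorm(n)
  d_orth <- qr.resid(qr(cbind(1, x)), matrix(stats::rnorm(n)))
  out2 <- vox_matrix(regress_out(vol_from_matrix(cbind(x, x)), d_orth))
  expect_equal(out2[, 1], x, tolerance = 1e-10)
  # collinear columns dropped with a message
  expect_message(regress_out(vol, cbind(design, design[, 1])), "collinear")
})

test_that("bandpass passes in-band sinusoids unchanged and rejects out-of-band", {
  dt <- 0.5
  tt <- (0:1079) * dt
  s_in <- sin(2 * pi * 0.03 * tt + 1)
  out <- bandpass(s_in, 0.008, 0.07, frame_interval_s = dt)
  mid <- 100:980   # judge away from the padded edges
  amp <- sqrt(2 * mean(out[mid]^2))
  expect_equal(amp, 1, tolerance = 0.05)
  # zero phase: peak of cross-correlation with the input at 0 shift
  cc <- stats::ccf(out[mid], s_in[mid], lag.max = 4, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # one octave above the band: >= 20 dB attenuation
  s_hi <- sin(2 * pi * 0.5 * tt)
  out_hi <- bandpass(s_hi, 0.008, 0.07, frame_interval_s = dt)
  expect_lt(sqrt(mean(out_hi[mid]^2)) / sqrt(mean(s_hi[mid]^2)), 0.1)
  # constant series maps to (near) zero: DC outside the band
  expect_equal(max(abs(bandpass(rep(7, 500), 0.008, 0.07,
                                frame_interval_s = dt))), 0, tolerance = 1e-9)
  expect_error(bandpass(s_in, 0.05, 1.2, frame_interval_s = dt), "Nyquist")
})

test_that("bandpass is linear", {
  set.seed(2)
  x <- stats::rnorm(400); y <- stats::rnorm(400)
  f <- function(v) bandpass(v, 0.008, 0.07, frame_interval_s = 0.5)
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-10)
})

test_that("percent_change matches its closed form", {
  expect_true(all(vox_matrix(percent_change(make_const_vol(200))) == 0))
  M <- matrix(100, 20, 2); M[5, 1] <- 101; M[6, 1] <- 99  # mean stays 100
  out <- vox_matrix(percent_change(vol_from_matrix(M)))
  expect_equal(out[5, 1], 1.0)
  # SD of percent change of a*w + m is 100*a*sd(w)/m
  w <- make_slfo(400, 0.5, seed = 6)
  a <- 3; m0 <- 250
  vol <- vol_from_matrix(cbind(a * w + m0, a * w + m0))
  pc <- vox_matrix(percent_change(vol))[, 1]
  expect_equal(stats::sd(pc), 100 * a * stats::sd(w) / mean(a * w + m0),
               tolerance = 1e-9)
  Mneg <- matrix(c(rep(0, 20), rep(5, 20)), 20, 2)
  expect_error(percent_change(vol_from_matrix(Mneg)), "non-positive")
})
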