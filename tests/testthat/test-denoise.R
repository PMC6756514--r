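test_that("GSR removes the global component and preserves means", {
  w <- make_slfo(400, 0.5, seed = 2)
  # voxel identical to the global mean -> residual constant
  M <- matrix(100 + w, 400, 3)
  out <- vox_matrix(gsr(vol_from_matrix(M)))
  expect_equal(apply(out, 2, stats::sd), rep(0, 3), tolerance = 1e-10)
  expect_equal(colMeans(out), rep(100, 3), tolerance = 1e-10)

  # two anti-phase halves: global fluctuation cancels, voxels unchanged
  M2 <- cbind(100 + w, 100 - w)
  out2 <- vox_matrix(gsr(vol_from_matrix(M2)))
  expect_equal(out2, M2, tolerance = 1e-8)

  # low-pass GSR is blind to out-of-band fluctuations
  tt <- (0:399) * 0.5
  fast <- sin(2 * pi * 0.3 * tt)
  M3 <- cbind(100 + fast, 100 + fast + 0.1 * w)
  out3 <- vox_matrix(gsr(vol_from_matrix(M3), lowpass_only = TRUE))
  expect_equal(out3[, 1], M3[, 1], tolerance = 0.02)
})

test_that("global scaling removes multiplicative artifacts, GSR additive ones", {
  w <- make_slfo(300, 0.5, seed = 7)
  base <- c(80, 100, 140)
  mult <- outer(1 + 0.02 * w, base)         # uniform multiplicative
  out_m <- vox_matrix(global_scaling(vol_from_matrix(mult)))
  expect_equal(apply(out_m, 2, stats::sd), rep(0, 3), tolerance = 1e-10)
  # constant data: identity
  const <- vol_from_matrix(matrix(rep(base, each = 300), 300, 3))
  expect_equal(vox_matrix(global_scaling(const)),
               vox_matrix(const), tolerance = 1e-12)
  # additive artifact: GSR exact, scaling not
  addv <- outer(2 * w, c(1, 1, 1)) + rep(base, each = 300)
  out_a <- vox_matrix(gsr(vol_from_matrix(addv)))
  expect_equal(apply(out_a, 2, stats::sd), rep(0, 3), tolerance = 1e-10)
  out_as <- vox_matrix(global_scaling(vol_from_matrix(addv)))
  expect_gt(max(apply(out_as, 2, stats::sd)), 1e-6)
  expect_error(global_scaling(vol_from_matrix(matrix(c(-1, 1), 300, 2))),
               "non-positive")
})

test_that("deperfusion annihilates a pure lag structure and spares null data", {
  sim <- simulate_bold(small_spec(grid = c(10, 8, 3), n_frames = 600,
                                  delay_range_s = 2, rng_seed = 23))
  pct <- percent_change(sim$volume)
  vb <- prep_bp(sim$volume)
  ls <- track_lags(vb, 0.3, 0.5, 2)
  pre <- band_variance(pct)
  post <- band_variance(suppressMessages(deperfusion(pct, ls)))
  expect_lt(mean(post) / mean(pre), 0.05)

  # nothing to remove: independent noise dataset cleaned with this ls
  set.seed(5)
  noise <- matrix(stats::rnorm(600 * sum(vb$mask), 100), 600)
  nvol <- set_vox_matrix(pct, noise)
  out <- suppressMessages(deperfusion(nvol, ls))
  expect_equal(vox_matrix(out), noise, tolerance = 0.05)
})

test_that("deperfusion beats uniform GSR at off-phase voxels", {
  sim <- simulate_bold(small_spec(grid = c(12, 8, 3), n_frames = 720,
                                  delay_range_s = 2, noise_sd_pct = 0.3,
                                  rng_seed = 25))
  pct <- percent_change(sim$volume)
  ls <- track_lags(prep_bp(sim$volume), 0.3, 0.5, 2)
  v_gsr <- band_variance(gsr(pct, lowpass_only = TRUE))
  v_dep <- band_variance(suppressMessages(deperfusion(pct, ls)))
  off <- abs(sim$truth$delay_field[sim$volume$mask]) >= 1
  expect_gt(mean(v_gsr[off]) / mean(v_dep[off]), 2)
})

test_that("GLM recovers exact regressors and calibrated null t-statistics", {
  ev <- data.frame(onset = seq(10, 250, 30), duration = 0.5)
  nt <- 600
  reg <- hrf_regressor(ev, nt, 0.5)
  # voxel equal to the regressor: beta 1, zero residual
  M <- cbind(reg + 10, 2.5 * reg - 3)
  res <- fit_glm(vol_from_matrix(M), ev)
  expect_equal(res$beta[1, 1, 1], 1, tolerance = 1e-8)
  expect_equal(res$beta[2, 1, 1], 2.5, tolerance = 1e-8)
  expect_equal(res$sigma2[1, 1, 1], 0, tolerance = 1e-10)

  # null calibration: iid noise voxels give t ~ t(df)
  set.seed(31)
  noise <- matrix(stats::rnorm(600 * 1000, 100), 600, 1000)
  resn <- fit_glm(vol_from_matrix(noise), ev)
  ks <- stats::ks.test(resn$tstat[!is.na(resn$tstat)], stats::pt,
                       df = resn$df)
  expect_gt(ks$p.value, 0.01)
  expect_error(fit_glm(vol_from_matrix(M), ev[0, ]), "empty")
})

test_that("active-voxel betas survive deperfusioning within 10%", {
  # activation scattered across lag bins, a small fraction of each (as in
  # real data); a compact box concentrated in one bin would bleed into that
  # bin's seed series
  act <- array(FALSE, c(12, 10, 3))
  act[cbind(rep(2:11, each = 2), rep(c(3, 8), 10), rep(1:3, length.out = 20))] <- TRUE
  # strong-task regime: the residual chance correlation between the advected
  # sLFO seeds and the regressor scales with the sLFO/NVC amplitude ratio
  spec <- small_spec(grid = c(12, 10, 3), n_frames = 720, delay_range_s = 2,
                     slfo_amp_pct = 0.5, nvc_amp_pct = 2, noise_sd_pct = 0.2,
                     active_mask = act, rng_seed = 33)
  sim <- simulate_bold(spec)
  pct <- percent_change(sim$volume)
  ls <- track_lags(prep_bp(sim$volume), 0.3, 0.5, 2)
  clean <- suppressMessages(deperfusion(pct, ls))
  res <- fit_glm(clean, sim$events)
  act <- sim$truth$active_mask
  expect_equal(mean(res$beta[act]), 2, tolerance = 0.10)
})

test_that("correlated NVC/sLFO produces spurious negative betas under GSR only", {
  spec <- small_spec(grid = c(10, 8, 3), n_frames = 720, delay_range_s = 2,
                     nvc_amp_pct = 1, noise_sd_pct = 0.3,
                     slfo_nvc_corr = 0.1, rng_seed = 37)
  sim <- simulate_bold(spec)
  pct <- percent_change(sim$volume)
  ls <- track_lags(prep_bp(sim$volume), 0.3, 0.5, 2)
  nonact <- !sim$truth$active_mask & sim$volume$mask
  beta_of <- function(v) mean(fit_glm(v, sim$events)$beta[nonact])
  b_raw <- beta_of(pct)
  b_gsr <- beta_of(gsr(pct))
  b_dep <- beta_of(suppressMessages(deperfusion(pct, ls)))
  expect_lt(b_gsr, 0)               # spurious deactivation
  expect_lt(b_gsr, b_raw)
  expect_lte(b_dep, b_raw + 1e-6)   # the full ordering is a multi-seed property
})

test_that("cleaning methods leave geometry and frame count unchanged", {
  sim <- simulate_bold(small_spec(grid = c(8, 6, 2), n_frames = 300,
                                  delay_range_s = 1, rng_seed = 39))
  pct <- percent_change(sim$volume)
  ls <- track_lags(prep_bp(sim$volume), 0.3, 0.5, 1)
  for (out in list(gsr(pct), gsr(pct, lowpass_only = TRUE),
                   global_scaling(sim$volume),
                   suppressMessages(deperfusion(pct, ls))))
    expect_identical(dim(out$data), dim(sim$volume$data))
})
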