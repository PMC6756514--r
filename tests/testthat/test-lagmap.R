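test_that("xcorrelogram obeys the lead-positive sign convention", {
  w <- make_slfo(600, 0.5, seed = 21)
  cg0 <- xcorrelogram(w, w, 5, 0.5)
  expect_equal(cg0$peak_lag, 0)
  expect_equal(cg0$peak_r, 1)
  # x one frame ahead of y -> peak at +frame_interval
  x <- w[-1]; y <- w[-length(w)]        # x(t) = y(t + dt): x leads
  cg <- xcorrelogram(x, y, 5, 0.5)
  expect_equal(cg$peak_lag, +0.5)
  expect_gt(cg$peak_r, 0.99)
  # anti-correlated input: values are signed, the signed peak is NOT at 0
  cgn <- xcorrelogram(w, -w, 5, 0.5)
  expect_equal(cgn$r[cgn$lags == 0], -1, tolerance = 1e-12)
  expect_lt(cgn$peak_r, 1)
  expect_error(xcorrelogram(w, w[-1], 5, 0.5), "lengths")
  expect_error(xcorrelogram(rep(1, 600), w, 5, 0.5), "zero-variance")
  expect_error(xcorrelogram(w[1:10], w[1:10], 5, 0.5), "too short")
})

test_that("initial seed is the lag-zero voxel set", {
  # all voxels identical: everything selected, reference = global mean
  w <- make_slfo(480, 0.5, seed = 3)
  M <- matrix(w, 480, 12) + 0
  vol <- vol_from_matrix(M)
  s <- initial_seed(vol, max_search_s = 4)
  expect_equal(sort(s$voxels), 1:12)
  expect_equal(s$reference, rowMeans(M))

  # symmetric delay field: selected voxels are those with |tau| < step/2
  tau <- array(rep(c(-1, -0.5, 0, 0.5, 1), each = 2), c(10, 1, 1))
  sim <- simulate_bold(small_spec(grid = c(10, 1, 1), n_frames = 720,
                                  delay_field = tau, rng_seed = 17))
  sel <- initial_seed(prep_bp(sim$volume), max_search_s = 4)$voxels
  expect_setequal(sel, which(abs(as.vector(tau)) < 0.25))

  # independent white-noise voxels: no voxel passes -> error
  set.seed(4)
  noise <- matrix(stats::rnorm(1000 * 50), 1000, 50)
  expect_error(initial_seed(vol_from_matrix(noise), max_search_s = 4),
               "empty")
})

test_that("recursive tracking recovers a noiseless gradient field bin-exactly", {
  sim <- simulate_bold(small_spec(grid = c(14, 10, 4), n_frames = 720,
                                  delay_range_s = 3, rng_seed = 5))
  vb <- prep_bp(sim$volume)
  ls <- track_lags(vb, 0.3, 0.5, 3)
  expect_equal(ls$lags, seq(3, -3, by = -0.5))          # every bin recovered
  expect_true(all(lengths(ls$bins) > 0))
  tru <- sim$truth$delay_field[sim$volume$mask]
  est <- ls$lag_map[sim$volume$mask]
  # tracked voxels are bin-exact up to boundary quantization
  expect_gt(mean(!is.na(est)), 0.98)
  expect_gt(mean(abs(est - tru) <= 0.25 + 1e-9, na.rm = TRUE), 0.98)
  expect_lte(max(abs(est - tru), na.rm = TRUE), 0.3)
  # after hole filling the whole field is recovered
  full <- fill_holes(ls, vb)$lag_map[sim$volume$mask]
  expect_true(all(!is.na(full)))
  expect_gt(stats::cor(full, tru), 0.99)
  expect_lte(mean(abs(full - tru)), 0.25)
})

test_that("identical voxels collapse to a single bin at lag 0", {
  w <- make_slfo(480, 0.5, seed = 30)
  vol <- vol_from_matrix(matrix(w, 480, 9))
  ls <- track_lags(vol, 0.3, 0.5, 3, max_search_s = 3)
  expect_equal(ls$lags, 0)
  expect_equal(ls$bins[["0"]], 1:9)
})

test_that("raising the correlation threshold shrinks (never grows) coverage", {
  sim <- simulate_bold(small_spec(grid = c(10, 8, 3), n_frames = 600,
                                  delay_range_s = 2, noise_sd_pct = 8,
                                  rng_seed = 9))
  vb <- prep_bp(sim$volume)
  n03 <- sum(!is.na(track_lags(vb, 0.3, 0.5, 2)$lag_map))
  n06 <- sum(!is.na(track_lags(vb, 0.6, 0.5, 2)$lag_map))
  expect_lt(n06, n03)
})

test_that("hole filling restores deleted voxels and resolves noise voxels", {
  sim <- simulate_bold(small_spec(grid = c(10, 8, 4), n_frames = 600,
                                  delay_range_s = 2, rng_seed = 11))
  vb <- prep_bp(sim$volume)
  ls <- track_lags(vb, 0.3, 0.5, 2)
  # no holes -> identity on the map
  expect_equal(fill_holes(ls, vb)$lag_map, ls$lag_map)

  # delete one interior voxel's lag (signal intact): pass 1 restores it
  idx <- which(!is.na(ls$lag_map))
  target <- idx[which.min(abs(ls$lag_map[idx] - 1))]
  truth_val <- ls$lag_map[target]
  ls2 <- ls
  ls2$lag_map[target] <- NA
  vox_pos <- match(target, which(ls$mask))
  ls2$bins <- lapply(ls2$bins, function(b) setdiff(b, vox_pos))
  filled <- fill_holes(ls2, vb)
  expect_equal(filled$fill[target], 1L)
  expect_lt(abs(filled$lag_map[target] - truth_val), 0.5)
})

test_that("a pure-noise voxel is resolved only by the neighbour pass", {
  spec <- small_spec(grid = c(9, 7, 3), n_frames = 600, delay_range_s = 2,
                     rng_seed = 13)
  sim <- simulate_bold(spec)
  vol <- sim$volume
  set.seed(99)
  vol$data[5, 4, 2, ] <- mean(vol$data) * (1 + 0.02 * stats::rnorm(n_frames(vol)))
  vb <- prep_bp(vol)
  ls <- fill_holes(track_lags(vb, 0.3, 0.5, 2), vb)
  pos <- which(array(seq_len(prod(dim(vol$data)[1:3])), dim(vol$data)[1:3]) ==
                 (5 + (4 - 1) * 9 + (2 - 1) * 63))
  expect_equal(ls$fill[5, 4, 2], 2L)
  nb <- c(ls$lag_map[4, 4, 2], ls$lag_map[6, 4, 2], ls$lag_map[5, 3, 2],
          ls$lag_map[5, 5, 2], ls$lag_map[5, 4, 1], ls$lag_map[5, 4, 3])
  expect_equal(ls$lag_map[5, 4, 2], mean(nb))
})

test_that("lag maps are shift-equivariant (lags are relative, not absolute)", {
  sim <- simulate_bold(small_spec(grid = c(10, 8, 3), n_frames = 660,
                                  delay_range_s = 2, rng_seed = 15))
  k <- 6
  nt <- n_frames(sim$volume)
  v1 <- sim$volume; v1$data <- v1$data[, , , 1:(nt - k), drop = FALSE]
  v2 <- sim$volume; v2$data <- v2$data[, , , (k + 1):nt, drop = FALSE]
  m1 <- track_lags(prep_bp(v1), 0.3, 0.5, 2)$lag_map
  m2 <- track_lags(prep_bp(v2), 0.3, 0.5, 2)$lag_map
  both <- !is.na(m1) & !is.na(m2)
  expect_gt(mean(both), 0.98)
  expect_true(all(m1[both] == m2[both]))
})

test_that("seed series are mutually consistent: pairwise peaks at lag differences", {
  sim <- simulate_bold(small_spec(grid = c(12, 8, 3), n_frames = 720,
                                  delay_range_s = 2, rng_seed = 19))
  ls <- track_lags(prep_bp(sim$volume), 0.3, 0.5, 2)
  for (pair in list(c("2", "0"), c("1.5", "-1"), c("0.5", "-2"))) {
    cg <- xcorrelogram(ls$seed_series[, pair[1]], ls$seed_series[, pair[2]],
                       ls$range_s * 2, ls$frame_interval_s)
    expect_equal(cg$peak_lag,
                 as.numeric(pair[1]) - as.numeric(pair[2]))
  }
})
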