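test_that("directional filter separates forward and backward plane waves", {
  # grid-periodic plane waves (integer cycle counts) so the spectral
  # support sits exactly in one pair of quadrants
  N <- 64; M <- 100; dx <- 1e-3; dt <- 1e-5
  i <- 0:(N - 1); j <- 0:(M - 1)
  fwd <- outer(i, j, function(i, j) sin(2 * pi * (5 * i / N - 12 * j / M)))
  bwd <- outer(i, j, function(i, j) sin(2 * pi * (5 * i / N + 12 * j / M)))
  mf <- spatiotemporal_map(fwd, dx, dt)
  mb <- spatiotemporal_map(bwd, dx, dt)
  out_f <- directional_filter(mf)
  out_b <- directional_filter(mb)
  # passband identity within 2% RMS, stopband below 5% RMS
  expect_lt(sqrt(mean((out_f$u - fwd)^2)) / sqrt(mean(fwd^2)), 0.02)
  expect_lt(sqrt(mean(out_b$u^2)) / sqrt(mean(bwd^2)), 0.05)
  expect_true(isTRUE(out_f$meta$directional_filtered))
  expect_error(directional_filter(spatiotemporal_map(matrix(1, 4, 4), 1, 1)),
               "8 x 8")
})

test_that("superposed forward and backward waves yield the forward speed", {
  sm <- synth_plane_wave_map(50, reflection = 1)
  est <- radon_speed(directional_filter(sm))
  expect_lt(abs(est$speed - 50) / 50, 0.02)
})

test_that("radon estimator is accurate, amplitude-invariant and grid-stable", {
  sm <- synth_plane_wave_map(50)
  est <- radon_speed(sm, filtered = TRUE)
  expect_lt(abs(est$speed - 50), 0.5)
  expect_false(any(est$flags))
  expect_gt(est$peak_angle, est$angle_grid_range[1])
  # amplitude scaling leaves the estimate unchanged (Radon linearity)
  sm10 <- spatiotemporal_map(10 * sm$u, sm$dx, sm$dt, sm$meta)
  expect_equal(radon_speed(sm10, filtered = TRUE)$speed, est$speed,
               tolerance = 1e-9)
  # halving the angle step moves the estimate < 0.2%
  est2 <- radon_speed(sm, angle_grid = seq(5, 85, by = 0.125), filtered = TRUE)
  expect_lt(abs(est2$speed - est$speed) / est$speed, 0.002)
})

test_that("estimator consistency across log-spaced speeds, noiseless < 1%", {
  for (cc in exp(seq(log(20), log(160), length.out = 7))) {
    sm <- synth_plane_wave_map(cc)
    est <- radon_speed(sm, filtered = TRUE)
    expect_lt(abs(est$speed - cc) / cc, 0.01)
  }
})

test_that("noisy estimates stay within 5% at SNR 20 dB (seeded replicates)", {
  errs <- vapply(1:25, function(s) {
    sm <- synth_plane_wave_map(50, snr_db = 20, seed = s)
    abs(radon_speed(sm, filtered = TRUE)$speed - 50) / 50
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("degenerate maps are flagged rather than silently trusted", {
  flat <- spatiotemporal_map(matrix(0, 32, 64), 1e-3, 1e-5)
  est <- radon_speed(flat, filtered = TRUE)
  expect_true(est$flags[["low_signal"]])
})

test_that("assemble_map resamples to uniform spacing and fills gaps", {
  sm <- synth_plane_wave_map(40, n_x = 33, n_t = 60)
  pos <- (0:32) * sm$dx
  # identity on already uniform input
  out <- assemble_map(sm$u, pos, sm$dt)
  expect_equal(out$u, sm$u)
  expect_equal(out$dx, sm$dx)
  # dropped node is infilled and flagged
  u2 <- sm$u; u2[10, ] <- NA
  out2 <- assemble_map(u2, pos, sm$dt)
  expect_identical(out2$meta$infilled_rows, 10L)
  expect_lt(max(abs(out2$u[10, ] - sm$u[10, ])),
            0.3 * max(abs(sm$u)))
  # non-uniform (helical-arc) positions resampled onto a uniform grid
  warp <- pos + 1e-4 * sin(seq(0, pi, length.out = 33))
  out3 <- assemble_map(sm$u, warp, sm$dt)
  expect_equal(nrow(out3$u) , length(warp))
  expect_equal((nrow(out3$u) - 1) * out3$dx, warp[33] - warp[1],
               tolerance = 1e-12)
  expect_error(assemble_map(sm$u, rev(pos), sm$dt), "increasing")
})

test_that("map CSV container round-trips with metadata", {
  sm <- synth_plane_wave_map(72, n_x = 16, n_t = 20)
  f <- tempfile(fileext = ".csv")
  write_map_csv(sm, f)
  back <- read_map_csv(f)
  expect_equal(back$u, sm$u, tolerance = 1e-12)
  expect_equal(back$dx, sm$dx)
  expect_equal(back$dt, sm$dt)
  expect_equal(back$meta$true_speed, 72)
})
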