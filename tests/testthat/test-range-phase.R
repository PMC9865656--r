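test_that("resampling fixes the session length at 660 frames", {
  s <- idle_session()
  expect_identical(resample_session(s$rec), s$rec)  # already 660

  long <- simulate_session(s$user, s$cfg, duration = 60, seed = 9)  # 1320
  res <- resample_session(long)
  expect_equal(length(res$belt), 660)
  expect_equal(dim(res$frames)[1], 660)
  # integer-multiple input: every other original sample reproduced exactly
  expect_equal(res$belt, long$belt[seq(1, 1319, by = 2)])

  short <- simulate_session(s$user, s$cfg, duration = 600 / 22, seed = 9) # 600
  res2 <- resample_session(short)
  expect_equal(length(res2$belt), 660)
  expect_true(all(res2$belt[601:660] == 0))
  expect_true(all(res2$frames[601:660, , , ] == 0))
})

test_that("the range cube finds a stationary target and ignores DC offsets", {
  s <- idle_noiseless()
  cfg <- s$cfg
  u <- make_user(3, overrides = list(breath_amp = 1e-12, motion_rate = 0,
                                     base_range = 5 * range_bin_spacing(cfg)))
  rec <- simulate_session(u, cfg, seed = 2,
                          noise = noise_spec(adc_sd = 0, belt_sd = 0))
  cube <- to_range_cube(rec, cfg)
  maxes <- vapply(seq_len(nrow(cube$sr)), function(m) detect_max_bin(cube, m),
                  integer(1))
  expect_true(all(maxes == 6L))  # 0-based bin 5 = target range / bin spacing

  # adding a constant to every sample leaves the cube unchanged
  rec2 <- rec
  rec2$frames <- rec$frames + 17
  cube2 <- to_range_cube(rec2, cfg)
  expect_equal(cube2$sr, cube$sr, tolerance = 1e-9)

  rec3 <- rec
  rec3$frames[] <- 0
  expect_true(all(Mod(to_range_cube(rec3, cfg)$sr) == 0))
})

test_that("detect_max_bin matches an exhaustive scan and breaks ties low", {
  s <- idle_session()
  cube <- to_range_cube(s$rec, s$cfg)
  set.seed(11)
  for (m in sample(nrow(cube$sr), 50)) {
    mag <- Mod(cube$sr[m, ])
    mag[1] <- -Inf
    expect_identical(detect_max_bin(cube, m), which.max(mag))
  }
  # constructed tie
  fake <- structure(list(sr = matrix(complex(real = c(0, 3, 3, 1)), 1),
                         bin_spacing = 1, frame_rate = 22),
                    class = "range_cube")
  expect_identical(detect_max_bin(fake, 1), 2L)
})

test_that("the tracked window is 12 bins wide and moves smoothly", {
  s <- idle_session()
  cube <- to_range_cube(s$rec, s$cfg)
  track <- track_bin_window(cube)
  expect_true(all(track$hi - track$lo + 1 == 12))
  expect_true(all(abs(diff(track$center)) <= 2))
  # warm-up: first frame centered on its own max bin
  expect_equal(track$center[1], track$max_bin[1])

  # steady state away from the grid edge: constant max bin b -> [b-6, b+5]
  fake <- structure(list(sr = matrix(complex(real = rep(c(rep(0, 19), 5,
                                                          rep(0, 80)), 40)),
                                     nrow = 40, byrow = TRUE),
                         bin_spacing = 1, frame_rate = 22),
                    class = "range_cube")
  tr2 <- track_bin_window(fake)
  expect_true(all(tr2$max_bin == 20L))
  expect_true(all(tr2$lo == 14L) && all(tr2$hi == 25L))

  # a single-frame spike moves the smoothed center by at most spike/8 + 1
  mags <- matrix(0, 40, 100)
  mags[, 20] <- 5
  mags[15, 20] <- 0
  mags[15, 60] <- 9        # one-frame jump of 40 bins
  fake2 <- structure(list(sr = matrix(complex(real = mags), 40),
                          bin_spacing = 1, frame_rate = 22),
                     class = "range_cube")
  tr3 <- track_bin_window(fake2)
  expect_lte(max(abs(diff(tr3$center))), ceiling(40 / 8) + 1)
})

test_that("MTI clutter follows the exponential recurrence", {
  st <- clutter_state(1, alpha = 0.4)
  st <- update_clutter(st, 1 + 0i)
  expect_equal(st$s_bar, 0.4 + 0i)
  st <- update_clutter(st, 1 + 0i)
  expect_equal(st$s_bar, 0.64 + 0i)

  # geometric convergence to a constant input
  st <- clutter_state(1, alpha = 0.4)
  v <- 2 - 1i
  for (k in 1:12) {
    st <- update_clutter(st, v)
    expect_equal(Mod(st$s_bar - v), 0.6^k * Mod(v), tolerance = 1e-12)
  }
  # static scene residual below 1% within ceil(log(.01)/log(.6)) = 10 frames
  expect_lt(0.6^10, 0.01)

  expect_error(clutter_state(1, alpha = 1.5), "alpha")
  expect_error(update_clutter(clutter_state(2), 1 + 0i), "bins")
})

test_that("phase-bin selection maximizes peak-to-clutter and reduces to the
           magnitude argmax for zero clutter", {
  set.seed(21)
  for (r in 1:25) {
    vals <- complex(real = runif(12), imaginary = runif(12))
    st <- clutter_state(12)
    st$s_bar <- complex(real = runif(12, -0.2, 0.2),
                        imaginary = runif(12, -0.2, 0.2))
    expect_identical(select_phase_bin(vals, st),
                     which.max(Mod(vals - st$s_bar)^2))
  }
  # zero clutter, real inputs: same as the magnitude argmax
  vals <- complex(real = c(0.3, 1.4, 0.9, 1.4))
  expect_identical(select_phase_bin(vals, clutter_state(4)), 2L)
  # frame identical to clutter in all bins: tie -> lowest index
  st <- clutter_state(3)
  st$s_bar <- complex(real = c(1, 2, 3))
  expect_identical(select_phase_bin(st$s_bar, st), 1L)
})

test_that("breathing-bin selection hits the true bin in a cluttered scene", {
  s <- idle_session()
  cfg <- s$cfg
  cube <- to_range_cube(s$rec, cfg)
  track <- track_bin_window(cube)
  target_bin <- 6L
  hits <- 0L
  s_bar <- complex(real = rep(0, ncol(cube$sr)))
  sel <- integer(nrow(cube$sr))
  for (m in seq_len(nrow(cube$sr))) {
    w <- track$lo[m]:track$hi[m]
    s_bar[w] <- 0.4 * cube$sr[m, w] + 0.6 * s_bar[w]
    sel[m] <- w[which.max(Mod(cube$sr[m, w] - s_bar[w])^2)]
  }
  expect_gte(mean(sel[-(1:20)] == target_bin), 0.95)
})

test_that("phase unwrapping undoes wrapping exactly", {
  expect_equal(unwrap_phase(c(0, 2.5, -2.9)), c(0, 2.5, -2.9 + 2 * pi))

  # identity on sequences whose steps already lie within (-pi, pi)
  set.seed(30)
  gentle <- cumsum(runif(100, -3, 3))
  expect_equal(unwrap_phase(gentle * 0.3), gentle * 0.3, tolerance = 1e-12)

  set.seed(31)
  for (r in 1:200) {
    phi <- cumsum(runif(120, -3, 3))       # smooth ramp, steps within (-pi, pi)
    wrapped <- atan2(sin(phi), cos(phi))
    expect_equal(unwrap_phase(wrapped), phi - phi[1] + wrapped[1],
                 tolerance = 1e-12)
  }
})

test_that("the extracted phase trace is normalized and frequency-faithful", {
  s <- idle_session()
  tr <- extract_phase_trace(s$rec, s$cfg)
  expect_equal(range(tr$x), c(0, 1))
  expect_equal(length(tr$x), 660)
  est <- belt_fc_reference(tr$x, s$rec$frame_rate)$fc
  expect_lt(abs(est - s$user$fc_true), 0.02)
})

test_that("a global range offset below one bin leaves selected bins unchanged", {
  cfg <- radar_config()
  base <- 5 * range_bin_spacing(cfg)
  u1 <- make_user(8, overrides = list(motion_rate = 0, base_range = base))
  u2 <- make_user(8, overrides = list(motion_rate = 0, base_range = base + 0.02))
  r1 <- simulate_session(u1, cfg, seed = 4, noise = noise_spec(adc_sd = 0))
  r2 <- simulate_session(u2, cfg, seed = 4, noise = noise_spec(adc_sd = 0))
  t1 <- extract_phase_trace(r1, cfg)
  t2 <- extract_phase_trace(r2, cfg)
  expect_identical(t1$selected_bin, t2$selected_bin)
})

test_that("recovered displacement matches the simulated chest motion", {
  s <- idle_noiseless()
  tr <- extract_phase_trace(s$rec, s$cfg, phase_source = "raw")
  disp <- tr$raw_phase * wavelength(s$cfg) / (4 * pi)
  truth <- s$rec$truth$displacement
  err <- (disp - mean(disp)) - (truth - mean(truth))
  expect_lt(sqrt(mean(err^2)), 0.05 * s$user$breath_amp)
})
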