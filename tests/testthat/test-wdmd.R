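test_that("a static window is pure background: c1 = frame, c2 = 0", {
  set.seed(11)
  v <- matrix(runif(64) * 10 + 5, 8, 8)
  win <- frame_stack(replicate(3, v, simplify = FALSE), dt = 1.5)
  comp <- window_components(win)
  expect_equal(comp$c1, v, tolerance = 1e-8)
  expect_lt(max(abs(comp$c2)), 1e-8)
})

test_that("an alternating perturbation lands in the sparse component", {
  set.seed(12)
  v <- matrix(runif(256) * 10 + 10, 16, 16)
  s <- matrix(0, 16, 16)
  s[5:8, 5:8] <- 0.5  # small localised disturbance
  win <- frame_stack(list(v, v + s, v), dt = 1.5)
  comp <- window_components(win)
  expect_equal(comp$c1, v, tolerance = 0.05)
  # |c2| should concentrate on the support of s
  on <- mean(abs(comp$c2[s != 0]))
  off <- mean(abs(comp$c2[s == 0]))
  expect_gt(on, 10 * off)
})

test_that("a window of 3 distinct frames yields exactly 2 modes internally", {
  set.seed(13)
  frames <- replicate(3, matrix(rnorm(36), 6, 6), simplify = FALSE)
  win <- frame_stack(frames, dt = 1.5)
  dec <- compute_dmd(build_snapshot_matrix(win), dt = 1.5)
  expect_equal(dec$d, 2L)
})

test_that("component sequences have length N - W + 1", {
  set.seed(14)
  for (case in list(c(N = 5, W = 3), c(N = 8, W = 4), c(N = 6, W = 2))) {
    fs <- frame_stack(replicate(case["N"], matrix(rnorm(16) + 10, 4, 4),
                                simplify = FALSE), dt = 1)
    wd <- run_wdmd(fs, W = case["W"])
    expect_equal(wd$c1$N, as.integer(case["N"] - case["W"] + 1))
    expect_equal(wd$c2$N, wd$c1$N)
    expect_equal(c(wd$c1$m, wd$c1$n), c(fs$m, fs$n))
  }
  fs <- frame_stack(replicate(3, matrix(1, 2, 2), simplify = FALSE), dt = 1)
  expect_error(run_wdmd(fs, W = 5), "shorter")
})

test_that("W-DMD is idempotent on a constant sequence", {
  set.seed(15)
  v <- matrix(runif(49) + 2, 7, 7)
  fs <- frame_stack(replicate(10, v, simplify = FALSE), dt = 1)
  wd <- run_wdmd(fs, W = 3)
  for (i in seq_len(wd$c1$N)) {
    expect_equal(wd$c1$frames[[i]], v, tolerance = 1e-6)
    expect_lt(max(abs(wd$c2$frames[[i]])), 1e-6)
  }
})

test_that("a motion-free slowly enhancing stack has a near-empty sparse channel", {
  # realistic noise level: on exactly noiseless smoothly enhancing data the
  # window modes become nearly parallel and amplitude fitting is ill-posed
  ph <- small_phantom(seed = 16, amplitude = 0, noise_sd = 0.4)
  wd <- run_wdmd(ph$stack, W = 3)
  c1_mean <- mean(vapply(wd$c1$frames, function(f) mean(abs(f)), numeric(1)))
  c2_mean <- mean(vapply(wd$c2$frames, function(f) mean(abs(f)), numeric(1)))
  expect_lt(c2_mean, 0.1 * c1_mean)
})

test_that("window length is selected from the motion periodicity", {
  # full-size phantoms: on very small frames the enhancing region dominates
  # the block grid and the vs-first motion series loses its periodicity
  cfg <- block_match_config()
  ph3 <- default_renography_phantom(seed = 17, motion_period = 3)
  expect_identical(select_window_length(ph3$stack, cfg), 3L)
  ph4 <- default_renography_phantom(seed = 18, motion_period = 4)
  expect_identical(select_window_length(ph4$stack, cfg), 4L)
  ph0 <- default_renography_phantom(seed = 19, motion_amplitude = 0)
  expect_warning(w <- select_window_length(ph0$stack, cfg), "falling back")
  expect_identical(w, 3L)
})
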