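test_that("matching a frame against itself gives a zero motion field", {
  canvas <- textured_canvas(40, 40, 0, seed = 31)
  mf <- block_match(canvas, canvas, block_match_config())
  expect_true(all(mf$dr == 0))
  expect_true(all(mf$dc == 0))
  expect_true(all(mf$cost == 0))
})

test_that("a rigid integer translation is recovered exactly", {
  canvas <- textured_canvas(40, 40, 5, seed = 32)
  ref <- crop_at(canvas, 40, 40, 5, 0, 0)
  # the scene content of the target sits at (dr, dc) = (+2, +1) relative to
  # the reference; positive displacements stay inside the frame for every
  # block of the grid, so recovery must be exact everywhere
  target <- crop_at(canvas, 40, 40, 5, -2, -1)
  mf <- block_match(ref, target, block_match_config())
  expect_true(all(mf$dr == 2))
  expect_true(all(mf$dc == 1))
})

test_that("block matching agrees with an independent brute-force oracle", {
  cfg <- block_match_config(block_height = 7L, block_width = 7L,
                            overlap_r = 2L, overlap_c = 2L,
                            max_disp_r = 3L, max_disp_c = 3L)
  for (seed in 1:6) {
    set.seed(seed + 100)
    ref <- matrix(rnorm(32 * 32), 32, 32)
    target <- matrix(rnorm(32 * 32), 32, 32)
    mf <- block_match(ref, target, cfg)
    oracle <- brute_force_block_match(ref, target, cfg)
    expect_equal(mf$dr, oracle$dr)
    expect_equal(mf$dc, oracle$dc)
    expect_equal(mf$cost, oracle$cost, tolerance = 1e-12)
  }
  # and with the MAD criterion
  cfg_mad <- block_match_config(block_height = 7L, block_width = 7L,
                                overlap_r = 2L, overlap_c = 2L,
                                max_disp_r = 3L, max_disp_c = 3L,
                                cost = "mad")
  set.seed(200)
  ref <- matrix(rnorm(32 * 32), 32, 32)
  target <- matrix(rnorm(32 * 32), 32, 32)
  mf <- block_match(ref, target, cfg_mad)
  oracle <- brute_force_block_match(ref, target, cfg_mad)
  expect_equal(mf$dr, oracle$dr)
  expect_equal(mf$dc, oracle$dc)
})

test_that("displacements never exceed the search range", {
  set.seed(33)
  ref <- matrix(rnorm(30 * 30), 30, 30)
  target <- matrix(rnorm(30 * 30), 30, 30)
  cfg <- block_match_config(block_height = 9L, block_width = 9L,
                            overlap_r = 3L, overlap_c = 3L,
                            max_disp_r = 4L, max_disp_c = 2L)
  mf <- block_match(ref, target, cfg)
  expect_true(all(abs(mf$dr) <= 4))
  expect_true(all(abs(mf$dc) <= 2))
})

test_that("mean motion magnitude matches a known alternating shift", {
  canvas <- textured_canvas(40, 40, 3, seed = 34)
  # frames alternate between crops at shift 0 and shift -3: relative to each
  # zero-shift frame, the shifted frames carry their content at dr = +3,
  # which is inside the search range for every block of the grid
  frames <- lapply(rep(c(0L, -3L), 4),
                   function(s) crop_at(canvas, 40, 40, 3, s, 0))
  fs <- frame_stack(frames, dt = 1)
  prof <- mean_motion_magnitude(fs, block_match_config())
  expect_s3_class(prof, "motion_profile")
  expect_length(prof$per_pair, 7L)
  # pairs with the zero-shift frame as reference see exactly dr = +3;
  # the reverse pairs need dr = -3, which falls outside the frame for the
  # top block row, so only an upper bound is asserted for them
  expect_equal(prof$per_pair[c(1, 3, 5, 7)], rep(3, 4), tolerance = 1e-12)
  expect_true(all(prof$per_pair <= 5 * sqrt(2)))
  # vs_first: frame 1 has shift 0, so odd targets are at magnitude 3 exactly
  prof2 <- mean_motion_magnitude(fs, block_match_config(), scheme = "vs_first")
  expect_equal(prof2$per_pair, rep(c(3, 0), length.out = 7), tolerance = 1e-12)
})

test_that("estimate_period recovers known periodicities", {
  t_idx <- 0:99
  expect_identical(estimate_period(5 + sin(2 * pi * t_idx / 4)), 4L)
  # a linear ramp on top must not hide a period-3 oscillation
  expect_identical(estimate_period(0.05 * t_idx + rep(c(0, 2, 2), length.out = 100)),
                   3L)
  expect_identical(estimate_period(rep(1, 50)), 0L)
  # pure trend, no oscillation
  expect_identical(estimate_period(seq(0, 10, length.out = 60)), 0L)
})
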