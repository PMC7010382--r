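test_that("a constant sequence yields one background mode at eigenvalue 1", {
  set.seed(3)
  v <- matrix(runif(24) + 1, 4, 6)
  fs <- frame_stack(replicate(7, v, simplify = FALSE), dt = 1.5)
  dec <- compute_dmd(fs)
  expect_equal(dec$d, 1L)
  expect_equal(dec$eigenvalues, 1 + 0i, tolerance = 1e-10)
  expect_lt(Mod(dec$frequencies[1]), 1e-10)
})

test_that("scalar decay and rotation dynamics recover their spectra", {
  # x_{t+1} = 0.9 x_t: the propagator is scalar multiplication by 0.9
  fs <- linear_system_stack(matrix(0.9), 1, 8, 5, 6, seed = 4)
  dec <- compute_dmd(fs)
  expect_equal(dec$d, 1L)
  expect_lt(Mod(dec$eigenvalues[1] - 0.9), 1e-8)

  # 2x2 rotation block: conjugate eigenvalue pair exp(+-i theta)
  th <- 0.3
  A0 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  fs2 <- linear_system_stack(A0, c(1, 0.5), 9, 5, 6, seed = 5)
  dec2 <- compute_dmd(fs2)
  expect_equal(dec2$d, 2L)
  expect_equal(sort(Arg(dec2$eigenvalues)), c(-th, th), tolerance = 1e-6)
  expect_equal(Mod(dec2$eigenvalues), c(1, 1), tolerance = 1e-6)
})

test_that("mode count equals min(svd_rank, rank, N-1) and errors are raised", {
  set.seed(6)
  fs <- frame_stack(replicate(10, matrix(rnorm(64), 8, 8), simplify = FALSE),
                    dt = 1)
  expect_equal(compute_dmd(fs)$d, 9L)
  expect_equal(compute_dmd(fs, svd_rank = 4)$d, 4L)
  expect_error(compute_dmd(fs, svd_rank = 10), "svd_rank")

  zero <- frame_stack(replicate(4, matrix(0, 3, 3), simplify = FALSE), dt = 1)
  expect_error(compute_dmd(zero), "degenerate")

  two <- build_snapshot_matrix(
    frame_stack(replicate(2, matrix(1, 2, 2), simplify = FALSE), dt = 1))
  expect_error(compute_dmd(two, dt = 1), "at least 3")
})

test_that("non-real eigenvalues of real data come in conjugate pairs", {
  for (seed in 1:5) {
    set.seed(seed)
    fs <- frame_stack(replicate(8, matrix(rnorm(36), 6, 6), simplify = FALSE),
                      dt = 1)
    s <- compute_dmd(fs)$eigenvalues
    cplx <- s[abs(Im(s)) > 1e-10]
    for (z in cplx) {
      expect_lt(min(Mod(cplx - Conj(z))), 1e-8 * (1 + Mod(z)))
    }
  }
})

test_that("scaling frames leaves eigenvalues unchanged and scales modes", {
  set.seed(7)
  frames <- replicate(6, matrix(rnorm(25), 5, 5), simplify = FALSE)
  fs1 <- frame_stack(frames, dt = 1)
  fs2 <- frame_stack(lapply(frames, function(f) 3.7 * f), dt = 1)
  d1 <- compute_dmd(fs1); d2 <- compute_dmd(fs2)
  expect_equal(sort(Re(d1$eigenvalues)), sort(Re(d2$eigenvalues)),
               tolerance = 1e-8)
  r1 <- reconstruct(d1, order_modes(d1, prune = FALSE), k = d1$d)
  r2 <- reconstruct(d2, order_modes(d2, prune = FALSE), k = d2$d)
  for (i in seq_len(r1$N)) {
    expect_equal(3.7 * r1$frames[[i]], r2$frames[[i]], tolerance = 1e-6)
  }
})

test_that("modes satisfy the definition Psi = P2 V S^-1 w", {
  set.seed(8)
  fs <- frame_stack(replicate(7, matrix(rnorm(30), 5, 6), simplify = FALSE),
                    dt = 1)
  dec <- compute_dmd(fs)
  X <- build_snapshot_matrix(fs)
  P2 <- X[, -1]
  lhs <- P2 %*% sweep(dec$V, 2, dec$sv, "/") %*% dec$eigenvectors
  expect_lt(max(Mod(lhs - dec$modes)), 1e-10)
  # frequencies are elementwise log(sigma)/dt
  expect_equal(dec$frequencies, log(dec$eigenvalues) / dec$dt)
})

test_that("conjugate pairs collapse to one mode, sorted by phase angle", {
  # spectrum {1, 0.8 e^{+-i pi/4}}: pair collapses, angle-0 mode first
  th <- pi / 4
  A0 <- rbind(c(1, 0, 0),
              cbind(0, 0.8 * matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                    2, 2)))
  fs <- linear_system_stack(A0, c(1, 1, 0.5), 10, 4, 5, seed = 9)
  dec <- compute_dmd(fs)
  ord <- order_modes(dec)
  expect_length(ord$kept_indices, 2L)
  expect_equal(ord$phase_angles, c(0, th), tolerance = 1e-6)
  kept <- dec$eigenvalues[ord$kept_indices]
  expect_true(all(Im(kept) >= -1e-10))  # non-negative member retained

  # all-real positive spectrum: nothing pruned, ties broken by |sigma| desc
  A1 <- diag(c(0.95, 0.7, 0.5))
  fs1 <- linear_system_stack(A1, c(1, 1, 1), 10, 4, 5, seed = 10)
  dec1 <- compute_dmd(fs1)
  ord1 <- order_modes(dec1)
  expect_length(ord1$kept_indices, 3L)
  expect_true(all(ord1$phase_angles == 0))
  expect_equal(Mod(dec1$eigenvalues[ord1$kept_indices]),
               sort(Mod(dec1$eigenvalues), decreasing = TRUE))
})

test_that("a spectrum of 1 real eigenvalue plus 58 conjugate pairs keeps 59", {
  # construct the decomposition object directly with a synthetic spectrum
  angs <- seq(0.01, 1.5, length.out = 58)
  sigma <- c(1 + 0i, complex(modulus = 0.9, argument = angs),
             complex(modulus = 0.9, argument = -angs))
  dec <- structure(list(eigenvalues = sigma, d = length(sigma)),
                   class = "dmd_decomposition")
  ord <- order_modes(dec)
  expect_length(ord$kept_indices, 59L)
  expect_false(is.unsorted(ord$phase_angles))
})

test_that("Vandermonde rows are successive eigenvalue powers", {
  expect_equal(build_vandermonde(c(2, 3), 3),
               rbind(c(1, 2, 4, 8), c(1, 3, 9, 27)) + 0i)
  expect_equal(build_vandermonde(c(1, 1), 4),
               matrix(1 + 0i, 2, 5))
  s1 <- 0.5 + 0.2i
  expect_equal(build_vandermonde(s1, 2), rbind(c(1 + 0i, s1, s1^2)))
})
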