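# Shared fixtures and independent oracles, built in code at test time.

# A smooth textured scene on a padded canvas, cropped at an integer shift:
# exact rigid translation with no border artefacts.
textured_canvas <- function(m, n, pad, seed = 1) {
  set.seed(seed)
  M <- m + 2 * pad; Nc <- n + 2 * pad
  outer(sin(2 * pi * seq_len(M) / 13), cos(2 * pi * seq_len(Nc) / 11)) * 10 +
    outer(seq_len(M) / M, seq_len(Nc) / Nc) * 5 +
    matrix(rnorm(M * Nc, sd = 0.5), M, Nc) + 20
}

crop_at <- function(canvas, m, n, pad, dr = 0, dc = 0) {
  canvas[(pad + 1 + dr):(pad + m + dr), (pad + 1 + dc):(pad + n + dc)]
}

# Independent brute-force block matcher: plain nested loops, written without
# reference to the package implementation. Same candidate set and tie rule
# (smallest cost, then smallest displacement norm, then first in dr-major,
# dc-minor order).
brute_force_block_match <- function(ref, target, cfg) {
  m <- nrow(ref); n <- ncol(ref)
  bh <- cfg$block_height; bw <- cfg$block_width
  rows0 <- seq(1, m - bh + 1, by = bh - cfg$overlap_r)
  cols0 <- seq(1, n - bw + 1, by = bw - cfg$overlap_c)
  out <- NULL
  for (r0 in rows0) {
    for (c0 in cols0) {
      best <- NULL
      for (dr in -cfg$max_disp_r:cfg$max_disp_r) {
        for (dc in -cfg$max_disp_c:cfg$max_disp_c) {
          if (r0 + dr < 1 || c0 + dc < 1 ||
              r0 + dr + bh - 1 > m || c0 + dc + bw - 1 > n) next
          s <- 0
          for (i in 0:(bh - 1)) {
            for (j in 0:(bw - 1)) {
              dif <- ref[r0 + i, c0 + j] - target[r0 + dr + i, c0 + dc + j]
              s <- s + if (cfg$cost == "mse") dif * dif else abs(dif)
            }
          }
          cost <- s / (bh * bw)
          nrm <- dr * dr + dc * dc
          if (is.null(best) || cost < best$cost ||
              (cost == best$cost && nrm < best$nrm)) {
            best <- list(cost = cost, nrm = nrm, dr = dr, dc = dc)
          }
        }
      }
      out <- rbind(out, c(dr = best$dr, dc = best$dc, cost = best$cost))
    }
  }
  as.data.frame(out)
}

# A quick small phantom for unit tests (full default geometry is exercised in
# the acceptance suite).
small_phantom <- function(seed = 1, amplitude = 2L, period = 3L,
                          noise_sd = 0.4, n_frames = 30L) {
  generate_phantom(phantom_config(
    m = 32L, n = 32L, n_frames = n_frames, dt = 1.5,
    background = list(level = 20, texture_amplitude = 2, texture_period = 16),
    regions = list(
      phantom_region("kidney", "ellipse", centre = c(13, 12), axes = c(5, 4),
                     amplitude = 40, onset_s = 5, time_to_peak_s = 20,
                     alpha = 3)),
    motion = list(axis = "row", amplitude = as.integer(amplitude),
                  period = as.integer(period), waveform = "cycle"),
    noise_sd = noise_sd, seed = seed))
}

# Frame stack generated by a known linear propagator acting in a low-dim
# subspace embedded into pixel space.
linear_system_stack <- function(A0, x0, n_frames, m, n, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(m * n * nrow(A0)), m * n, nrow(A0))
  Z <- matrix(0, nrow(A0), n_frames)
  Z[, 1] <- x0
  for (t in 2:n_frames) Z[, t] <- A0 %*% Z[, t - 1]
  X <- B %*% Z
  frame_stack(lapply(seq_len(n_frames), function(t) matrix(X[, t], m, n)),
              dt = 1)
}
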