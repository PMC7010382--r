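#' Describe one enhancing region of a phantom
#'
#' Regions follow a gamma-variate-shaped enhancement curve — the canonical
#' smooth rise-then-slow-decay of a contrast agent bolus:
#' `e(t) = (tau/tp)^alpha * exp(alpha * (1 - tau/tp))` for `tau = t - onset >
#' 0` (else 0), which peaks at exactly 1 when `tau = tp`.
#'
#' @param name region label (used to name masks and truth curves).
#' @param shape `"ellipse"` or `"rectangle"`.
#' @param centre centre `c(row, col)` in pixels.
#' @param axes half-axes `c(row, col)` in pixels (half-heights for a
#'   rectangle).
#' @param amplitude peak intensity added inside the region at full enhancement.
#' @param onset_s contrast arrival time in seconds.
#' @param time_to_peak_s time from onset to peak, seconds.
#' @param alpha gamma-variate shape parameter (larger = sharper bolus).
#' @return a `phantom_region` list.
#' @export
phantom_region <- function(name, shape = c("ellipse", "rectangle"),
                           centre, axes, amplitude,
                           onset_s = 10, time_to_peak_s = 60, alpha = 3) {
  shape <- match.arg(shape)
  stopifnot(length(centre) == 2L, length(axes) == 2L, all(axes > 0),
            amplitude >= 0, time_to_peak_s > 0, alpha > 0)
  structure(list(name = name, shape = shape, centre = centre, axes = axes,
                 amplitude = amplitude, onset_s = onset_s,
                 time_to_peak_s = time_to_peak_s, alpha = alpha),
            class = "phantom_region")
}

# Gamma-variate enhancement, peak 1 at onset + time_to_peak.
gamma_variate <- function(t, onset, tp, alpha) {
  tau <- t - onset
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- (tau[pos] / tp)^alpha * exp(alpha * (1 - tau[pos] / tp))
  out
}

region_mask <- function(region, m, n) {
  r <- matrix(seq_len(m), m, n)
  c_ <- matrix(seq_len(n), m, n, byrow = TRUE)
  if (region$shape == "ellipse") {
    ((r - region$centre[1L]) / region$axes[1L])^2 +
      ((c_ - region$centre[2L]) / region$axes[2L])^2 <= 1
  } else {
    abs(r - region$centre[1L]) <= region$axes[1L] &
      abs(c_ - region$centre[2L]) <= region$axes[2L]
  }
}

#' Phantom configuration
#'
#' Full parametric description of a synthetic DCE sequence: frame geometry,
#' timing, enhancing regions, rigid pseudo-periodic translation, linear drift
#' and additive Gaussian noise. The default timing (120 frames at 1.5 s,
#' i.e. 180 s of acquisition) matches a typical renography protocol.
#'
#' The scene is built on a padded canvas — a flat background level plus a
#' smooth sinusoidal texture (so that every block of the frame carries
#' gradient information for block matching) plus the enhancing regions — and
#' each frame is a cropped view of that canvas at the frame's ground-truth
#' translation, so the rigid motion is exact and free of border artefacts.
#'
#' @param m,n frame height and width in pixels.
#' @param n_frames number of frames.
#' @param dt seconds per frame.
#' @param background list with `level` (base intensity), `texture_amplitude`
#'   and `texture_period` (pixels) of the sinusoidal texture.
#' @param regions list of [phantom_region()] objects.
#' @param motion list with `axis` (`"row"` or `"col"`), `amplitude` (pixels),
#'   `period` (frames, >= 2) and `waveform` (`"cycle"`: the displacement
#'   pattern `0, a, a, ...` repeated every `period` frames, emulating the
#'   exhale-rest / inhale pattern of shallow breathing; or `"sine"`: a
#'   sinusoid sampled at the period, rounded to integer pixels).
#' @param drift linear drift in px/frame along the motion axis (rounded to
#'   integers per frame).
#' @param noise_sd standard deviation of additive Gaussian noise (intensity
#'   units).
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(m = 64L, n = 64L, n_frames = 120L, dt = 1.5,
                           background = list(level = 20,
                                             texture_amplitude = 2,
                                             texture_period = 16),
                           regions = list(),
                           motion = list(axis = "row", amplitude = 2L,
                                         period = 3L, waveform = "cycle"),
                           drift = 0, noise_sd = 0, seed = 1L) {
  stopifnot(m > 0, n > 0, n_frames >= 2L, dt > 0,
            motion$period >= 2L, motion$amplitude >= 0, noise_sd >= 0)
  structure(list(m = as.integer(m), n = as.integer(n),
                 n_frames = as.integer(n_frames), dt = dt,
                 background = background, regions = regions, motion = motion,
                 drift = drift, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# Ground-truth integer shifts along (row, col) for each frame.
phantom_shifts <- function(config) {
  t_idx <- seq_len(config$n_frames) - 1L
  a <- config$motion$amplitude
  p <- config$motion$period
  base <- switch(config$motion$waveform,
    cycle = c(0, rep(a, p - 1L))[(t_idx %% p) + 1L],
    sine = round(a * sin(2 * pi * t_idx / p)),
    stop("unknown motion waveform", call. = FALSE)
  )
  base <- base + round(config$drift * t_idx)
  dr <- if (config$motion$axis == "row") base else rep(0, config$n_frames)
  dc <- if (config$motion$axis == "col") base else rep(0, config$n_frames)
  cbind(dr = as.integer(dr), dc = as.integer(dc))
}

#' Generate a synthetic DCE sequence with ground truth
#'
#' @param config a [phantom_config()].
#' @return an object of class `phantom_output`: `stack` (a [frame_stack]),
#'   `masks` (named list of logical ROI masks at the zero-shift position),
#'   `motion_trace` (data frame `frame`, `dr`, `dc` of ground-truth
#'   displacements in pixels), `curve_truth` (data frame of per-region
#'   noiseless mean ROI intensities per frame) and the `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  m <- config$m; n <- config$n; N <- config$n_frames
  shifts <- phantom_shifts(config)
  pad_r <- max(abs(shifts[, "dr"]))
  pad_c <- max(abs(shifts[, "dc"]))
  M <- m + 2L * pad_r; Nc <- n + 2L * pad_c

  bg <- config$background
  rr <- matrix(seq_len(M), M, Nc)
  cc <- matrix(seq_len(Nc), M, Nc, byrow = TRUE)
  scene <- bg$level + bg$texture_amplitude *
    sin(2 * pi * rr / bg$texture_period) * cos(2 * pi * cc / bg$texture_period)

  canvas_masks <- lapply(config$regions, function(reg) {
    reg2 <- reg
    reg2$centre <- reg$centre + c(pad_r, pad_c)
    mk <- region_mask(reg2, M, Nc)
    rows <- range(which(rowSums(mk) > 0))
    cols <- range(which(colSums(mk) > 0))
    if (rows[1L] < pad_r + 1L + max(shifts[, "dr"]) ||
        rows[2L] > pad_r + m + min(shifts[, "dr"]) ||
        cols[1L] < pad_c + 1L + max(shifts[, "dc"]) ||
        cols[2L] > pad_c + n + min(shifts[, "dc"])) {
      stop(sprintf("region '%s' leaves the frame under the configured motion",
                   reg$name), call. = FALSE)
    }
    mk
  })
  names(canvas_masks) <- vapply(config$regions, `[[`, character(1L), "name")

  times <- (seq_len(N) - 1L) * config$dt
  enh <- vapply(config$regions, function(reg) {
    reg$amplitude * gamma_variate(times, reg$onset_s, reg$time_to_peak_s,
                                  reg$alpha)
  }, numeric(N))
  if (length(config$regions)) dim(enh) <- c(N, length(config$regions))

  set.seed(config$seed)
  frames <- vector("list", N)
  for (t in seq_len(N)) {
    canvas_t <- scene
    for (q in seq_along(canvas_masks)) {
      canvas_t <- canvas_t + enh[t, q] * canvas_masks[[q]]
    }
    rows <- (pad_r + 1L + shifts[t, "dr"]):(pad_r + m + shifts[t, "dr"])
    cols <- (pad_c + 1L + shifts[t, "dc"]):(pad_c + n + shifts[t, "dc"])
    fr <- canvas_t[rows, cols]
    if (config$noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(m * n, sd = config$noise_sd), m, n)
    }
    frames[[t]] <- fr
  }

  masks <- lapply(canvas_masks, function(mk) {
    mk[(pad_r + 1L):(pad_r + m), (pad_c + 1L):(pad_c + n)]
  })

  # noiseless zero-shift ROI means: the ground-truth time-intensity curves
  curve_truth <- data.frame(frame = seq_len(N), time_s = times)
  for (q in seq_along(masks)) {
    base_mean <- mean(scene[canvas_masks[[q]]])
    overlaps <- vapply(seq_along(canvas_masks), function(p) {
      mean(canvas_masks[[p]][canvas_masks[[q]]])
    }, numeric(1L))
    curve_truth[[names(masks)[q]]] <-
      base_mean + as.numeric(enh %*% overlaps)
  }

  structure(
    list(stack = frame_stack(frames, dt = config$dt),
         masks = masks,
         motion_trace = data.frame(frame = seq_len(N),
                                   dr = shifts[, "dr"], dc = shifts[, "dc"]),
         curve_truth = curve_truth,
         config = config),
    class = "phantom_output"
  )
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> %d frames of %d x %d px, %d region(s), seed %d\n",
              x$stack$N, x$stack$m, x$stack$n, length(x$masks),
              x$config$seed))
  invisible(x)
}

#' Default renography phantom
#'
#' A ready-made stand-in for an abdominal DCE-MRI renography acquisition:
#' 120 frames of 64 x 64 px at 1.5 s, a kidney ellipse with a sharp
#' gamma-variate enhancement peaking mid-sequence, a slower-enhancing liver
#' band, vertical period-3 translation of 2 px (pseudo-periodic breathing)
#' and Gaussian noise with standard deviation 1% of the peak intensity.
#'
#' @param seed integer seed.
#' @param motion_amplitude vertical translation amplitude in pixels
#'   (default 2; set 0 for a motionless phantom).
#' @param motion_period breathing period in frames (default 3).
#' @param noise_sd noise standard deviation; default 0.8 (1% of the 80-unit
#'   peak kidney intensity).
#' @return a `phantom_output`, see [generate_phantom()].
#' @export
default_renography_phantom <- function(seed = 1L, motion_amplitude = 2L,
                                       motion_period = 3L, noise_sd = 0.8) {
  cfg <- phantom_config(
    m = 64L, n = 64L, n_frames = 120L, dt = 1.5,
    regions = list(
      phantom_region("kidney", "ellipse", centre = c(24, 20), axes = c(10, 7),
                     amplitude = 60, onset_s = 10, time_to_peak_s = 80,
                     alpha = 3),
      phantom_region("liver", "rectangle", centre = c(46, 40), axes = c(8, 18),
                     amplitude = 30, onset_s = 20, time_to_peak_s = 120,
                     alpha = 2)
    ),
    motion = list(axis = "row", amplitude = as.integer(motion_amplitude),
                  period = as.integer(motion_period), waveform = "cycle"),
    noise_sd = noise_sd, seed = seed
  )
  generate_phantom(cfg)
}
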