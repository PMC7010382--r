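#' Low-rank / sparse components of one window
#'
#' Runs DMD on a short window of `W` consecutive frames (producing at most
#' `W - 1` modes) and splits the window into a low-rank image `c1` — the
#' background mode, identified as the mode whose frequency has the smallest
#' `|Re(mu)|`, ties broken by smallest `|Im(mu)|`, then largest eigenvalue
#' magnitude — and a sparse
#' image `c2` aggregating all remaining modes, which carry fast intensity
#' changes such as pseudo-periodic breathing displacement.
#'
#' Dynamic modes are defined only up to complex scale, so raw modes are not
#' photometrically meaningful. Mode amplitudes `b` are obtained by
#' least-squares projection of the window's first frame onto the modes
#' (`x1 ~ Psi b`); `c1 = Re(Psi_bg b_bg)` and `c2 = Re(sum_{j != bg} Psi_j
#' b_j)`, which keeps both components on the input intensity scale. A window
#' of identical frames has rank one: `c1` equals the frame and `c2` is zero.
#'
#' @param window a [frame_stack] of length `W >= 2` (for the classic setting
#'   `W = 3`, exactly two modes arise).
#' @return a list with matrices `c1` and `c2` of the window's frame geometry.
#' @export
window_components <- function(window) {
  stopifnot(is_frame_stack(window), window$N >= 2L)
  X <- build_snapshot_matrix(window)
  m <- window$m; n <- window$n

  if (window$N == 2L) {
    # Degenerate two-frame window: one snapshot pair, one mode at most.
    # Treat frame 1 as background and the difference as the sparse part.
    return(list(c1 = window$frames[[1L]],
                c2 = window$frames[[2L]] - window$frames[[1L]]))
  }

  dec <- compute_dmd(X, dt = window$dt)
  # background = least dynamic mode: smallest growth/decay rate, then least
  # oscillatory (an eigenvalue at -1 has Re(mu) = 0 but flickers at Nyquist),
  # then dominant magnitude
  bg <- order(abs(Re(dec$frequencies)), abs(Im(dec$frequencies)),
              -Mod(dec$eigenvalues))[1L]

  Psi <- dec$modes
  x1 <- X[, 1L] + 0i
  # minimum-norm least squares; robust to nearly dependent modes
  b <- pinv(Psi) %*% x1

  c1 <- Re(Psi[, bg] * b[bg])
  if (dec$d > 1L) {
    c2 <- Re(Psi[, -bg, drop = FALSE] %*% b[-bg, , drop = FALSE])
  } else {
    c2 <- numeric(m * n)
  }
  list(c1 = matrix_to_frame(c1, m, n), c2 = matrix_to_frame(c2, m, n))
}

#' Windowed DMD (W-DMD) over a frame sequence
#'
#' Slides a window of `W` consecutive frames over the sequence with stride 1
#' (windows `{1..W}, {2..W+1}, ...`), extracts per-window low-rank and sparse
#' components with [window_components()], and concatenates them into the
#' component sequences C1 (low rank) and C2 (sparse). For `N` input frames
#' each component has `N - W + 1` frames; with the default `W = 3` that is
#' `N - 2`. Downstream motion correction uses C1 only — discarding C2 is what
#' removes the pseudo-periodic breathing motion — but C2 is returned for
#' inspection.
#'
#' @param stack a [frame_stack] with `N >= W`.
#' @param W window length in frames (default 3, matching a breathing cycle
#'   spanning three frames at 1.5 s temporal resolution).
#' @return an object of class `wdmd_result`: `c1` and `c2` ([frame_stack]s of
#'   length `N - W + 1`) and `W`. Component frame `i` is labelled with the
#'   index of its window's first input frame.
#' @export
run_wdmd <- function(stack, W = 3L) {
  stopifnot(is_frame_stack(stack))
  W <- as.integer(W)
  if (W < 2L) stop("'W' must be at least 2", call. = FALSE)
  if (stack$N < W) stop("sequence shorter than window length W", call. = FALSE)

  n_win <- stack$N - W + 1L
  c1 <- vector("list", n_win)
  c2 <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    win <- frame_stack(stack$frames[i:(i + W - 1L)], dt = stack$dt)
    comp <- window_components(win)
    c1[[i]] <- comp$c1
    c2[[i]] <- comp$c2
  }
  idx <- stack$frame_indices[seq_len(n_win)]
  structure(
    list(c1 = frame_stack(c1, dt = stack$dt, frame_indices = idx),
         c2 = frame_stack(c2, dt = stack$dt, frame_indices = idx),
         W = W),
    class = "wdmd_result"
  )
}

#' @export
print.wdmd_result <- function(x, ...) {
  cat(sprintf("<wdmd_result> W = %d; C1/C2 of %d frames (%d x %d px)\n",
              x$W, x$c1$N, x$c1$m, x$c1$n))
  invisible(x)
}

#' Select the window length from motion periodicity
#'
#' Breathing shows up as a periodic pattern in the block-matching motion
#' magnitude of each frame against the first frame of the sequence. The
#' dominant period of that series (see [estimate_period()]) is the natural
#' window length: one window then spans a full breathing cycle. If no
#' periodicity is detected, or the detected period is outside `candidates`,
#' the conventional default of 3 frames is returned with a warning.
#'
#' @param stack a [frame_stack].
#' @param bm_config a [block_match_config()].
#' @param candidates admissible window lengths (default `2:6`).
#' @return an integer window length.
#' @export
select_window_length <- function(stack, bm_config = block_match_config(),
                                 candidates = 2:6) {
  stopifnot(length(candidates) >= 1L, all(candidates >= 2L))
  prof <- mean_motion_magnitude(stack, bm_config, scheme = "vs_first")
  p <- estimate_period(prof$per_pair)
  if (p %in% candidates) return(as.integer(p))
  warning("no usable motion periodicity detected; falling back to W = 3",
          call. = FALSE)
  3L
}
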