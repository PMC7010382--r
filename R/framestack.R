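#' Construct a frame stack
#'
#' A `frame_stack` is the universal container passed between all stages of the
#' pipeline: an ordered sequence of equally sized 2-D grayscale frames together
#' with the inter-frame interval `dt` (seconds). Intensities are arbitrary
#' real units; integer inputs are promoted to double.
#'
#' @param frames a list of numeric matrices, all of identical dimension, or a
#'   3-D numeric array with time on the third axis.
#' @param dt inter-frame interval in seconds (default 1.5, the temporal
#'   resolution typical of abdominal DCE-MRI renography).
#' @param frame_indices optional integer labels for the frames, used to keep
#'   time axes honest when a stage drops leading frames. Defaults to
#'   `seq_len(N)`.
#' @return an object of class `frame_stack` with elements `frames` (list of
#'   matrices), `m`, `n` (frame height and width in pixels), `N` (number of
#'   frames), `dt`, and `frame_indices`.
#' @examples
#' fs <- frame_stack(replicate(4, matrix(rnorm(12), 3, 4), simplify = FALSE))
#' fs$N
#' @export
frame_stack <- function(frames, dt = 1.5, frame_indices = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t])
  }
  if (!is.list(frames) || length(frames) < 2L) {
    stop("'frames' must be a list (or 3-D array) of at least 2 frames",
         call. = FALSE)
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) stop("each frame must be a 2-D matrix", call. = FALSE)
    storage.mode(f) <- "double"
    f
  })
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("all frames must share identical dimensions", call. = FALSE)
  }
  if (!all(vapply(frames, function(f) all(is.finite(f)), logical(1L)))) {
    stop("frame intensities must be finite", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("'dt' must be a positive scalar (seconds)", call. = FALSE)
  }
  N <- length(frames)
  if (is.null(frame_indices)) frame_indices <- seq_len(N)
  stopifnot(length(frame_indices) == N)
  structure(
    list(frames = frames, m = dims[1L, 1L], n = dims[2L, 1L], N = N,
         dt = dt, frame_indices = as.integer(frame_indices)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px, dt = %g s (%.1f s total)\n",
              x$N, x$m, x$n, x$dt, x$dt * (x$N - 1)))
  invisible(x)
}

is_frame_stack <- function(x) inherits(x, "frame_stack")

#' Build the snapshot matrix of a frame stack
#'
#' Vectorises each frame into a column, yielding the (m*n) x N snapshot matrix
#' X whose consecutive-column pairs are related by the unknown linear
#' propagator that DMD estimates. Vectorisation is column-major (R's native
#' layout); the same convention is used everywhere a mode or column is
#' reshaped back into an image.
#'
#' @param stack a [frame_stack].
#' @return a numeric matrix of dimension `(m*n) x N`; attribute `frame_dim`
#'   stores `c(m, n)` for reshaping.
#' @seealso [matrix_to_frame()] for the inverse of one column.
#' @examples
#' fs <- frame_stack(replicate(5, matrix(1:4, 2, 2), simplify = FALSE))
#' dim(build_snapshot_matrix(fs))  # 4 x 5
#' @export
build_snapshot_matrix <- function(stack) {
  stopifnot(is_frame_stack(stack))
  X <- vapply(stack$frames, as.vector, numeric(stack$m * stack$n))
  dim(X) <- c(stack$m * stack$n, stack$N)
  attr(X, "frame_dim") <- c(stack$m, stack$n)
  X
}

#' Reshape a vectorised frame back into an image
#'
#' @param v a numeric (or complex) vector of length `m*n`, e.g. one column of a
#'   snapshot matrix or one dynamic mode.
#' @param m,n frame height and width in pixels.
#' @return an `m x n` matrix, inverting the vectorisation convention of
#'   [build_snapshot_matrix()].
#' @export
matrix_to_frame <- function(v, m, n) {
  stopifnot(length(v) == m * n)
  matrix(v, nrow = m, ncol = n)
}

# Internal: wrap columns of a (m*n) x N matrix as a frame_stack.
stack_from_matrix <- function(X, m, n, dt, frame_indices = NULL) {
  frames <- lapply(seq_len(ncol(X)), function(j) matrix_to_frame(X[, j], m, n))
  frame_stack(frames, dt = dt, frame_indices = frame_indices)
}
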