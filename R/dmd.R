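#' Dynamic mode decomposition of a snapshot matrix
#'
#' SVD-based DMD. The snapshot matrix `X` is split into `P1` (columns
#' `1..N-1`) and `P2` (columns `2..N`), assumed related by an unknown linear
#' propagator `A` with `P2 = A P1`. A thin SVD `P1 = U S V*` projects `A` onto
#' the leading left-singular subspace, giving the small reduced operator
#' `H = U* P2 V S^-1` whose eigenvalues approximate those of `A`. The dynamic
#' modes are `Psi = P2 V S^-1 w`, with `w` the eigenvectors of `H`, and each
#' mode's continuous-time frequency is `mu_j = log(sigma_j) / dt`: `Re(mu)`
#' is growth/decay, `Im(mu)` oscillation. Eigenvalues on the unit circle
#' (`|sigma| = 1`) give `Re(mu) = 0` — the stationary "background" dynamics.
#'
#' Singular values below `max(S) * 1e-10` are dropped before inversion;
#' near-zero singular values would otherwise amplify noise into the modes.
#'
#' @param X a snapshot matrix from [build_snapshot_matrix()], or a
#'   [frame_stack] (converted internally).
#' @param dt inter-frame interval in seconds; taken from the stack when `X` is
#'   a [frame_stack].
#' @param svd_rank optional cap on the number of singular vectors retained;
#'   must not exceed `N - 1`.
#' @return an object of class `dmd_decomposition`: `U`, `sv` (singular
#'   values, descending), `V`, `H` (reduced operator), `eigenvalues` (complex),
#'   `eigenvectors` (complex, columns), `modes` (complex, one column per mode),
#'   `frequencies` (complex, 1/seconds), `dt`, `d` (number of modes), and
#'   `frame_dim` when known.
#' @examples
#' v <- rnorm(30)
#' X <- vapply(0:5, function(t) 0.9^t * v, numeric(30))
#' d <- compute_dmd(X, dt = 1)
#' d$eigenvalues  # ~0.9
#' @export
compute_dmd <- function(X, dt = NULL, svd_rank = NULL) {
  frame_dim <- NULL
  if (is_frame_stack(X)) {
    if (is.null(dt)) dt <- X$dt
    frame_dim <- c(X$m, X$n)
    X <- build_snapshot_matrix(X)
  } else {
    frame_dim <- attr(X, "frame_dim")
    if (is.null(dt)) stop("'dt' must be supplied with a raw snapshot matrix",
                          call. = FALSE)
  }
  N <- ncol(X)
  if (N < 3L) stop("at least 3 snapshots are required", call. = FALSE)
  if (!is.null(svd_rank)) {
    svd_rank <- as.integer(svd_rank)
    if (svd_rank < 1L || svd_rank > N - 1L)
      stop("'svd_rank' must be in [1, N-1]", call. = FALSE)
  }

  P1 <- X[, -N, drop = FALSE]
  P2 <- X[, -1L, drop = FALSE]

  sv <- svd(P1)
  keep <- sv$d > max(sv$d) * 1e-10
  if (max(sv$d) == 0 || !any(keep)) {
    stop("degenerate input: P1 has numerical rank 0 (all-zero frames?)",
         call. = FALSE)
  }
  d <- sum(keep)
  if (!is.null(svd_rank)) d <- min(d, svd_rank)

  U <- sv$u[, seq_len(d), drop = FALSE]
  S <- sv$d[seq_len(d)]
  V <- sv$v[, seq_len(d), drop = FALSE]

  # P2 V S^-1 appears both in H and in the modes; form it once.
  P2VSinv <- P2 %*% sweep(V, 2L, S, "/")
  H <- crossprod(U, P2VSinv)

  eig <- eigen(H)
  sigma <- as.complex(eig$values)
  omega <- eig$vectors
  if (!is.complex(omega)) omega <- omega + 0i

  modes <- P2VSinv %*% omega
  mu <- log(sigma) / dt

  structure(
    list(U = U, sv = S, V = V, H = H,
         eigenvalues = sigma, eigenvectors = omega,
         modes = modes, frequencies = mu,
         dt = dt, d = d, N = N, frame_dim = frame_dim, P2 = P2),
    class = "dmd_decomposition"
  )
}

#' @export
print.dmd_decomposition <- function(x, ...) {
  cat(sprintf("<dmd_decomposition> %d modes from %d snapshots (dt = %g s)\n",
              x$d, x$N, x$dt))
  cat(sprintf("  |eigenvalue| range: [%.4g, %.4g]\n",
              min(Mod(x$eigenvalues)), max(Mod(x$eigenvalues))))
  invisible(x)
}

#' Order dynamic modes by significance
#'
#' For real-valued input data complex eigenvalues occur in conjugate pairs
#' whose modes carry duplicate information; one member of each pair (the one
#' with non-negative imaginary part) is pruned. The survivors are ranked by
#' ascending absolute phase angle `|Arg(sigma)|`: modes near angle zero vary
#' slowly (contrast enhancement, background) and are "most significant", while
#' large-angle modes oscillate fast (motion, noise). Ties in phase angle are
#' broken by descending eigenvalue magnitude, so a dominant background mode
#' precedes decaying ones; the sort is stable.
#'
#' @param decomp a `dmd_decomposition`.
#' @param uniqueness_tol tolerance used to recognise a conjugate pair:
#'   eigenvalues `a`, `b` are paired when `|a - Conj(b)| <
#'   uniqueness_tol * (1 + |a|)` and both have non-negligible imaginary part.
#' @param prune drop one member of each conjugate pair (default `TRUE`).
#'   With `prune = FALSE` all modes are ranked; reconstructing from that full
#'   ordering with `k = d` reproduces the snapshot columns exactly on
#'   full-rank data.
#' @return an object of class `mode_ordering`: `kept_indices` (indices into
#'   the decomposition's modes, most significant first) and `phase_angles`
#'   (matching `|Arg(sigma)|`, non-decreasing).
#' @export
order_modes <- function(decomp, uniqueness_tol = 1e-8, prune = TRUE) {
  stopifnot(inherits(decomp, "dmd_decomposition"), decomp$d >= 1L)
  sigma <- decomp$eigenvalues
  d <- length(sigma)
  drop <- rep(FALSE, d)
  if (prune) for (i in seq_len(d)) {
    if (drop[i]) next
    tol_i <- uniqueness_tol * (1 + Mod(sigma[i]))
    if (abs(Im(sigma[i])) <= tol_i) next  # real eigenvalue, no partner
    for (j in seq_len(d)) {
      if (j == i || drop[j]) next
      if (Mod(sigma[i] - Conj(sigma[j])) < tol_i) {
        # keep the member with non-negative imaginary part
        drop[if (Im(sigma[i]) >= 0) j else i] <- TRUE
        break
      }
    }
  }
  kept <- which(!drop)
  ang <- abs(Arg(sigma[kept]))
  ord <- order(ang, -Mod(sigma[kept]))  # stable; ties by descending |sigma|
  structure(
    list(kept_indices = kept[ord], phase_angles = ang[ord]),
    class = "mode_ordering"
  )
}

#' @export
print.mode_ordering <- function(x, ...) {
  cat(sprintf("<mode_ordering> %d modes kept after conjugate pruning\n",
              length(x$kept_indices)))
  invisible(x)
}

#' Vandermonde matrix of eigenvalue powers
#'
#' The temporal evolution of the dynamic modes is encoded by raising each
#' eigenvalue to successive powers: row `j` is `(1, sigma_j, sigma_j^2, ...,
#' sigma_j^f)`. With `f = N` this reconstructs the observed time span; `f > N`
#' extrapolates (forecasting, not validated here).
#'
#' @param eigenvalues complex (or numeric) vector of DMD eigenvalues.
#' @param f highest power, `f >= 0`.
#' @return a `length(eigenvalues) x (f+1)` complex matrix.
#' @export
build_vandermonde <- function(eigenvalues, f) {
  stopifnot(length(eigenvalues) >= 1L, f >= 0)
  f <- as.integer(f)
  sigma <- as.complex(eigenvalues)
  outer(sigma, 0:f, `^`)
}

# Internal: close a mode index set under complex conjugation, so that linear
# combinations of the selected modes can represent real-valued images.
expand_conjugate_pairs <- function(sigma, sel, tol = 1e-8) {
  out <- sel
  for (i in sel) {
    if (abs(Im(sigma[i])) > tol * (1 + Mod(sigma[i]))) {
      j <- which(Mod(sigma - Conj(sigma[i])) < tol * (1 + Mod(sigma[i])) &
                   seq_along(sigma) != i)
      out <- c(out, j)
    }
  }
  sort(unique(out))
}

# Internal: Moore-Penrose pseudo-inverse via SVD, real or complex.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(array(0, rev(dim(A))))
  s$v[, pos, drop = FALSE] %*%
    (Conj(t(s$u[, pos, drop = FALSE])) / s$d[pos])
}
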