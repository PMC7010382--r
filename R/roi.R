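#' ROI time-intensity curve
#'
#' The clinical readout of a dynamic contrast-enhanced sequence: the mean
#' intensity over a fixed region of interest (ROI), e.g. a delineated kidney,
#' in every frame. Respiratory motion moves tissue in and out of the fixed
#' mask and shows up as fluctuations in this curve; a successful motion
#' correction makes it smooth. The mask is applied as-is to every frame —
#' after correction the organ is expected to stay put, so no mask propagation
#' is performed.
#'
#' @param stack a [frame_stack].
#' @param mask a logical (or 0/1 numeric) matrix of the frame geometry with at
#'   least one `TRUE` pixel.
#' @return an object of class `time_intensity_curve`: `values` (mean ROI
#'   intensity per frame), `times` (seconds, from the stack's frame labels and
#'   `dt`), and `frame_indices`.
#' @export
time_intensity_curve <- function(stack, mask) {
  stopifnot(is_frame_stack(stack))
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask) ||
      nrow(mask) != stack$m || ncol(mask) != stack$n) {
    stop("'mask' must be a logical matrix matching the frame geometry",
         call. = FALSE)
  }
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  values <- vapply(stack$frames, function(f) mean(f[mask]), numeric(1L))
  structure(
    list(values = values,
         times = (stack$frame_indices - 1L) * stack$dt,
         frame_indices = stack$frame_indices),
    class = "time_intensity_curve"
  )
}

#' @export
print.time_intensity_curve <- function(x, ...) {
  cat(sprintf("<time_intensity_curve> %d points over %.1f s, range [%.4g, %.4g]\n",
              length(x$values), max(x$times) - min(x$times),
          min(x$values), max(x$values)))
  invisible(x)
}

#' Degree-of-smoothness score of a time-intensity curve
#'
#' A scale- and shift-invariant surrogate for motion-artefact severity:
#' `D = sd(t~) / |mean(t~)|`, where `t~` is the first-differenced curve
#' (`t~[i] = t[i+1] - t[i]`); differencing avoids assuming stationarity, and
#' dividing by the absolute mean difference makes the score invariant to
#' rescaling the intensities. Smaller is smoother; a strictly linear ramp
#' scores exactly 0. The sample standard deviation (denominator `m - 2` for
#' `m - 1` differences) is used. A curve whose differences sum to zero (e.g. a
#' constant curve) yields `Inf` with a warning.
#'
#' @param curve a `time_intensity_curve` from [time_intensity_curve()], or a
#'   plain numeric vector of length >= 3.
#' @return a non-negative scalar (possibly `Inf`).
#' @export
degree_of_smoothness <- function(curve) {
  values <- if (inherits(curve, "time_intensity_curve")) curve$values else curve
  stopifnot(is.numeric(values), length(values) >= 3L)
  d <- diff(values)
  mu <- mean(d)
  if (mu == 0) {
    warning("mean of differenced curve is zero; degree of smoothness is Inf",
            call. = FALSE)
    return(Inf)
  }
  stats::sd(d) / abs(mu)
}
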