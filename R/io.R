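#' Read an image sequence into a frame stack
#'
#' Supported containers: a multi-page TIFF, a directory of single-frame PNG or
#' TIFF files (taken in lexicographic name order), or a NIfTI stack whose
#' third axis is time. Intensities are read as stored (integer types promoted
#' to double); colour frames are collapsed to grayscale by channel averaging.
#'
#' @param path file or directory path.
#' @param format `"auto"` (by extension / file type), `"tiff"`, `"dir"` or
#'   `"nifti"`.
#' @param dt inter-frame interval in seconds (default 1.5).
#' @return a [frame_stack].
#' @export
read_sequence <- function(path, format = c("auto", "tiff", "dir", "nifti"),
                          dt = 1.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path,
                               call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dir"
      else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
      else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
      else stop("cannot infer format of ", path, call. = FALSE)
  }
  frames <- switch(format,
    tiff = {
      imgs <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
      if (!is.list(imgs)) imgs <- list(imgs)
      lapply(imgs, collapse_gray)
    },
    dir = {
      files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                               ignore.case = TRUE, full.names = TRUE))
      if (length(files) < 2L) stop("directory ", path,
                                   " holds fewer than 2 frame images",
                                   call. = FALSE)
      lapply(files, function(f) {
        img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
          png::readPNG(f)
        } else tiff::readTIFF(f)
        collapse_gray(img)
      })
    },
    nifti = {
      vol <- RNifti::readNifti(path)
      a <- as.array(vol)
      if (length(dim(a)) == 4L && dim(a)[4L] == 1L) dim(a) <- dim(a)[1:3]
      if (length(dim(a)) != 3L) {
        stop("NIfTI at ", path, " is not a 3-D stack (axes row, col, time)",
             call. = FALSE)
      }
      lapply(seq_len(dim(a)[3L]), function(t) a[, , t])
    }
  )
  frame_stack(frames, dt = dt)
}

collapse_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  storage.mode(img) <- "double"
  img
}

#' Write a frame stack to disk
#'
#' NIfTI (`.nii`) preserves intensities losslessly (64-bit float) and is the
#' recommended interchange format. Multi-page TIFF is written as 32-bit float
#' after min-max normalisation to [0, 1] (the TIFF container stores values
#' outside that range unreliably); the applied offset and scale are returned
#' invisibly so intensities can be undone downstream.
#'
#' @param stack a [frame_stack].
#' @param path output path; format inferred from the extension (`.nii` /
#'   `.nii.gz` or `.tif` / `.tiff`).
#' @param normalize for TIFF only: min-max normalise to [0, 1] (default TRUE).
#' @return invisibly, a list with `path`, `offset` and `scale` such that
#'   `stored = (value - offset) / scale`.
#' @export
write_sequence <- function(stack, path, normalize = TRUE) {
  stopifnot(is_frame_stack(stack))
  offset <- 0; scale <- 1
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- array(0, c(stack$m, stack$n, stack$N))
    for (t in seq_len(stack$N)) a[, , t] <- stack$frames[[t]]
    RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    frames <- stack$frames
    if (normalize) {
      lo <- min(vapply(frames, min, numeric(1L)))
      hi <- max(vapply(frames, max, numeric(1L)))
      offset <- lo
      scale <- if (hi > lo) hi - lo else 1
      frames <- lapply(frames, function(f) (f - offset) / scale)
    }
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  } else {
    stop("unsupported output extension for ", path, call. = FALSE)
  }
  invisible(list(path = path, offset = offset, scale = scale))
}

#' Read a binary ROI mask
#'
#' Nonzero pixels are in-ROI. PNG and NIfTI masks are supported.
#'
#' @param path mask file path.
#' @return a logical matrix.
#' @export
read_roi_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    collapse_gray(png::readPNG(path))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    a
  } else stop("unsupported mask format: ", path, call. = FALSE)
  img != 0
}

#' Write a binary mask as PNG
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @export
write_roi_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Serialise a motion profile to CSV
#' @param profile a `motion_profile`.
#' @param path output `.csv` path.
#' @export
write_motion_profile <- function(profile, path) {
  stopifnot(inherits(profile, "motion_profile"))
  utils::write.csv(
    data.frame(frame_a = profile$pairs[, 1L], frame_b = profile$pairs[, 2L],
               mean_magnitude_px = profile$per_pair),
    path, row.names = FALSE)
  invisible(path)
}

#' Serialise a time-intensity curve to CSV
#' @param curve a `time_intensity_curve`.
#' @param path output `.csv` path.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "time_intensity_curve"))
  utils::write.csv(
    data.frame(frame_index = curve$frame_indices, time_s = curve$times,
               mean_intensity = curve$values),
    path, row.names = FALSE)
  invisible(path)
}

#' Eigenvalue table of a decomposition
#'
#' One row per mode: eigenvalue real/imaginary parts, modulus, phase angle,
#' continuous-time frequency, and whether the mode survives conjugate pruning
#' (with its significance rank).
#'
#' @param decomp a `dmd_decomposition`.
#' @param ordering a `mode_ordering`; defaults to [order_modes()] of `decomp`.
#' @return a data frame.
#' @export
eigenvalue_table <- function(decomp, ordering = order_modes(decomp)) {
  s <- decomp$eigenvalues
  rank <- match(seq_along(s), ordering$kept_indices)
  data.frame(index = seq_along(s),
             re_sigma = Re(s), im_sigma = Im(s),
             mod_sigma = Mod(s), phase = Arg(s),
             re_mu = Re(decomp$frequencies), im_mu = Im(decomp$frequencies),
             kept = !is.na(rank), significance_rank = rank)
}

#' Write mode images
#'
#' Each selected dynamic mode is written twice: the raw real part as lossless
#' NIfTI, and a min-max-normalised 8-bit PNG preview (modes carry arbitrary
#' scale and sign, so previews are for inspection only).
#'
#' @param decomp a `dmd_decomposition` holding frame geometry.
#' @param indices mode indices to write (default: all).
#' @param dir output directory, created if needed.
#' @param prefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
write_mode_images <- function(decomp, indices = seq_len(decomp$d),
                              dir = ".", prefix = "mode") {
  stopifnot(!is.null(decomp$frame_dim))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  for (j in indices) {
    img <- Re(matrix_to_frame(decomp$modes[, j],
                              decomp$frame_dim[1L], decomp$frame_dim[2L]))
    raw_path <- file.path(dir, sprintf("%s_%03d.nii", prefix, j))
    RNifti::writeNifti(RNifti::asNifti(img, datatype = "double"), raw_path)
    rng <- range(img)
    prev <- if (rng[2L] > rng[1L]) (img - rng[1L]) / diff(rng) else img * 0
    png_path <- file.path(dir, sprintf("%s_%03d.png", prefix, j))
    png::writePNG(prev, png_path)
    paths <- c(paths, raw_path, png_path)
  }
  invisible(paths)
}
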