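#' Stack of synthetic bright-field frames
#'
#' @param frames List of equal-dimension numeric matrices (one per frame).
#' @param pixel_size Pixel size, nm/px.
#' @param frame_rate Acquisition rate, Hz.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size = 100, frame_rate = 25) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, is.matrix, logical(1))),
            pixel_size > 0, frame_rate > 0)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(fr) identical(dim(fr), d), logical(1)))) {
    stop("all frames must share the same dimensions")
  }
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_rate = frame_rate),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame stack: %d frames of %dx%d px (%g nm/px, %g Hz)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_rate))
  invisible(x)
}

#' Render synthetic bead images from a trajectory
#'
#' Places a radially symmetric Gaussian intensity spot (unit amplitude,
#' width `psf_width` pixels) at each bead position on a `frame_dim` canvas,
#' with additive Gaussian pixel noise of standard deviation `1/snr`
#' (`snr = Inf` for noiseless frames). The trajectory origin maps to the
#' frame centre; every position must keep a margin of at least
#' `3 * psf_width` pixels from the frame edge.
#'
#' @param traj A [tpm_trajectory()] (positions in nm).
#' @param frame_dim Frame size in pixels, `c(rows, cols)`.
#' @param psf_width Spot Gaussian width, px.
#' @param snr Peak signal-to-noise ratio.
#' @param pixel_size Pixel size, nm/px.
#' @param seed Integer seed for the pixel noise, or NULL.
#' @return A [frame_stack()].
#' @export
render_bead_frames <- function(traj, frame_dim = c(48, 48), psf_width = 2,
                               snr = 20, pixel_size = 100, seed = NULL) {
  stopifnot(inherits(traj, "tpm_trajectory"), length(frame_dim) == 2L,
            all(frame_dim >= 8), psf_width > 0, snr > 0, pixel_size > 0)
  cx <- traj$x / pixel_size + (frame_dim[2] + 1) / 2
  cy <- traj$y / pixel_size + (frame_dim[1] + 1) / 2
  margin <- 3 * psf_width
  if (any(cx < margin) || any(cx > frame_dim[2] - margin + 1) ||
      any(cy < margin) || any(cy > frame_dim[1] - margin + 1)) {
    stop("bead out of frame: positions violate the 3*psf_width margin")
  }
  rows <- seq_len(frame_dim[1])
  cols <- seq_len(frame_dim[2])
  with_seed(seed, {
    frames <- lapply(seq_along(cx), function(i) {
      gy <- exp(-(rows - cy[i])^2 / (2 * psf_width^2))
      gx <- exp(-(cols - cx[i])^2 / (2 * psf_width^2))
      fr <- outer(gy, gx)
      if (is.finite(snr)) {
        fr <- fr + matrix(stats::rnorm(length(fr), sd = 1 / snr),
                          nrow = frame_dim[1])
      }
      fr
    })
    frame_stack(frames, pixel_size = pixel_size,
                frame_rate = traj$sample_rate)
  })
}

#' Track the bead centroid through a frame stack
#'
#' Per frame, the background is taken as the median pixel value and the
#' intensity-weighted centroid is computed over pixels whose
#' background-subtracted intensity exceeds `threshold_fraction` of the frame
#' maximum. A frame is flagged missing when no localised spot is present:
#' either the peak does not rise above the pixel-noise floor, or the
#' thresholded region covers more than a quarter of the frame.
#'
#' @param stack A [frame_stack()].
#' @param threshold_fraction Fraction of the (background-subtracted) peak
#'   used as the centroid support threshold.
#' @return A data frame `t`, `x_nm`, `y_nm`, `flagged`; positions are `NA`
#'   on flagged frames. Positions are relative to the frame centre.
#' @export
track_centroid <- function(stack, threshold_fraction = 0.5) {
  stopifnot(inherits(stack, "frame_stack"),
            threshold_fraction > 0, threshold_fraction < 1)
  d <- dim(stack$frames[[1]])
  ctr_x <- (d[2] + 1) / 2
  ctr_y <- (d[1] + 1) / 2
  res <- lapply(stack$frames, function(fr) {
    bg <- stats::median(fr)
    peak <- max(fr)
    noise <- stats::mad(fr)
    if (peak - bg <= max(5 * noise, 1e-12)) {
      return(c(NA_real_, NA_real_, TRUE))
    }
    mask <- fr - bg >= threshold_fraction * (peak - bg)
    if (sum(mask) > 0.25 * length(fr)) {
      return(c(NA_real_, NA_real_, TRUE))
    }
    w <- (fr - bg)[mask]
    ij <- which(mask, arr.ind = TRUE)
    c(sum(w * ij[, 2]) / sum(w), sum(w * ij[, 1]) / sum(w), FALSE)
  })
  res <- do.call(rbind, res)
  data.frame(
    t = (seq_len(nrow(res)) - 1) / stack$frame_rate,
    x_nm = (res[, 1] - ctr_x) * stack$pixel_size,
    y_nm = (res[, 2] - ctr_y) * stack$pixel_size,
    flagged = as.logical(res[, 3]))
}

#' Convert tracked centroid positions to a trajectory
#'
#' @param tracked Data frame from [track_centroid()].
#' @param bead_id Identifier for the trajectory.
#' @return A [tpm_trajectory()]; errors if any frame was flagged missing.
#' @export
tracked_to_trajectory <- function(tracked, bead_id = "tracked") {
  stopifnot(is.data.frame(tracked),
            all(c("t", "x_nm", "y_nm", "flagged") %in% names(tracked)))
  if (any(tracked$flagged)) {
    stop(sum(tracked$flagged), " flagged frame(s); cannot build a trajectory")
  }
  tpm_trajectory(tracked$t, tracked$x_nm, tracked$y_nm, bead_id = bead_id)
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are linearly rescaled to the unit interval per stack; the
#' storage is meant for inspection and re-tracking, both of which are
#' invariant under global intensity scaling. Requires the suggested `tiff`
#' package.
#'
#' @param stack A [frame_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF stacks")
  }
  lo <- min(vapply(stack$frames, min, numeric(1)))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  rng <- max(hi - lo, 1e-12)
  tiff::writeTIFF(lapply(stack$frames, function(fr) (fr - lo) / rng), path)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' @param path Input path.
#' @param pixel_size Pixel size, nm/px.
#' @param frame_rate Acquisition rate, Hz.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, pixel_size = 100, frame_rate = 25) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF stacks")
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  frame_stack(frames, pixel_size = pixel_size, frame_rate = frame_rate)
}
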