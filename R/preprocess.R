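#' Crop every frame of a stack
#'
#' Exact sub-array extraction, no resampling.  The crop box is 0-based and
#' half-open: `(row0, col0, height, width)` keeps rows `row0 .. row0+height-1`.
#'
#' @param stack A `frame_stack`.
#' @param crop_box Integer vector `c(row0, col0, height, width)`.
#' @return The cropped `frame_stack`.
#' @export
crop_stack <- function(stack, crop_box) {
  stopifnot(inherits(stack, "frame_stack"), length(crop_box) == 4)
  d <- dim(stack$frames)
  r0 <- crop_box[1]; c0 <- crop_box[2]; h <- crop_box[3]; w <- crop_box[4]
  if (r0 < 0 || c0 < 0 || h < 1 || w < 1 ||
      r0 + h > d[1] || c0 + w > d[2])
    stop("crop_box (", paste(crop_box, collapse = ", "),
         ") exceeds frame bounds ", d[1], " x ", d[2])
  out <- stack
  out$frames <- stack$frames[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), ,
                             drop = FALSE]
  if (!is.null(out$config)) {
    out$config$frame_height <- as.integer(h)
    out$config$frame_width <- as.integer(w)
  }
  out
}

# Gaussian high-pass transfer function on the (u, v) cycles-per-frame grid.
.highpass_transfer <- function(H, W, sigma) {
  f2 <- outer(fft_freq(H)^2, fft_freq(W)^2, `+`)
  1 - exp(-f2 / (2 * sigma^2))
}

#' Fourier-domain Gaussian high-pass filter
#'
#' Removes the smooth fluorescent background from each frame by multiplying
#' its spectrum with `1 - exp(-f^2 / (2 sigma^2))`, `f` in cycles per frame —
#' equivalently subtracting a Gaussian-blurred copy.  The DC component of
#' every filtered frame is exactly zero before clipping.  Filtering is
#' per-frame (no temporal mixing) and circular; frames are much larger than
#' the filter scale so wrap-around bias is negligible.
#'
#' The default `highpass_sigma = 2` suppresses only the lowest couple of
#' spatial frequencies: the background varies over the whole frame while the
#' speckle grains of interest live tens of cycles up.
#'
#' @param stack A `frame_stack` with finite values.
#' @param highpass_sigma Gaussian cutoff in cycles per frame (> 0).
#' @param clip_mode `"clip_zero"` sets post-filter negatives to 0 (default:
#'   preserves sparse speckle structure); `"shift_min"` subtracts the
#'   per-frame minimum instead.
#' @return Filtered non-negative `frame_stack`.
#' @export
highpass_filter <- function(stack, highpass_sigma = 2,
                            clip_mode = c("clip_zero", "shift_min")) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(inherits(stack, "frame_stack"))
  if (highpass_sigma <= 0) stop("highpass_sigma must be > 0")
  stopifnot_finite(stack$frames, "frame stack")
  d <- dim(stack$frames)
  tf <- .highpass_transfer(d[1], d[2], highpass_sigma)
  out <- stack
  for (t in seq_len(d[3])) {
    f <- Re(ifft2(fft2(stack$frames[, , t]) * tf))
    if (clip_mode == "clip_zero") f[f < 0] <- 0 else f <- f - min(f)
    out$frames[, , t] <- f
  }
  out
}
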