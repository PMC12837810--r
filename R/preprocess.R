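# Input pipeline: gradient-based B-scan cropping, canonical bilinear resize to
# the network input size with channel replication, and per-image Z-score
# normalization.

#' Per-column horizontal gradient profile
#'
#' Mean absolute first-order column difference, averaged over rows. The profile
#' has one value per column; column 1 (which has no left neighbour) gets 0.
#' Coordinates are 1-based; the boundary column reported by [crop_bscan()] is
#' the first column of the retained region.
#'
#' @param img H x W matrix.
#' @return List with `profile` (length W) and `peak_index`.
#' @export
gradient_profile <- function(img) {
  W <- ncol(img)
  if (W < 3L) stopf("image must have at least 3 columns")
  prof <- c(0, colMeans(abs(img[, -1L, drop = FALSE] -
                              img[, -W, drop = FALSE])))
  list(profile = prof, peak_index = which.max(prof))
}

#' Crop a B-scan at the horizontal-gradient peak
#'
#' Computes the per-column mean absolute horizontal difference and takes the
#' profile argmax as the boundary: the sub-image from that column rightwards is
#' returned (flip `side = "left"` for the opposite convention). If the peak is
#' not at least `min_peak_ratio` times the median profile value (or the image
#' is constant), the input is returned unchanged with a logged notice.
#'
#' @param raw H x W matrix, W >= 3.
#' @param min_peak_ratio Prominence ratio of peak over median profile.
#' @param side Keep the region to the "right" (default) or "left" of the peak.
#' @return The cropped matrix, with attributes `boundary` (column index) and
#'   `cropped` (logical).
#' @export
crop_bscan <- function(raw, min_peak_ratio = 3, side = c("right", "left")) {
  side <- match.arg(side)
  gp <- gradient_profile(raw)
  med <- stats::median(gp$profile)
  peak <- gp$profile[gp$peak_index]
  if (peak <= 0 || (med > 0 && peak < min_peak_ratio * med)) {
    notice("no prominent gradient boundary found; image returned uncropped")
    out <- raw
    attr(out, "boundary") <- NA_integer_
    attr(out, "cropped") <- FALSE
    return(out)
  }
  b <- gp$peak_index
  out <- if (side == "right") raw[, b:ncol(raw), drop = FALSE]
         else raw[, seq_len(max(b - 1L, 1L)), drop = FALSE]
  attr(out, "boundary") <- b
  attr(out, "cropped") <- TRUE
  out
}

#' Resize to the canonical network input
#'
#' Bilinear resize to `size` x `size`; grayscale inputs are replicated to three
#' channels. The identity case (already canonical) is returned untouched.
#'
#' @param img H x W matrix or H x W x 3 array.
#' @param size Output side length (default 512).
#' @return A `size` x `size` x 3 array.
#' @export
resize_canonical <- function(img, size = 512L) {
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3)
    out[, , ch] <- EBImage::resize(img[, , ch], w = size, h = size)
  out
}

#' Per-image Z-score normalization
#'
#' `(x - mean) / sd` over all elements (channels share one statistic); an
#' (effectively) constant input yields an all-zero output with a logged notice
#' (sd floor 1e-8). The operation is idempotent to within 1e-6.
#'
#' @param img Numeric array; must be finite.
#' @return Array of the same shape with mean 0 and sd 1 (or all zeros).
#' @export
zscore <- function(img) {
  if (!all(is.finite(img))) stopf("zscore: input contains non-finite values")
  s <- stats::sd(img)
  if (is.na(s) || s < 1e-8) {
    notice("constant image in zscore; returning zeros")
    return(img * 0)
  }
  (img - mean(img)) / s
}

#' Full preprocessing pipeline for one image
#'
#' Crop (OCT only), canonical resize, Z-score, in that order.
#'
#' @param img Matrix (OCT) or array (UWF).
#' @param size Canonical side length.
#' @param crop Apply the gradient crop (disable for UWF inputs).
#' @param min_peak_ratio Passed to [crop_bscan()].
#' @return `size` x `size` x 3 normalized array.
#' @export
preprocess_image <- function(img, size = 512L, crop = TRUE,
                             min_peak_ratio = 3) {
  if (crop && length(dim(img)) == 2L)
    img <- crop_bscan(img, min_peak_ratio = min_peak_ratio)
  zscore(resize_canonical(img, size = size))
}
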