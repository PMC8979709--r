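#' Rectangular region of interest
#'
#' 0-based, half-open pixel coordinates: the ROI covers rows
#' `top .. top + height - 1` and columns `left .. left + width - 1`.
#'
#' @param top,left Upper-left corner (0-based).
#' @param height,width Extent in pixels.
#' @return A `ct_roi` object.
#' @export
roi <- function(top, left, height, width) {
  top <- check_count(top, "top", min = 0)
  left <- check_count(left, "left", min = 0)
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  structure(list(top = top, left = left, height = height, width = width),
            class = "ct_roi")
}

roi_values <- function(image, r, what = "roi") {
  if (!inherits(image, "image_grid")) stop_ct("`image` must be an image_grid")
  if (!inherits(r, "ct_roi")) stop_ct("`", what, "` must be a roi()")
  d <- dim(image)
  if (r$top + r$height > d[1] || r$left + r$width > d[2])
    stop_ct(sprintf("%s [%d+%d, %d+%d] lies outside the %d x %d image",
                    what, r$top, r$height, r$left, r$width, d[1], d[2]))
  image$values[r$top + seq_len(r$height), r$left + seq_len(r$width)]
}

#' Mean squared error between two images
#'
#' `MSE = (1 / M) * sum_i (y_i - yhat_i)^2` over all `M` pixels of the
#' compared images. Symmetric, non-negative, zero iff the images are
#' identical.
#'
#' @param reference,estimate [image_grid()]s of identical dimensions.
#' @return Non-negative scalar.
#' @export
mse <- function(reference, estimate) {
  if (!inherits(reference, "image_grid") || !inherits(estimate, "image_grid"))
    stop_ct("`reference` and `estimate` must be image_grids")
  if (!all(dim(reference) == dim(estimate)))
    stop_ct("`reference` and `estimate` dimensions differ")
  mean((reference$values - estimate$values)^2)
}

#' ROI noise (sample standard deviation)
#'
#' Standard deviation (denominator `n - 1`) of the pixel values inside a
#' declared uniform ROI — the operational image-noise measure.
#'
#' @param image An [image_grid()].
#' @param roi A [roi()] with at least 2 pixels, inside the image.
#' @return Non-negative scalar.
#' @export
noise_std <- function(image, roi) {
  v <- roi_values(image, roi)
  if (length(v) < 2) stop_ct("noise ROI must contain at least 2 pixels")
  sd(v)
}

#' Signal-to-noise ratio
#'
#' Mean of the signal ROI divided by the noise standard deviation of the
#' background ROI.
#'
#' @param image An [image_grid()].
#' @param signal_roi,background_roi [roi()]s inside the image.
#' @return Scalar SNR.
#' @export
snr <- function(image, signal_roi, background_roi) {
  s <- mean(roi_values(image, signal_roi, "signal_roi"))
  n <- noise_std(image, background_roi)
  if (n == 0) stop_ct("background ROI has zero standard deviation ",
                      sprintf("(top %d, left %d)", background_roi$top,
                              background_roi$left))
  s / n
}

#' Low-contrast measure between two ROIs
#'
#' Absolute difference of ROI means; symmetric in its ROIs.
#'
#' @param image An [image_grid()].
#' @param roi_a,roi_b [roi()]s inside the image.
#' @return Non-negative scalar.
#' @export
contrast <- function(image, roi_a, roi_b) {
  abs(mean(roi_values(image, roi_a, "roi_a")) -
        mean(roi_values(image, roi_b, "roi_b")))
}

#' Full image-quality report
#'
#' @param reference Ground-truth [image_grid()].
#' @param estimate Reconstructed [image_grid()].
#' @param rois A named list with entries `uniform` (noise ROI), `signal`
#'   and `background` (SNR ROIs), and optionally `contrast_a` /
#'   `contrast_b`; see [default_rois()].
#' @return A one-row tibble: `mse`, `noise_std`, `snr`, `contrast` (`NA`
#'   when contrast ROIs are absent).
#' @export
metric_report <- function(reference, estimate, rois = default_rois(reference)) {
  tibble::tibble(
    mse = mse(reference, estimate),
    noise_std = noise_std(estimate, rois$uniform),
    snr = snr(estimate, rois$signal, rois$background),
    contrast = if (is.null(rois$contrast_a) || is.null(rois$contrast_b))
      NA_real_
    else contrast(estimate, rois$contrast_a, rois$contrast_b)
  )
}

#' Default ROI layout for a centred phantom
#'
#' `uniform` and `signal`: a `h/8`-sized block at the image centre (inside
#' the object for any centred phantom wider than a quarter of the grid);
#' `background`: a same-sized block at mid-height near the left edge
#' (air, but inside the reconstruction circle).
#'
#' @param image An [image_grid()] (only its dimensions are used).
#' @return Named list of [roi()]s.
#' @export
default_rois <- function(image) {
  d <- dim(image)
  side <- max(2L, as.integer(d[1] %/% 8))
  centre_top <- as.integer((d[1] - side) %/% 2)
  centre_left <- as.integer((d[2] - side) %/% 2)
  edge_left <- max(0L, as.integer(d[2] %/% 16))
  list(
    uniform = roi(centre_top, centre_left, side, side),
    signal = roi(centre_top, centre_left, side, side),
    background = roi(centre_top, edge_left, side, side)
  )
}
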