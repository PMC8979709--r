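#' Parallel-beam acquisition geometry
#'
#' Defines the sampling of the Radon transform: `num_angles` view angles in
#' `[0, pi)` and `num_bins` detector bins with physical spacing
#' `bin_spacing` mm. Rays pass through bin centres, one ray per bin; bin
#' centre offsets are `(k - (Y - 1) / 2) * bin_spacing` so the detector is
#' centred on the rotation axis.
#'
#' @param num_angles Number of view angles (ignored when `angles` given).
#' @param angles Optional vector of angles in radians, strictly increasing
#'   within `[0, pi)`. Defaults to `num_angles` uniformly spaced values.
#' @param num_bins Number of detector bins. `NULL` defers to
#'   [default_num_bins()] at use time.
#' @param bin_spacing Detector bin spacing in mm. Default 1.
#'
#' @return A `ct_geometry` object.
#' @export
ct_geometry <- function(num_angles = 180L, angles = NULL, num_bins = NULL,
                        bin_spacing = 1) {
  if (is.null(angles)) {
    num_angles <- check_count(num_angles, "num_angles")
    angles <- seq(0, pi, length.out = num_angles + 1L)[seq_len(num_angles)]
  }
  if (length(angles) < 1 || any(!is.finite(angles)))
    stop_ct("`angles` must be a non-empty finite vector")
  if (any(angles < 0) || any(angles >= pi))
    stop_ct("all angles must lie in [0, pi)")
  if (length(angles) > 1 && any(diff(angles) <= 0))
    stop_ct("`angles` must be strictly increasing")
  if (!is.null(num_bins)) num_bins <- check_count(num_bins, "num_bins")
  if (!is.numeric(bin_spacing) || length(bin_spacing) != 1 || bin_spacing <= 0)
    stop_ct("`bin_spacing` must be a single positive number (mm)")
  structure(list(angles = as.numeric(angles), num_bins = num_bins,
                 bin_spacing = as.numeric(bin_spacing)),
            class = "ct_geometry")
}

#' Default detector bin count for an image
#'
#' `ceiling(sqrt(2) * max(height, width))` bins: at `bin_spacing` equal to
#' `pixel_size` this spans the image diagonal, the coverage the projector
#' requires.
#'
#' @param height,width Image size in pixels.
#' @return Integer bin count.
#' @export
default_num_bins <- function(height, width) {
  as.integer(ceiling(sqrt(2) * max(height, width)))
}

# Resolve deferred fields and check detector coverage against an image.
bind_geometry <- function(geometry, height, width, pixel_size) {
  if (!inherits(geometry, "ct_geometry"))
    stop_ct("`geometry` must be a ct_geometry")
  if (is.null(geometry$num_bins))
    geometry$num_bins <- default_num_bins(height, width)
  diag_mm <- pixel_size * sqrt(height^2 + width^2)
  if (geometry$num_bins * geometry$bin_spacing < diag_mm)
    stop_ct(sprintf(
      "detector (%d bins x %g mm) does not cover the image diagonal %.2f mm",
      geometry$num_bins, geometry$bin_spacing, diag_mm))
  geometry
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf("<ct_geometry> %d angles in [%.3f, %.3f] rad, %s bins x %g mm\n",
              length(x$angles), min(x$angles), max(x$angles),
              if (is.null(x$num_bins)) "auto" else x$num_bins, x$bin_spacing))
  invisible(x)
}

#' Sinogram container
#'
#' Projection data: a `num_angles x num_bins` matrix of line integrals
#' (attenuation x mm), one row per view angle.
#'
#' @param values Numeric `X x Y` matrix of line integrals.
#' @param geometry A bound [ct_geometry()] with `num_bins` set.
#' @return A `sinogram` object.
#' @export
sinogram <- function(values, geometry) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_ct("`values` must be a numeric matrix")
  if (!inherits(geometry, "ct_geometry") || is.null(geometry$num_bins))
    stop_ct("`geometry` must be a ct_geometry with num_bins set")
  if (nrow(values) != length(geometry$angles) ||
      ncol(values) != geometry$num_bins)
    stop_ct(sprintf("sinogram shape %d x %d does not match geometry %d x %d",
                    nrow(values), ncol(values), length(geometry$angles),
                    geometry$num_bins))
  if (!all(is.finite(values)))
    stop_ct("sinogram values must all be finite")
  structure(list(values = unname(values), geometry = geometry),
            class = "sinogram")
}

#' @export
dim.sinogram <- function(x) dim(x$values)

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d bins, value range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Forward projection (Radon transform)
#'
#' Line-integral projection of an image under parallel-beam geometry, via
#' exact Siddon ray--pixel intersection lengths. Matrix-free, but agrees
#' with `entries %*% flatten_image(image)` of [build_system_matrix()] to
#' rounding error because both share one traversal.
#'
#' @param image An [image_grid()].
#' @param geometry A [ct_geometry()]; `num_bins = NULL` is resolved with
#'   [default_num_bins()].
#' @return A [sinogram()].
#' @export
project <- function(image, geometry) {
  if (!inherits(image, "image_grid")) stop_ct("`image` must be an image_grid")
  d <- dim(image)
  geometry <- bind_geometry(geometry, d[1], d[2], image$pixel_size)
  vals <- cpp_project(image$values, image$pixel_size, geometry$angles,
                      geometry$num_bins, geometry$bin_spacing)
  sinogram(vals, geometry)
}

#' Back projection (adjoint of the forward projector)
#'
#' Implements the exact transpose of [project()] under the same
#' discretization: `<project(x), y> == <x, backproject(y)>` for any `x`,
#' `y`. Note this is the unfiltered adjoint, not an inverse; see
#' [fbp_reconstruct()] for the calibrated inversion.
#'
#' @param sino A [sinogram()].
#' @param height,width Output image size in pixels.
#' @param pixel_size Pixel edge length in mm.
#' @return An [image_grid()].
#' @export
backproject <- function(sino, height, width, pixel_size = 1) {
  if (!inherits(sino, "sinogram")) stop_ct("`sino` must be a sinogram")
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  geometry <- bind_geometry(sino$geometry, height, width, pixel_size)
  if (geometry$num_bins != ncol(sino$values))
    stop_ct("sinogram bin count does not match its geometry")
  vals <- cpp_backproject(sino$values, height, width, pixel_size,
                          geometry$angles, geometry$bin_spacing)
  image_grid(vals, pixel_size)
}

#' Explicit sparse system matrix
#'
#' The discrete forward model as a sparse `(X * Y) x (height * width)`
#' matrix of ray--pixel intersection lengths (mm). Rows are ordered
#' angle-major then bin; columns are row-major pixels (see
#' [flatten_image()]). Intended for small grids where the dense
#' pseudo-inverse algebra is tractable.
#'
#' @inheritParams backproject
#' @param geometry A [ct_geometry()].
#' @return A `system_matrix` object with fields `entries`
#'   (a [Matrix::sparseMatrix()]), `geometry`, `height`, `width`,
#'   `pixel_size`.
#' @export
build_system_matrix <- function(geometry, height, width, pixel_size = 1) {
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  geometry <- bind_geometry(geometry, height, width, pixel_size)
  tr <- cpp_system_matrix(height, width, pixel_size, geometry$angles,
                          geometry$num_bins, geometry$bin_spacing)
  entries <- Matrix::sparseMatrix(
    i = tr$i, j = tr$j, x = tr$x,
    dims = c(length(geometry$angles) * geometry$num_bins, height * width)
  )
  structure(list(entries = entries, geometry = geometry, height = height,
                 width = width, pixel_size = pixel_size),
            class = "system_matrix")
}

#' @export
dim.system_matrix <- function(x) dim(x$entries)

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d rays x %d pixels, %d nonzeros\n",
              nrow(x$entries), ncol(x$entries),
              length(x$entries@x)))
  invisible(x)
}
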