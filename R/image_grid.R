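#' 2-D attenuation image
#'
#' An `image_grid` is the package's container for a two-dimensional map of
#' linear attenuation values: the phantom fed to the forward projector, and
#' the output of every reconstruction. Values are stored as a numeric
#' `height x width` matrix with a physical pixel edge length in millimetres.
#'
#' @param values Numeric matrix (`height x width`) of finite attenuation
#'   values. Phantom generators keep values in `[0, 1]`; reconstructions may
#'   leave that range.
#' @param pixel_size Pixel edge length in mm. Default 1.
#'
#' @return An `image_grid` object.
#' @export
image_grid <- function(values, pixel_size = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_ct("`values` must be a numeric matrix")
  if (nrow(values) < 1 || ncol(values) < 1)
    stop_ct("image must have height >= 1 and width >= 1")
  if (!all(is.finite(values)))
    stop_ct("image values must all be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop_ct("`pixel_size` must be a single positive number (mm)")
  structure(
    list(values = unname(values), pixel_size = as.numeric(pixel_size)),
    class = "image_grid"
  )
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' @export
as.matrix.image_grid <- function(x, ...) x$values

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_grid> %d x %d pixels, pixel_size %g mm\n", d[1], d[2],
              x$pixel_size))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Flatten an image to the system-matrix pixel ordering
#'
#' The sparse system matrix orders pixels row-major (`index = i * width + j`
#' with 0-based row `i`, column `j`), so `entries %*% flatten_image(img)`
#' reproduces `project(img, geometry)` exactly.
#'
#' @param image An [image_grid()].
#' @return Numeric vector of length `height * width`.
#' @export
flatten_image <- function(image) {
  as.vector(t(image$values))
}

#' @rdname flatten_image
#' @param x Numeric vector of length `height * width` in row-major order.
#' @param height,width Image dimensions in pixels.
#' @param pixel_size Pixel edge length in mm.
#' @export
unflatten_image <- function(x, height, width, pixel_size = 1) {
  image_grid(matrix(x, nrow = height, ncol = width, byrow = TRUE), pixel_size)
}

#' Convert an image to a long tibble of pixel values
#'
#' @param image An [image_grid()].
#' @return A tibble with columns `row`, `col` (1-based), `x`, `y` (mm,
#'   centred frame), `value`.
#' @export
image_to_tibble <- function(image) {
  d <- dim(image)
  px <- image$pixel_size
  tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    x = (rep(seq_len(d[2]), each = d[1]) - 0.5 - d[2] / 2) * px,
    y = (rep(seq_len(d[1]), times = d[2]) - 0.5 - d[1] / 2) * px,
    value = as.vector(image$values)
  )
}

#' @export
autoplot.image_grid <- function(object, ...) {
  df <- image_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "attenuation")
}
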