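#' Uniform disk phantom
#'
#' A centred disk of constant attenuation on a zero background: the simplest
#' object with a closed-form Radon transform (a chord-length profile), used
#' throughout the package's own tests to calibrate the projector and FBP.
#'
#' A pixel belongs to the disk iff its centre does: pixel centres sit at
#' `(i + 0.5, j + 0.5)` in a frame whose origin is the grid centre, and the
#' disk radius is `radius_fraction * min(height, width)` pixels. No
#' anti-aliasing is applied, so membership is exactly reproducible.
#'
#' @param height,width Grid size in pixels.
#' @param radius_fraction Disk radius as a fraction of `min(height, width)`,
#'   in `(0, 0.5]`.
#' @param value Attenuation inside the disk, in `[0, 1]`.
#' @param pixel_size Pixel edge length in mm. Default 1.
#'
#' @return An [image_grid()] with values in `[0, 1]`.
#' @examples
#' ph <- make_disk_phantom(64, 64, 0.3, 1.0)
#' range(as.matrix(ph))
#' @export
make_disk_phantom <- function(height, width, radius_fraction, value,
                              pixel_size = 1) {
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  if (!is.numeric(radius_fraction) || length(radius_fraction) != 1 ||
      radius_fraction <= 0 || radius_fraction > 0.5)
    stop_ct("`radius_fraction` must lie in (0, 0.5]")
  if (!is.numeric(value) || length(value) != 1 || value < 0 || value > 1)
    stop_ct("`value` must lie in [0, 1]")
  r <- radius_fraction * min(height, width)
  cy <- (seq_len(height) - 0.5) - height / 2
  cx <- (seq_len(width) - 0.5) - width / 2
  inside <- outer(cy^2, cx^2, `+`) <= r^2
  image_grid(matrix(value * inside, height, width), pixel_size)
}

#' Phantom specification
#'
#' Describes a composite-ellipse phantom in the centred unit frame: pixel
#' centres map to `(u, v)` in `[-1, 1]^2` (u along columns, v along rows),
#' and each ellipse contributes its `additive_value` wherever
#' `((u' / a)^2 + (v' / b)^2) <= 1` after rotating by `-rotation_deg` about
#' the ellipse centre. Contributions are summed and clipped to `[0, 1]`.
#'
#' @param kind One of `"disk"`, `"shepp_logan"`, `"lesion"`. The first two
#'   require a non-empty `ellipses` table; `"lesion"` generates a seeded
#'   background + necrotic-focus + ring-enhanced (pseudocyst-like)
#'   composition when `ellipses` is empty.
#' @param ellipses A data frame with columns `center_x`, `center_y` (in
#'   `[-1, 1]`), `semi_axis_a`, `semi_axis_b` (> 0, unit-frame fractions),
#'   `rotation_deg`, `additive_value`. May be empty only for kind
#'   `"lesion"`.
#' @param seed Integer seed controlling any randomised placement.
#'
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(kind = c("disk", "shepp_logan", "lesion"),
                         ellipses = NULL, seed = 0L) {
  kind <- match.arg(kind)
  if (is.null(ellipses))
    ellipses <- tibble::tibble(center_x = numeric(), center_y = numeric(),
                               semi_axis_a = numeric(), semi_axis_b = numeric(),
                               rotation_deg = numeric(),
                               additive_value = numeric())
  ellipses <- tibble::as_tibble(ellipses)
  needed <- c("center_x", "center_y", "semi_axis_a", "semi_axis_b",
              "rotation_deg", "additive_value")
  if (!all(needed %in% names(ellipses)))
    stop_ct("`ellipses` must have columns ", paste(needed, collapse = ", "))
  if (nrow(ellipses) == 0 && kind != "lesion")
    stop_ct("kind '", kind, "' requires a non-empty ellipse list")
  if (nrow(ellipses) > 0) {
    if (any(abs(ellipses$center_x) > 1) || any(abs(ellipses$center_y) > 1))
      stop_ct("ellipse centers must lie in the unit square [-1, 1]^2")
    if (any(ellipses$semi_axis_a <= 0) || any(ellipses$semi_axis_b <= 0))
      stop_ct("ellipse semi-axes must be positive")
  }
  structure(list(kind = kind, ellipses = ellipses,
                 seed = check_count(seed, "seed", min = 0)),
            class = "phantom_spec")
}

# The classical ten-ellipse head phantom, with the additive values rescaled
# so the summed, clipped image stays in [0, 1].
#' Ellipse table of a Shepp-Logan-style head phantom
#' @return A tibble usable as the `ellipses` field of [phantom_spec()].
#' @export
shepp_logan_ellipses <- function() {
  tibble::tibble(
    center_x = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    center_y = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.605, -0.605),
    semi_axis_a = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046,
                    0.023, 0.023),
    semi_axis_b = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023,
                    0.023, 0.046),
    rotation_deg = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
    additive_value = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  )
}

lesion_ellipses <- function(seed) {
  # Background organ + one low-attenuation interior focus (necrosis
  # analogue) + one ring-enhanced region (pseudocyst analogue: bright rim
  # around a darker core). Placement jitter is seeded.
  with_seed(seed, {
    fx <- stats::runif(1, -0.25, 0.25)
    fy <- stats::runif(1, -0.25, 0.25)
    px <- stats::runif(1, -0.3, 0.3)
    py <- stats::runif(1, -0.3, 0.3)
    while (sqrt((px - fx)^2 + (py - fy)^2) < 0.3) {
      px <- stats::runif(1, -0.3, 0.3)
      py <- stats::runif(1, -0.3, 0.3)
    }
    tibble::tibble(
      center_x = c(0, fx, px, px),
      center_y = c(0, fy, py, py),
      semi_axis_a = c(0.75, 0.12, 0.16, 0.10),
      semi_axis_b = c(0.6, 0.09, 0.16, 0.10),
      rotation_deg = c(0, stats::runif(1, 0, 180), 0, 0),
      additive_value = c(0.5, -0.3, 0.4, -0.25)
    )
  })
}

#' Generate a composite-ellipse phantom
#'
#' Renders a [phantom_spec()] onto a pixel grid. Output is deterministic for
#' identical `(spec, height, width)` — bit-identical across calls.
#'
#' @param spec A [phantom_spec()].
#' @param height,width Grid size in pixels.
#' @param pixel_size Pixel edge length in mm. Default 1.
#' @return An [image_grid()] with values clipped to `[0, 1]`.
#' @examples
#' ph <- make_phantom(phantom_spec("lesion", seed = 7), 64, 64)
#' @export
make_phantom <- function(spec, height, width, pixel_size = 1) {
  if (!inherits(spec, "phantom_spec")) stop_ct("`spec` must be a phantom_spec")
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  ell <- spec$ellipses
  if (spec$kind == "lesion" && nrow(ell) == 0)
    ell <- lesion_ellipses(spec$seed)
  u <- ((seq_len(width) - 0.5) - width / 2) / (width / 2)
  v <- ((seq_len(height) - 0.5) - height / 2) / (height / 2)
  U <- matrix(u, height, width, byrow = TRUE)
  V <- matrix(v, height, width)
  img <- matrix(0, height, width)
  for (e in seq_len(nrow(ell))) {
    phi <- ell$rotation_deg[e] * pi / 180
    du <- U - ell$center_x[e]
    dv <- V - ell$center_y[e]
    ur <- cos(phi) * du + sin(phi) * dv
    vr <- -sin(phi) * du + cos(phi) * dv
    inside <- (ur / ell$semi_axis_a[e])^2 + (vr / ell$semi_axis_b[e])^2 <= 1
    img <- img + ell$additive_value[e] * inside
  }
  img <- pmin(pmax(img, 0), 1)
  image_grid(img, pixel_size)
}
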