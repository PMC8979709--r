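#' Low-dose photon-noise model
#'
#' Beer--Lambert photon statistics for a parallel-beam acquisition:
#' `I0` incident photons per detector bin at full dose, thinned by a dose
#' fraction `d`. For a noiseless line integral `p` the detected count is
#' `N ~ Poisson(I0 * d * exp(-p))`; the noisy integral is recovered as
#' `-log(N / (I0 * d))`, so noise grows as dose falls.
#'
#' @param incident_photons Photons per bin at full dose (`I0 >= 1`).
#'   Default `1e5`.
#' @param dose_fraction Dose fraction `d` in `(0, 1]`.
#' @param seed Integer seed; the simulator is bit-reproducible.
#' @return A `noise_model` object.
#' @export
noise_model <- function(incident_photons = 1e5, dose_fraction = 1, seed = 0L) {
  if (!is.numeric(incident_photons) || length(incident_photons) != 1 ||
      incident_photons < 1)
    stop_ct("`incident_photons` must be >= 1")
  if (!is.numeric(dose_fraction) || length(dose_fraction) != 1 ||
      dose_fraction <= 0 || dose_fraction > 1)
    stop_ct("`dose_fraction` must lie in (0, 1]")
  structure(list(incident_photons = as.numeric(incident_photons),
                 dose_fraction = as.numeric(dose_fraction),
                 seed = check_count(seed, "seed", min = 0)),
            class = "noise_model")
}

#' Simulate a low-dose acquisition
#'
#' Replaces each noiseless line integral `p` with
#' `-log(N / (I0 * d))`, `N ~ Poisson(I0 * d * exp(-p))`. Zero counts are
#' floored to one photon before the log so the result stays finite
#' (photon starvation handling). Identical `(sino, model)` give
#' bit-identical output.
#'
#' @param sino A noiseless [sinogram()] with non-negative values.
#' @param model A [noise_model()].
#' @return A noisy [sinogram()].
#' @examples
#' sg <- project(make_disk_phantom(32, 32, 0.3, 0.5), ct_geometry(45))
#' noisy <- simulate_low_dose(sg, noise_model(1e4, 0.5, seed = 1))
#' @export
simulate_low_dose <- function(sino, model) {
  if (!inherits(sino, "sinogram")) stop_ct("`sino` must be a sinogram")
  if (!inherits(model, "noise_model")) stop_ct("`model` must be a noise_model")
  p <- sino$values
  if (any(p < 0)) stop_ct("sinogram must be non-negative (line integrals)")
  flux <- model$incident_photons * model$dose_fraction
  counts <- with_seed(model$seed,
                      rpois(length(p), lambda = flux * exp(-as.vector(p))))
  counts[counts == 0] <- 1
  phat <- -log(counts / flux)
  sinogram(matrix(phat, nrow(p), ncol(p)), sino$geometry)
}

#' Dose-ladder simulation study
#'
#' The dose-reduction experiment: for each dose fraction, simulate a noisy
#' acquisition of the same object, reconstruct with plain FBP and with
#' iterative FBP, and evaluate ROI noise, MSE against the true object, and
#' SNR. One row per `(dose_fraction, method)`. Per-fraction noise seeds are
#' derived from `seed` by fixed offsets (`seed + 1000 * index`), so each
#' arm is independently reproducible.
#'
#' @param image Ground-truth [image_grid()].
#' @param geometry A [ct_geometry()].
#' @param fractions Dose fractions in `(0, 1]`. Default `c(1, 0.75, 0.5)`.
#' @param incident_photons Full-dose photons per bin. Default `1e4`.
#' @param seed Master seed.
#' @param config A [recon_config()] for the iterative arm (its `filter` is
#'   shared by the FBP arm).
#' @param rois ROI layout, see [metric_report()].
#' @return A `dose_ladder` tibble: `dose_fraction`, `method`
#'   (`"fbp"` / `"ifbp"`), `noise_std`, `mse`, `snr`.
#' @export
dose_ladder <- function(image, geometry, fractions = c(1, 0.75, 0.5),
                        incident_photons = 1e4, seed = 0L,
                        config = recon_config(),
                        rois = default_rois(image)) {
  if (!inherits(image, "image_grid")) stop_ct("`image` must be an image_grid")
  if (any(fractions <= 0) || any(fractions > 1))
    stop_ct("`fractions` must lie in (0, 1]")
  seed <- check_count(seed, "seed", min = 0)
  d <- dim(image)
  clean <- project(image, geometry)
  rows <- purrr::imap(fractions, function(frac, idx) {
    model <- noise_model(incident_photons, frac, seed + 1000L * idx)
    noisy <- simulate_low_dose(clean, model)
    fbp_img <- fbp_reconstruct(noisy, d[1], d[2], image$pixel_size,
                               config$filter)
    ifbp_img <- suppressWarnings(
      ifbp_reconstruct(noisy, d[1], d[2], image$pixel_size, config))$image
    dplyr::bind_rows(
      dplyr::mutate(metric_report(image, fbp_img, rois),
                    dose_fraction = frac, method = "fbp"),
      dplyr::mutate(metric_report(image, ifbp_img, rois),
                    dose_fraction = frac, method = "ifbp")
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "dose_fraction", "method", "noise_std", "mse",
                       "snr", "contrast")
  class(out) <- c("dose_ladder", class(out))
  out
}

#' @export
autoplot.dose_ladder <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$dose_fraction, y = .data$noise_std,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dose fraction", y = "uniform-ROI noise SD",
                  colour = NULL)
}
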