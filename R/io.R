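#' Read and write images
#'
#' The package's primary on-disk image format is a plain-text CSV with
#' comment headers (`# pixel_size_mm: ...`), written with 17 significant
#' digits so values round-trip bit-exactly. Paths ending in `.tif`/`.tiff`
#' use single-channel 32-bit float TIFF instead — convenient for viewers,
#' but restricted to values in `[0, 1]` (the codec clamps outside that
#' range) and exact only to float32 precision; pixel size is not stored in
#' the TIFF and must be re-supplied on read.
#'
#' @param image An [image_grid()].
#' @param path Output path (`.csv` or `.tif`/`.tiff`).
#' @return `write_image` returns `path` invisibly; `read_image` returns an
#'   [image_grid()].
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "image_grid")) stop_ct("`image` must be an image_grid")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (min(image$values) < 0 || max(image$values) > 1)
      stop_ct("TIFF export requires values in [0, 1]; use a .csv path for ",
              "signed reconstructions")
    tiff::writeTIFF(image$values, path, bits.per.sample = 32L)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pixel_size_mm: %.17g", image$pixel_size), con)
  writeLines(apply(image$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size Pixel size in mm, used only for TIFF input (CSV stores
#'   its own).
#' @export
read_image <- function(path, pixel_size = 1) {
  if (!file.exists(path)) stop_ct("no such file: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    vals <- tiff::readTIFF(path)
    if (length(dim(vals)) == 3)
      stop_ct("expected a single-channel TIFF, got ", dim(vals)[3],
              " channels")
    return(image_grid(vals, pixel_size))
  }
  lines <- readLines(path)
  if (length(lines) == 0) stop_ct("empty image file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop_ct("image file has no data rows: ", path)
  px <- 1
  psl <- grep("^# pixel_size_mm:", hdr, value = TRUE)
  if (length(psl)) px <- as.numeric(sub("^# pixel_size_mm:", "", psl[1]))
  rows <- lapply(strsplit(body, ","), as.numeric)
  if (length(unique(lengths(rows))) != 1)
    stop_ct("ragged rows in image file: ", path)
  image_grid(do.call(rbind, rows), px)
}

#' Read and write sinograms
#'
#' CSV dialect: comment headers `# angles_deg: ...` (comma-separated view
#' angles in degrees) and `# bin_spacing_mm: ...`, followed by one row per
#' angle of comma-separated line integrals, printed with 17 significant
#' digits (bit-exact round trip).
#'
#' @param sino A [sinogram()].
#' @param path Output path.
#' @return `write_sinogram` returns `path` invisibly; `read_sinogram`
#'   returns a [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  if (!inherits(sino, "sinogram")) stop_ct("`sino` must be a sinogram")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# angles_deg: ",
           paste(sprintf("%.17g", sino$geometry$angles * 180 / pi),
                 collapse = ",")),
    sprintf("# bin_spacing_mm: %.17g", sino$geometry$bin_spacing)
  ), con)
  writeLines(apply(sino$values, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ",")), con)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop_ct("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) stop_ct("empty sinogram file: ", path)
  al <- grep("^# angles_deg:", lines, value = TRUE)
  bl <- grep("^# bin_spacing_mm:", lines, value = TRUE)
  if (!length(al) || !length(bl))
    stop_ct("sinogram file lacks its geometry headers: ", path)
  angles <- as.numeric(strsplit(sub("^# angles_deg:", "", al[1]), ",")[[1]]) *
    pi / 180
  spacing <- as.numeric(sub("^# bin_spacing_mm:", "", bl[1]))
  body <- lines[!grepl("^#", lines)]
  if (length(body) != length(angles))
    stop_ct(sprintf("sinogram has %d data rows but %d angles", length(body),
                    length(angles)))
  rows <- lapply(strsplit(body, ","), as.numeric)
  if (length(unique(lengths(rows))) != 1)
    stop_ct("ragged rows in sinogram file: ", path)
  vals <- do.call(rbind, rows)
  geometry <- ct_geometry(angles = angles, num_bins = ncol(vals),
                          bin_spacing = spacing)
  sinogram(vals, geometry)
}

#' Read/write small configuration objects as YAML
#'
#' @param spec A [phantom_spec()], [ct_geometry()], or other plain-list
#'   configuration.
#' @param path YAML path.
#' @return `write_config_yaml` returns `path` invisibly; `read_phantom_spec`
#'   and `read_geometry` return the reconstructed object.
#' @export
write_config_yaml <- function(spec, path) {
  plain <- unclass(spec)
  if (!is.null(plain$ellipses)) plain$ellipses <- as.data.frame(plain$ellipses)
  yaml::write_yaml(plain, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  ell <- if (is.null(x$ellipses) || length(x$ellipses) == 0) NULL
  else tibble::as_tibble(as.data.frame(x$ellipses))
  phantom_spec(kind = x$kind, ellipses = ell, seed = x$seed %||% 0L)
}

#' @rdname write_config_yaml
#' @export
read_geometry <- function(path) {
  x <- yaml::read_yaml(path)
  ct_geometry(angles = unlist(x$angles),
              num_bins = x$num_bins,
              bin_spacing = x$bin_spacing %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
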