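#' Reconstruction configuration
#'
#' Tunables of the iterative-FBP loop and the explicit pseudo-inverse
#' solver.
#'
#' @param theta Relaxation: a positive number, or `"auto"` to apply the
#'   dimension rule of [select_theta()] at run time.
#' @param phi Stopping tolerance on the Frobenius norm of the image update,
#'   `||R_{K+1} - R_K||`. `NULL` (default) resolves to
#'   `1e-4 * ||R_0||` at run time.
#' @param max_iters Iteration cap. Default 50.
#' @param filter A [filter_spec()] used by the inner FBP.
#' @param clamp_nonneg Clamp the final image at 0. Off by default: the
#'   update is signed and clamping inside the loop would break its algebra.
#' @param record_trace Keep the per-iteration trace. Default `TRUE`.
#' @return A `recon_config` object.
#' @export
recon_config <- function(theta = "auto", phi = NULL, max_iters = 50L,
                         filter = filter_spec(), clamp_nonneg = FALSE,
                         record_trace = TRUE) {
  if (!identical(theta, "auto")) {
    if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
      stop_ct("`theta` must be \"auto\" or a single positive number")
    theta <- as.numeric(theta)
  }
  if (!is.null(phi) && (!is.numeric(phi) || length(phi) != 1 || phi < 0))
    stop_ct("`phi` must be NULL or a single number >= 0")
  max_iters <- check_count(max_iters, "max_iters")
  if (!inherits(filter, "filter_spec")) stop_ct("`filter` must be a filter_spec")
  structure(list(theta = theta, phi = phi, max_iters = max_iters,
                 filter = filter, clamp_nonneg = isTRUE(clamp_nonneg),
                 record_trace = isTRUE(record_trace)),
            class = "recon_config")
}

#' Iterative FBP reconstruction
#'
#' The image-domain reconstruction loop in which filtered back projection
#' stands in for multiplication by the generalized inverse:
#'
#' \preformatted{
#'   R_0    = theta * FBP(U)
#'   U_K    = project(R_K)
#'   R_r    = theta * FBP(U_K)
#'   R_{K+1} = R_K + R_0 - R_r
#' }
#'
#' stopping when `Delta = ||R_{K+1} - R_K||_F <= phi` or at the iteration
#' cap. Each pass re-projects the current estimate, compares it (through
#' the FBP operator) with the measured data, and corrects the image; at a
#' fixed point the re-projection reproduces the data and the update
#' vanishes. Equivalent, when FBP is replaced by the exact
#' `theta * t(E)` operator, to [pseudoinverse_solve()]'s iterates.
#'
#' @param sino A measured [sinogram()] `U`.
#' @param height,width Output size in pixels.
#' @param pixel_size Pixel edge length in mm.
#' @param config A [recon_config()].
#' @param truth Optional reference [image_grid()]; when given, the trace
#'   records the per-iteration [mse()] against it.
#' @param reconstructor Optional replacement for the inner FBP: a
#'   `function(sinogram) -> image_grid` (used to study the exact-adjoint
#'   form of the update). `NULL` uses [fbp_reconstruct()] with
#'   `config$filter`.
#' @return An `ifbp_result`: list with `image`, `trace` (tibble of `K`,
#'   `delta`, `mse`), `converged`, `iterations`, `theta`, `phi`, `config`.
#'   Non-convergence at the cap is flagged and warned about; any
#'   non-finite iterate is a hard error naming the iteration.
#' @examples
#' ph <- make_disk_phantom(32, 32, 0.3, 1)
#' sg <- project(ph, ct_geometry(num_angles = 48))
#' res <- ifbp_reconstruct(sg, 32, 32, config = recon_config(theta = 1))
#' glance(res)
#' @export
ifbp_reconstruct <- function(sino, height, width, pixel_size = 1,
                             config = recon_config(), truth = NULL,
                             reconstructor = NULL) {
  if (!inherits(sino, "sinogram")) stop_ct("`sino` must be a sinogram")
  height <- check_count(height, "height")
  width <- check_count(width, "width")
  geometry <- bind_geometry(sino$geometry, height, width, pixel_size)
  X <- length(geometry$angles)
  Y <- geometry$num_bins
  theta <- config$theta
  if (identical(theta, "auto"))
    theta <- select_theta(height, width, X, Y)
  rec <- if (is.null(reconstructor)) {
    function(s) fbp_reconstruct(s, height, width, pixel_size, config$filter)
  } else {
    reconstructor
  }
  rec_values <- function(s) {
    out <- rec(s)
    if (inherits(out, "image_grid")) out$values else as.matrix(out)
  }
  R0 <- theta * rec_values(sino)
  phi <- if (is.null(config$phi)) 1e-4 * frob(R0) else config$phi
  R <- R0
  ks <- integer(0); deltas <- numeric(0); mses <- numeric(0)
  converged <- FALSE
  for (k in seq_len(config$max_iters)) {
    R_next <- tryCatch({
      UK <- project(image_grid(R, pixel_size), geometry)
      Rr <- theta * rec_values(UK)
      R + R0 - Rr
    }, error = function(e)
      stop_ct("iteration ", k, ": ", conditionMessage(e)))
    if (!all(is.finite(R_next)))
      stop_ct("non-finite image values at iteration ", k)
    delta <- frob(R_next - R)
    ks <- c(ks, k); deltas <- c(deltas, delta)
    if (!is.null(truth))
      mses <- c(mses, mean((R_next - truth$values)^2))
    R <- R_next
    if (delta <= phi) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(
      "iterative FBP stopped at max_iters = %d with delta = %.3g > phi = %.3g",
      config$max_iters, deltas[length(deltas)], phi), call. = FALSE)
  if (config$clamp_nonneg) R <- pmax(R, 0)
  trace <- tibble::tibble(K = ks, delta = deltas)
  trace$mse <- if (is.null(truth)) NA_real_ else mses
  structure(
    list(image = image_grid(R, pixel_size),
         trace = if (config$record_trace) trace else trace[0, ],
         converged = converged, iterations = length(ks), theta = theta,
         phi = phi, config = config),
    class = "ifbp_result"
  )
}

#' @export
print.ifbp_result <- function(x, ...) {
  cat(sprintf(
    "<ifbp_result> %d x %d image; %d iterations (%s), theta = %.4g, phi = %.3g\n",
    dim(x$image)[1], dim(x$image)[2], x$iterations,
    if (x$converged) "converged" else "not converged", x$theta, x$phi))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-iteration trace of an iterative reconstruction
#'
#' @param x An `ifbp_result`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: `K`, `delta`
#'   (`||R_{K+1} - R_K||_F`), and `mse` against the reference image when
#'   one was supplied.
#' @export
tidy.ifbp_result <- function(x, ...) x$trace

#' One-row summary of an iterative reconstruction
#'
#' @param x An `ifbp_result`.
#' @param ... Unused.
#' @return A one-row tibble: `iterations`, `converged`, `theta`, `phi`,
#'   `final_delta`, `final_mse`.
#' @export
glance.ifbp_result <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(
    iterations = x$iterations,
    converged = x$converged,
    theta = x$theta,
    phi = x$phi,
    final_delta = if (n) x$trace$delta[n] else NA_real_,
    final_mse = if (n) x$trace$mse[n] else NA_real_
  )
}

#' @export
autoplot.ifbp_result <- function(object, ...) {
  tr <- object$trace
  df <- tibble::tibble(
    K = rep(tr$K, 2),
    value = c(tr$delta, tr$mse),
    metric = rep(c("delta", "mse"), each = nrow(tr))
  )
  df <- df[is.finite(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration K", y = NULL, colour = NULL)
}
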