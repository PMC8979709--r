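#' @title First-order iteration for the generalized inverse
#'
#' @description
#' The algebraic core of the package: starting from `P_0 = theta * t(E)`,
#' the recursion `P_{K+1} = P_K + P_0 - P_0 E P_K` converges to the
#' Moore--Penrose pseudo-inverse `E^+` whenever the relaxation `theta` lies
#' in `(0, 2 / lambda_1(E E^t))`. The residual `C_K = Pi_range(E) - E P_K`
#' (with `Pi_range(E)` the orthogonal projector onto the column space of
#' `E`) contracts as `||C_{K+1}|| <= ||C_0|| * ||C_K||`, so convergence is
#' geometric once `||C_0|| < 1`. These functions operate on small explicit
#' systems; the image-domain production path is [ifbp_reconstruct()].
#'
#' @name pseudoinverse
NULL

as_E_matrix <- function(E) {
  if (inherits(E, "system_matrix")) E <- E$entries
  if (inherits(E, "Matrix") || is.matrix(E)) return(E)
  stop_ct("`E` must be a system_matrix, matrix, or Matrix")
}

frob <- function(x) sqrt(sum(x^2))

spectral_norm <- function(M) {
  M <- as.matrix(M)
  if (all(M == 0)) return(0)
  max(svd(M, nu = 0, nv = 0)$d)
}

# Orthogonal projector onto range(E).
range_projector <- function(E) {
  E <- as.matrix(as_E_matrix(E))
  s <- svd(E)
  r <- sum(s$d > max(dim(E)) * .Machine$double.eps * max(s$d))
  if (r == 0) return(matrix(0, nrow(E), nrow(E)))
  Ur <- s$u[, seq_len(r), drop = FALSE]
  Ur %*% t(Ur)
}

#' Spectral upper bound for the relaxation parameter
#'
#' Returns `2 / lambda_1(E E^t)`, `lambda_1` the largest eigenvalue,
#' computed by power iteration to `1e-8` relative accuracy. Any valid
#' relaxation must lie strictly inside `(0, theta_bound(E))`.
#'
#' @param E A `system_matrix`, base matrix, or `Matrix`.
#' @return Positive scalar bound.
#' @export
theta_bound <- function(E) {
  E <- as_E_matrix(E)
  if (sum(abs(E)) == 0) stop_ct("`E` must not be the zero matrix")
  m <- nrow(E)
  v <- with_seed(1L, stats::rnorm(m))
  v <- v / frob(v)
  lambda <- 0
  for (it in seq_len(10000L)) {
    w <- as.vector(E %*% crossprod(E, v))
    nw <- frob(w)
    if (nw == 0) break
    v_new <- w / nw
    lambda_new <- sum(v_new * as.vector(E %*% crossprod(E, v_new)))
    if (it > 1 && abs(lambda_new - lambda) <= 1e-8 * abs(lambda_new)) {
      lambda <- lambda_new
      break
    }
    lambda <- lambda_new
    v <- v_new
  }
  2 / lambda
}

#' Choose a relaxation parameter from the problem dimensions
#'
#' Applies the dimension rule: with `h * w` unknown pixels and `Y * X`
#' measurements, `theta = 1` when `h * w < Y * X` (over-determined systems),
#' otherwise `theta = 2^(-(h * w) / (Y * X))`; in both branches the result
#' is clamped strictly below the spectral bound (`0.99 * theta_bound(E)`)
#' so the iteration cannot diverge.
#'
#' @param height,width Image size in pixels.
#' @param num_angles,num_bins Acquisition size (X angles, Y bins).
#' @param E Optional system matrix for the spectral clamp; when `NULL` the
#'   dimension rule alone is used (appropriate for the calibrated
#'   image-domain operator, whose gain is at most 1).
#' @return Relaxation value in `(0, theta_bound(E))`.
#' @export
select_theta <- function(height, width, num_angles, num_bins, E = NULL) {
  hw <- as.numeric(height) * as.numeric(width)
  yx <- as.numeric(num_angles) * as.numeric(num_bins)
  raw <- if (hw < yx) 1 else 2^(-hw / yx)
  if (is.null(E)) return(raw)
  min(raw, 0.99 * theta_bound(E))
}

#' Initialize the pseudo-inverse iteration
#'
#' `P_0 = theta * t(E)`; the residual norm `||Pi_range(E) - E P_0||_2` is
#' computed at initialization and must be below 1 for the iteration to
#' contract.
#'
#' @param E A `system_matrix` or matrix (dense algebra: keep
#'   `height * width <= 1024`).
#' @param theta Relaxation in the open interval `(0, theta_bound(E))`.
#' @return A `pinv_state` with fields `P`, `K`, `residual_norm` (and the
#'   cached range projector used by [pseudoinverse_step()]).
#' @export
pseudoinverse_init <- function(E, theta) {
  Em <- as.matrix(as_E_matrix(E))
  bound <- theta_bound(Em)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 ||
      theta >= bound)
    stop_ct(sprintf("`theta` must lie strictly inside (0, %.6g)", bound))
  P0 <- theta * t(Em)
  Pi <- range_projector(Em)
  structure(
    list(P = P0, K = 0L,
         residual_norm = spectral_norm(Pi - Em %*% P0),
         pi_range = Pi),
    class = "pinv_state"
  )
}

#' One step of the pseudo-inverse recursion
#'
#' Applies `P_{K+1} = P_K + P_0 - P_0 E P_K` exactly, increments `K`, and
#' updates the residual norm `||Pi_range(E) - E P_{K+1}||_2`.
#'
#' @param state A `pinv_state` from [pseudoinverse_init()].
#' @param E The system matrix used at initialization.
#' @param P0 The initial approximation `theta * t(E)`.
#' @return The updated `pinv_state`.
#' @export
pseudoinverse_step <- function(state, E, P0) {
  if (!inherits(state, "pinv_state")) stop_ct("`state` must be a pinv_state")
  Em <- as.matrix(as_E_matrix(E))
  P0 <- as.matrix(P0)
  if (!all(dim(P0) == dim(state$P)) || nrow(Em) != ncol(state$P) ||
      ncol(Em) != nrow(state$P))
    stop_ct("shape mismatch between state, E, and P0")
  P_next <- state$P + P0 - P0 %*% (Em %*% state$P)
  state$P <- P_next
  state$K <- state$K + 1L
  state$residual_norm <- spectral_norm(state$pi_range - Em %*% P_next)
  state
}

#' Run the pseudo-inverse iteration to convergence
#'
#' Convenience driver around [pseudoinverse_init()] / [pseudoinverse_step()]
#' that records the residual trace and detects divergence (a residual that
#' grows beyond its initial value while exceeding 1, or any non-finite
#' iterate), the regime entered when `theta` violates the spectral bound.
#'
#' @inheritParams pseudoinverse_init
#' @param max_steps Iteration cap.
#' @param tol Stop when `||P_{K+1} - P_K||_F <= tol`.
#' @param check_theta Reject `theta` outside `(0, theta_bound)`. Set
#'   `FALSE` to study divergence above the bound.
#' @return A list with `P` (final approximation), `K`, `residual_trace`
#'   (tibble of `K`, `residual_norm`), `converged`, `diverged`.
#' @export
pinv_approx <- function(E, theta, max_steps = 500L, tol = 1e-10,
                        check_theta = TRUE) {
  Em <- as.matrix(as_E_matrix(E))
  if (check_theta) {
    state <- pseudoinverse_init(Em, theta)
  } else {
    if (theta <= 0) stop_ct("`theta` must be positive")
    P0 <- theta * t(Em)
    Pi <- range_projector(Em)
    state <- structure(
      list(P = P0, K = 0L, residual_norm = spectral_norm(Pi - Em %*% P0),
           pi_range = Pi),
      class = "pinv_state")
  }
  P0 <- theta * t(Em)
  res <- numeric(max_steps + 1L)
  res[1L] <- state$residual_norm
  converged <- FALSE
  diverged <- FALSE
  for (k in seq_len(max_steps)) {
    prev <- state$P
    state <- pseudoinverse_step(state, Em, P0)
    res[k + 1L] <- state$residual_norm
    if (!all(is.finite(state$P)) || !is.finite(state$residual_norm)) {
      diverged <- TRUE
      res <- res[seq_len(k + 1L)]
      break
    }
    if (state$residual_norm > max(1, res[1L]) &&
        state$residual_norm > res[k]) {
      diverged <- TRUE
      res <- res[seq_len(k + 1L)]
      break
    }
    if (frob(state$P - prev) <= tol) {
      converged <- TRUE
      res <- res[seq_len(k + 1L)]
      break
    }
  }
  if (!converged && !diverged) res <- res[seq_len(state$K + 1L)]
  list(P = state$P, K = state$K,
       residual_trace = tibble::tibble(K = seq_along(res) - 1L,
                                       residual_norm = res),
       converged = converged, diverged = diverged)
}

#' Reconstruct by explicit pseudo-inverse iteration
#'
#' Solves the small-system reconstruction `B = E^+ U` by iterating the
#' image-domain form of the recursion, `x_{K+1} = x_K + x_0 - theta
#' t(E) E x_K` with `x_0 = theta t(E) u` — algebraically identical to
#' `P_K U` at every step. Intended for systems with
#' `height * width <= 1024`.
#'
#' @param E A `system_matrix` (or matrix with dims supplied via
#'   `height`/`width`).
#' @param U A [sinogram()] (or numeric vector of length `nrow(E)`).
#' @param config A [recon_config()]; `theta = "auto"` resolves via
#'   [select_theta()] with the spectral clamp.
#' @param height,width Image size when `E` is a bare matrix.
#' @return A list with `image` ([image_grid()]), `trace` (tibble `K`,
#'   `delta`), `converged`, `iterations`, `theta`. Non-convergence at the
#'   iteration cap is flagged (and warned about), with the last iterate
#'   still returned.
#' @export
pseudoinverse_solve <- function(E, U, config = recon_config(),
                                height = NULL, width = NULL) {
  if (inherits(E, "system_matrix")) {
    height <- E$height; width <- E$width
    px <- E$pixel_size
    geometry <- E$geometry
    Em <- E$entries
  } else {
    Em <- as_E_matrix(E)
    px <- 1
    geometry <- NULL
    if (is.null(height) || is.null(width))
      stop_ct("`height` and `width` are required when `E` is a bare matrix")
  }
  if (height * width > 1024)
    stop_ct("explicit pseudo-inverse path is restricted to <= 1024 pixels; ",
            "use ifbp_reconstruct() for larger grids")
  u <- if (inherits(U, "sinogram")) as.vector(t(U$values)) else as.numeric(U)
  if (length(u) != nrow(Em)) stop_ct("`U` length does not match nrow(E)")
  theta <- config$theta
  if (identical(theta, "auto")) {
    X <- if (is.null(geometry)) 1 else length(geometry$angles)
    Y <- if (is.null(geometry)) nrow(Em) else geometry$num_bins
    theta <- select_theta(height, width, X, Y, Em)
  }
  x0 <- theta * as.vector(crossprod(Em, u))
  phi <- if (is.null(config$phi)) 1e-4 * frob(x0) else config$phi
  x <- x0
  deltas <- numeric(0)
  converged <- FALSE
  for (k in seq_len(config$max_iters)) {
    x_next <- x + x0 - theta * as.vector(crossprod(Em, Em %*% x))
    delta <- frob(x_next - x)
    deltas <- c(deltas, delta)
    x <- x_next
    if (delta <= phi) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf(
      "pseudo-inverse solve did not reach phi = %.3g in %d iterations (last delta %.3g)",
      phi, config$max_iters, deltas[length(deltas)]), call. = FALSE)
  list(
    image = unflatten_image(x, height, width, px),
    trace = tibble::tibble(K = seq_along(deltas), delta = deltas),
    converged = converged,
    iterations = length(deltas),
    theta = theta
  )
}
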