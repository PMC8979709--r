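test_that("theta_bound matches dense eigensolver results", {
  expect_rel_equal(theta_bound(diag(2)), 2, 1e-8)
  expect_rel_equal(theta_bound(2 * diag(3)), 0.5, 1e-8)
  E <- make_test_E(6, 9, c(2.5, 2, 1.3, 1, 0.7, 0.2), 42)
  expect_rel_equal(theta_bound(E), 2 / dense_lambda1(E), 1e-6)
  expect_error(theta_bound(matrix(0, 3, 3)), "zero matrix")
})

test_that("select_theta follows the dimension rule with a spectral clamp", {
  # over-determined: hw = 4 < YX = 12, spectrum small enough -> theta = 1
  E_tall <- rbind(0.9 * diag(4), matrix(0, 8, 4))
  expect_equal(select_theta(2, 2, 4, 3, E_tall), 1)
  # square counts: 2^(-1) = 0.5 when below the spectral cap
  E_sq <- make_test_E(12, 12, rep(1, 12), 7)   # lambda1 = 1, bound = 2
  expect_equal(select_theta(3, 4, 4, 3, E_sq), 0.5)
  # always strictly inside (0, bound)
  for (seed in 1:5) {
    E <- make_test_E(5, 8, c(4, 2, 1, 0.5, 0.2), seed)
    th <- select_theta(2, 4, 5, 1, E)
    expect_gt(th, 0)
    expect_lt(th, theta_bound(E))
  }
  # without E the bare dimension rule applies
  expect_equal(select_theta(8, 4, 8, 4), 0.5)
  expect_equal(select_theta(4, 4, 8, 8), 1)
})

test_that("pseudo-inverse initialization is theta * t(E) with its residual", {
  st <- pseudoinverse_init(diag(3), 1)
  expect_equal(st$P, diag(3))
  expect_equal(st$residual_norm, 0)
  expect_equal(st$K, 0L)

  E <- make_test_E(4, 6, c(3, 2, 1, 0.5), 12)
  theta <- 1 / dense_lambda1(E)
  st2 <- pseudoinverse_init(E, theta)
  expect_equal(st2$P, theta * t(E))
  # dense-algebra oracle for ||Pi_range - theta E E^t||_2
  s <- svd(E)
  Pi <- s$u %*% t(s$u)
  oracle <- max(svd(Pi - theta * E %*% t(E))$d)
  expect_rel_equal(st2$residual_norm, oracle, 1e-8)

  expect_error(pseudoinverse_init(E, 0), "strictly inside")
  expect_error(pseudoinverse_init(E, 2.1 / dense_lambda1(E)),
               "strictly inside")
})

test_that("one exact step inverts an orthogonal system", {
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  st <- pseudoinverse_init(Q, 1)
  st1 <- pseudoinverse_step(st, Q, 1 * t(Q))
  expect_equal(st1$P, t(Q), tolerance = 1e-12)
  expect_equal(st1$K, 1L)
  # identity system is stationary
  sti <- pseudoinverse_init(diag(4), 1)
  for (k in 1:3) sti <- pseudoinverse_step(sti, diag(4), diag(4))
  expect_equal(sti$P, diag(4))
  expect_error(pseudoinverse_step(st, Q, matrix(0, 2, 2)), "shape")
})

test_that("the iteration converges to the SVD pseudo-inverse", {
  E <- make_test_E(4, 6, c(3, 2, 1.5, 1), 55)
  res <- pinv_approx(E, theta_opt(E), max_steps = 200)
  expect_lt(norm(res$P - svd_pinv(E), "F"), 1e-6)
  expect_false(res$diverged)
})

test_that("residuals contract strictly while above the noise floor", {
  E <- make_test_E(6, 4, c(2, 1.5, 1, 0.6), 56)
  res <- pinv_approx(E, theta_opt(E), max_steps = 60, tol = 0)
  rn <- res$residual_trace$residual_norm
  expect_lt(rn[1], 1)
  live <- rn[rn > 1e-12]
  expect_true(all(diff(live) < 0))
})

test_that("a relaxation above the spectral bound is flagged as divergent", {
  E <- make_test_E(4, 6, c(3, 2, 1.5, 1), 57)
  res <- pinv_approx(E, 1.01 * theta_bound(E), max_steps = 300,
                     check_theta = FALSE)
  expect_true(res$diverged)
})

test_that("pseudoinverse_solve matches a dense least-squares oracle", {
  ph <- make_phantom(phantom_spec("lesion", seed = 3), 4, 4)
  geo <- ct_geometry(8, num_bins = 6)
  E <- build_system_matrix(geo, 4, 4, 1)
  U <- project(ph, geo)
  Em <- as.matrix(E$entries)
  x_ls <- as.vector(svd_pinv(Em) %*% as.vector(t(U$values)))
  res <- suppressWarnings(pseudoinverse_solve(
    E, U, recon_config(theta = theta_opt(Em), phi = 0, max_iters = 30000)))
  expect_lt(sqrt(mean((flatten_image(res$image) - x_ls)^2)), 1e-5)
})

test_that("pseudoinverse_solve on a zero sinogram stops immediately at zero", {
  geo <- ct_geometry(8, num_bins = 6)
  E <- build_system_matrix(geo, 4, 4, 1)
  z <- sinogram(matrix(0, 8, 6), E$geometry)
  res <- pseudoinverse_solve(E, z, recon_config(theta = 0.01))
  expect_equal(max(abs(as.matrix(res$image))), 0)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
})

test_that("more iterations never increase the data residual (noiseless)", {
  ph <- make_phantom(phantom_spec("lesion", seed = 9), 4, 4)
  geo <- ct_geometry(8, num_bins = 6)
  E <- build_system_matrix(geo, 4, 4, 1)
  U <- project(ph, geo)
  u <- as.vector(t(U$values))
  th <- theta_opt(as.matrix(E$entries))
  resid <- vapply(c(10, 20, 40, 80), function(n) {
    x <- suppressWarnings(pseudoinverse_solve(
      E, U, recon_config(theta = th, phi = 0, max_iters = n)))
    sqrt(sum((as.vector(E$entries %*% flatten_image(x$image)) - u)^2))
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-10))
})

test_that("image-domain loop with the exact adjoint reproduces the algebraic solve", {
  ph <- make_phantom(phantom_spec("lesion", seed = 3), 4, 4)
  geo <- ct_geometry(8, num_bins = 6)
  E <- build_system_matrix(geo, 4, 4, 1)
  U <- project(ph, geo)
  th <- 1 / dense_lambda1(as.matrix(E$entries))
  cfg <- recon_config(theta = th, phi = 0, max_iters = 25)
  exact_rec <- function(s)
    unflatten_image(as.vector(Matrix::crossprod(E$entries,
                                                as.vector(t(s$values)))),
                    4, 4)
  r_img <- suppressWarnings(
    ifbp_reconstruct(U, 4, 4, 1, cfg, reconstructor = exact_rec))
  r_alg <- suppressWarnings(pseudoinverse_solve(E, U, cfg))
  expect_lt(max(abs(as.matrix(r_img$image) - as.matrix(r_alg$image))), 1e-8)
  expect_lt(max(abs(r_img$trace$delta - r_alg$trace$delta)), 1e-8)
})

test_that("iterative FBP handles degenerate and fixed-point inputs", {
  geo <- ct_geometry(8, num_bins = 24)
  z <- sinogram(matrix(0, 8, 24), geo)
  res <- ifbp_reconstruct(z, 16, 16, config = recon_config(theta = 1))
  expect_equal(max(abs(as.matrix(res$image))), 0)
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$trace$delta, 0)
  expect_true(res$converged)

  # if theta * rec(project(R_0)) returns R_0 itself, the update is stationary
  set.seed(71)
  s <- sinogram(matrix(runif(8 * 24), 8), geo)
  const_img <- matrix(0.3, 16, 16)
  rec_const <- function(sino) image_grid(const_img)
  res_fp <- ifbp_reconstruct(s, 16, 16, config = recon_config(theta = 1),
                             reconstructor = rec_const)
  expect_equal(as.matrix(res_fp$image), const_img)
  expect_equal(res_fp$trace$delta[1], 0)

  # non-finite iterates are a hard error naming the iteration
  rec_huge <- function(sino) image_grid(matrix(1e308, 16, 16))
  expect_error(
    ifbp_reconstruct(s, 16, 16,
                     config = recon_config(theta = 1, max_iters = 5),
                     reconstructor = rec_huge),
    "iteration")
})

test_that("iterative FBP beats its FBP initialization on sparse views", {
  ph <- make_disk_phantom(64, 64, 0.3, 1.0)
  sg <- project(ph, ct_geometry(40))
  cfg <- recon_config(theta = 1, phi = 1e-4, max_iters = 30)
  res <- suppressWarnings(ifbp_reconstruct(sg, 64, 64, config = cfg,
                                           truth = ph))
  fbp0 <- fbp_reconstruct(sg, 64, 64)
  expect_lt(mse(ph, res$image), mse(ph, fbp0))
  expect_equal(nrow(res$trace), res$iterations)
})

test_that("result accessors expose the trace and summary", {
  ph <- make_disk_phantom(32, 32, 0.3, 1)
  sg <- project(ph, ct_geometry(24))
  res <- suppressWarnings(ifbp_reconstruct(
    sg, 32, 32, config = recon_config(theta = 1, max_iters = 8), truth = ph))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("K", "delta", "mse"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$iterations, res$iterations)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
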