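test_that("system matrix entries are exact intersection lengths", {
  # single pixel, one vertical ray through its centre: length = edge = 1 mm
  g1 <- ct_geometry(angles = 0, num_bins = 1, bin_spacing = 1.5)
  E1 <- build_system_matrix(g1, 1, 1, 1)
  expect_equal(dim(E1$entries), c(1L, 1L))
  expect_equal(as.numeric(E1$entries[1, 1]), 1.0)

  # axis-parallel rays at angle 0 stay within one pixel column
  g2 <- ct_geometry(angles = 0, num_bins = 4, bin_spacing = 1)
  E2 <- build_system_matrix(g2, 2, 2, 1)
  for (b in seq_len(4)) {
    cols <- which(E2$entries[b, ] != 0)
    if (length(cols)) {
      # row-major pixel index: column j = (idx - 1) %% width
      expect_length(unique((cols - 1) %% 2), 1L)
    }
  }

  # shape and sign contract
  g3 <- ct_geometry(7)
  E3 <- build_system_matrix(g3, 5, 4, 1)
  expect_equal(dim(E3$entries), c(7L * default_num_bins(5, 4), 20L))
  expect_gte(min(E3$entries@x), 0)
  # no row exceeds the image diagonal length
  expect_lte(max(Matrix::rowSums(E3$entries)), sqrt(5^2 + 4^2) + 1e-9)
})

test_that("matrix-free projection equals the system-matrix product", {
  set.seed(11)
  for (dims in list(c(16, 16), c(12, 20), c(64, 64))) {
    h <- dims[1]; w <- dims[2]
    img <- image_grid(matrix(runif(h * w), h, w), 1)
    geo <- ct_geometry(num_angles = 15)
    sg <- project(img, geo)
    E <- build_system_matrix(geo, h, w, 1)
    ref <- as.vector(E$entries %*% flatten_image(img))
    expect_lt(max(abs(ref - as.vector(t(sg$values)))),
              1e-10 * max(abs(ref)))
  }
})

test_that("projection is linear and preserves non-negativity", {
  set.seed(4)
  geo <- ct_geometry(9)
  z <- project(image_grid(matrix(0, 10, 10)), geo)
  expect_equal(max(abs(z$values)), 0)

  a <- image_grid(matrix(runif(100), 10), 1)
  b <- image_grid(matrix(runif(100), 10), 1)
  lin <- project(image_grid(2.5 * a$values - 1.25 * b$values), geo)
  ref <- 2.5 * project(a, geo)$values - 1.25 * project(b, geo)$values
  expect_lt(max(abs(lin$values - ref)), 1e-10 * max(abs(ref)))
  expect_gte(min(project(a, geo)$values), 0)
})

test_that("central chord of a disk matches the analytic length", {
  mu <- 0.8
  ph <- make_disk_phantom(64, 64, 0.3, mu)
  r_mm <- 0.3 * 64
  geo <- ct_geometry(12)
  sg <- project(ph, geo)
  centre_bin <- (default_num_bins(64, 64) + 1) %/% 2
  # the pixelized disk boundary shifts the central chord by up to
  # sqrt(2) * pixel_size
  for (a in seq_len(12))
    expect_lt(abs(sg$values[a, centre_bin] - 2 * r_mm * mu), sqrt(2) * mu)
})

test_that("centered-disk sinogram rows are angle-independent", {
  ph <- make_disk_phantom(32, 32, 0.25, 1)
  sg <- project(ph, ct_geometry(24))
  rows <- sg$values
  spread <- apply(rows, 2, function(col) max(col) - min(col))
  # row-to-row deviation bounded by one pixel's contribution
  expect_lt(max(spread), 2 * 1 * 1 + 1e-9)
})

test_that("backprojection is the exact adjoint of projection", {
  set.seed(21)
  for (dims in list(c(8, 8), c(16, 12))) {
    h <- dims[1]; w <- dims[2]
    geo <- ct_geometry(13)
    x <- image_grid(matrix(rnorm(h * w), h, w), 1)
    sx <- project(x, geo)
    y <- sinogram(matrix(rnorm(prod(dim(sx))), nrow(sx$values)), sx$geometry)
    ip_sino <- sum(sx$values * y$values)
    ip_img <- sum(x$values * backproject(y, h, w, 1)$values)
    expect_lt(abs(ip_sino - ip_img), 1e-8 * abs(ip_sino))
  }
})

test_that("one-hot backprojection reproduces a system-matrix row", {
  geo <- ct_geometry(6)
  h <- 12; w <- 12
  E <- build_system_matrix(geo, h, w, 1)
  nb <- E$geometry$num_bins
  for (ray in c(1L, as.integer(2 * nb + 3), nrow(E$entries))) {
    onehot <- matrix(0, 6, nb)
    onehot[(ray - 1) %/% nb + 1, (ray - 1) %% nb + 1] <- 1
    bp <- backproject(sinogram(onehot, E$geometry), h, w, 1)
    row_img <- matrix(as.numeric(E$entries[ray, ]), h, w, byrow = TRUE)
    expect_equal(bp$values, row_img, tolerance = 1e-12)
  }
})

test_that("zero sinogram backprojects to a zero image", {
  geo <- ct_geometry(5, num_bins = 20)
  z <- backproject(sinogram(matrix(0, 5, 20), geo), 8, 8, 1)
  expect_equal(max(abs(z$values)), 0)
})

test_that("geometry validation rejects bad inputs", {
  expect_error(ct_geometry(angles = c(0, 0.5, 0.4)), "increasing")
  expect_error(ct_geometry(angles = c(0, pi)), "\\[0, pi\\)")
  # detector too short for the image
  short <- ct_geometry(4, num_bins = 10, bin_spacing = 1)
  expect_error(project(make_disk_phantom(32, 32, 0.3, 1), short),
               "does not cover")
  # dimension mismatch between sinogram and geometry
  geo <- ct_geometry(4, num_bins = 46)
  expect_error(sinogram(matrix(0, 4, 30), geo), "does not match")
  expect_error(project(image_grid(matrix(c(1, NaN, 0, 0), 2)), geo),
               "finite")
})
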