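test_that("disk phantom matches a brute-force point-in-disk oracle", {
  ph <- make_disk_phantom(128, 128, 0.25, 1.0)
  # independent per-pixel membership loop
  r <- 0.25 * 128
  count <- 0L
  for (i in seq_len(128)) {
    for (j in seq_len(128)) {
      cy <- (i - 0.5) - 64
      cx <- (j - 0.5) - 64
      if (cx^2 + cy^2 <= r^2) count <- count + 1L
    }
  }
  expect_equal(sum(ph$values), count)
  expect_true(all(ph$values %in% c(0, 1)))
})

test_that("disk phantom degenerate cases and input validation", {
  expect_equal(max(abs(make_disk_phantom(8, 8, 0.5, 0.0)$values)), 0)
  one <- make_disk_phantom(1, 1, 0.5, 0.7)
  expect_equal(one$values, matrix(0.7, 1, 1))
  expect_error(make_disk_phantom(0, 8, 0.3, 0.5), "height")
  expect_error(make_disk_phantom(8, 8, 0.3, 1.5), "\\[0, 1\\]")
  expect_error(make_disk_phantom(8, 8, 0.7, 0.5), "\\(0, 0.5\\]")
})

test_that("composite phantoms are deterministic, clipped, and validated", {
  p1 <- make_phantom(phantom_spec("lesion", seed = 7), 48, 48)
  p2 <- make_phantom(phantom_spec("lesion", seed = 7), 48, 48)
  expect_identical(p1$values, p2$values)
  expect_true(all(p1$values >= 0 & p1$values <= 1))

  full <- tibble::tibble(center_x = 0, center_y = 0, semi_axis_a = 3,
                         semi_axis_b = 3, rotation_deg = 0,
                         additive_value = 0.4)
  expect_true(all(make_phantom(phantom_spec("disk", full), 8, 8)$values == 0.4))

  two <- tibble::tibble(center_x = c(0, 0.1), center_y = 0,
                        semi_axis_a = 0.5, semi_axis_b = 0.5,
                        rotation_deg = 0, additive_value = 0.7)
  overlap <- make_phantom(phantom_spec("disk", two), 16, 16)
  expect_equal(max(overlap$values), 1)

  expect_error(phantom_spec("disk"), "non-empty")
  expect_error(phantom_spec("shepp_logan"), "non-empty")
  bad <- tibble::tibble(center_x = 2, center_y = 0, semi_axis_a = 0.1,
                        semi_axis_b = 0.1, rotation_deg = 0,
                        additive_value = 0.5)
  expect_error(phantom_spec("disk", bad), "unit square")
})

test_that("lesion phantom carries a dark focus and a ring-enhanced region", {
  ph <- make_phantom(phantom_spec("lesion", seed = 0), 64, 64)
  v <- ph$values
  background <- 0.5
  expect_true(any(abs(v - 0.2) < 1e-12))   # focus darker than background
  expect_true(any(abs(v - 0.9) < 1e-12))   # bright rim
  expect_true(any(abs(v - 0.65) < 1e-12))  # core inside the rim
  expect_true(any(abs(v - background) < 1e-12))
})

test_that("rotated-ellipse membership agrees with the analytic inequality", {
  ell <- tibble::tibble(center_x = 0.2, center_y = -0.1, semi_axis_a = 0.5,
                        semi_axis_b = 0.25, rotation_deg = 30,
                        additive_value = 0.6)
  ph <- make_phantom(phantom_spec("disk", ell), 32, 32)
  phi <- 30 * pi / 180
  for (i in seq_len(32)) {
    for (j in seq_len(32)) {
      u <- ((j - 0.5) - 16) / 16
      v <- ((i - 0.5) - 16) / 16
      du <- u - 0.2; dv <- v + 0.1
      ur <- cos(phi) * du + sin(phi) * dv
      vr <- -sin(phi) * du + cos(phi) * dv
      inside <- (ur / 0.5)^2 + (vr / 0.25)^2 <= 1
      expect_identical(ph$values[i, j], if (inside) 0.6 else 0)
    }
  }
})

test_that("shepp_logan ellipse table renders within range at any size", {
  spec <- phantom_spec("shepp_logan", shepp_logan_ellipses())
  for (n in c(16, 33, 64)) {
    ph <- make_phantom(spec, n, n)
    expect_true(all(ph$values >= 0 & ph$values <= 1))
    expect_gt(max(ph$values), 0.5)
  }
})
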