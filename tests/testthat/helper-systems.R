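# Small dense test systems with a controlled singular spectrum, so the
# first-order iteration's convergence rate is known in advance.
make_test_E <- function(m, n, sv, seed) {
  set.seed(seed)
  G <- matrix(rnorm(m * n), m, n)
  s <- svd(G)
  k <- length(sv)
  s$u[, seq_len(k), drop = FALSE] %*% diag(sv, k) %*%
    t(s$v[, seq_len(k), drop = FALSE])
}

# Independent Moore-Penrose oracle via dense SVD.
svd_pinv <- function(E, tol = 1e-10) {
  s <- svd(E)
  r <- sum(s$d > tol * max(s$d))
  s$v[, seq_len(r), drop = FALSE] %*% diag(1 / s$d[seq_len(r)], r) %*%
    t(s$u[, seq_len(r), drop = FALSE])
}

# Largest eigenvalue of E E^t from a full dense eigendecomposition.
dense_lambda1 <- function(E) {
  max(eigen(E %*% t(E), symmetric = TRUE, only.values = TRUE)$values)
}

# Optimal relaxation over the nonzero spectrum of E E^t: fastest geometric
# rate, strictly inside (0, 2 / lambda_1).
theta_opt <- function(E, tol = 1e-10) {
  d <- svd(E)$d
  d <- d[d > tol * max(d)]
  2 / (max(d)^2 + min(d)^2)
}

# The toy-system suite used by the algebraic acceptance checks: shapes
# 4x6, 6x4, 8x8, the last rank-deficient (rank 6 of 8).
toy_systems <- function() {
  list(
    list(E = make_test_E(4, 6, c(3, 2, 1.5, 1), 101)),
    list(E = make_test_E(6, 4, c(3, 2, 1.5, 1), 102)),
    list(E = make_test_E(8, 8, c(3, 2.5, 2, 1.5, 1, 0.8), 103))
  )
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * max(abs(expected), 1e-300))
}
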