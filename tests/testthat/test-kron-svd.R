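test_that("factor SVDs reconstruct the kernels and order singular values", {
  kern <- random_kernel(8, 5, 6, 4, seed = 3)
  fs <- factor_svds(kern)
  expect_equal(fs$f1$u %*% diag(fs$f1$d) %*% t(fs$f1$v), kern$K1, tolerance = 1e-10)
  expect_equal(fs$f2$u %*% diag(fs$f2$d) %*% t(fs$f2$v), kern$K2, tolerance = 1e-10)
  expect_true(all(diff(fs$f1$d) <= 0) && all(fs$f1$d >= 0))
  expect_equal(crossprod(fs$f1$u), diag(5), tolerance = 1e-12)
  expect_equal(crossprod(fs$f1$v), diag(5), tolerance = 1e-12)
  # diagonal factor: singular values read off the diagonal
  kd <- separable_kernel(diag(c(3, 1)), diag(2))
  expect_equal(factor_svds(kd)$f1$d, c(3, 1))
})

test_that("spectral ordering sorts all pairwise products with a stable tie-break", {
  mk <- function(d1, d2) {
    # build kernels with prescribed singular values
    separable_kernel(diag(d1), diag(d2))
  }
  so <- spectral_ordering(factor_svds(mk(c(3, 1), c(2, 1))))
  expect_equal(so$sv, c(6, 3, 2, 1))
  expect_equal(so$pairs[, "i1"], c(1, 1, 2, 2), ignore_attr = TRUE)
  expect_equal(so$pairs[, "i2"], c(1, 2, 1, 2), ignore_attr = TRUE)
  # tie: products (4, 2, 2, 1); the two 2's keep composite column-major order
  so2 <- spectral_ordering(factor_svds(mk(c(2, 1), c(2, 1))))
  expect_equal(so2$sv, c(4, 2, 2, 1))
  expect_equal(so2$perm[2:3], c(2L, 3L))  # (2,1) before (1,2): index 2 < 3
  # against the dense SVD of the Kronecker product
  kern <- random_kernel(7, 5, 6, 4, seed = 11)
  so3 <- spectral_ordering(factor_svds(kern))
  expect_equal(so3$sv, svd(dense_kron(kern))$d, tolerance = 1e-10)
})

test_that("zero_tail keeps a prefix and zeroes the rest", {
  expect_equal(zero_tail(c(5, 4, 3), 2), c(5, 4, 0))
  x <- rnorm(6)
  expect_equal(zero_tail(x, 6), x)
  expect_equal(zero_tail(x, 0), rep(0, 6))
  expect_error(zero_tail(x, 7), "k must be")
  expect_error(zero_tail(x, -1), "k must be")
})

test_that("compress_data matches the dense truncated left basis", {
  kern <- small_ircpmg()
  op <- kron_tsvd(kern, k = 9)
  set.seed(5)
  S <- matrix(rnorm(8 * 7), 8, 7)
  got <- compress_data(op, S)
  Kd <- dense_kron(kern)
  sd <- svd(Kd)
  want <- crossprod(sd$u[, 1:9], as.vector(S))
  # per-coordinate sign conventions may differ between factorizations
  expect_equal(abs(got), abs(as.vector(want)), tolerance = 1e-9)
  # S = 0 -> zero coefficients
  expect_equal(compress_data(op, matrix(0, 8, 7)), rep(0, 9))
  # full k with square orthogonal factors preserves the norm
  kq <- separable_kernel(qr.Q(qr(matrix(rnorm(16), 4, 4))),
                         qr.Q(qr(matrix(rnorm(9), 3, 3))))
  opq <- kron_tsvd(kq, k = 12)
  Sq <- matrix(rnorm(12), 4, 3)
  expect_equal(sqrt(sum(compress_data(opq, Sq)^2)), norm(Sq, "F"), tolerance = 1e-10)
})

test_that("compressed coefficient norm never exceeds the data norm", {
  kern <- small_ircpmg()
  for (seed in 1:5) {
    set.seed(seed)
    S <- matrix(rnorm(56), 8, 7)
    for (k in c(1, 5, 20)) {
      op <- kron_tsvd(kern, k = k)
      expect_lte(sqrt(sum(compress_data(op, S)^2)), norm(S, "F") * (1 + 1e-12))
    }
  }
})

test_that("apply_VkT / apply_Vk are adjoint, orthonormal, and match the dense basis", {
  kern <- random_kernel(8, 6, 7, 5, seed = 9)
  op <- kron_tsvd(kern, k = 13)
  set.seed(2)
  Fm <- matrix(rnorm(30), 6, 5)
  cf <- rnorm(13)
  # adjoint identity <VkT F, c> = <F, Vk c>
  expect_equal(sum(apply_VkT(op, Fm) * cf), sum(Fm * apply_Vk(op, cf)),
               tolerance = 1e-11)
  # orthonormality: VkT Vk = I
  expect_equal(apply_VkT(op, apply_Vk(op, cf)), cf, tolerance = 1e-11)
  # dense comparison (magnitudes; signs are convention)
  sd <- svd(dense_kron(kern))
  expect_equal(abs(apply_VkT(op, Fm)),
               abs(as.vector(crossprod(sd$v[, 1:13], as.vector(Fm)))),
               tolerance = 1e-9)
  # F orthogonal to the retained right basis -> zero coefficients
  resid <- as.vector(Fm) - sd$v[, 1:13] %*% crossprod(sd$v[, 1:13], as.vector(Fm))
  expect_equal(apply_VkT(op, matrix(resid, 6, 5)), rep(0, 13), tolerance = 1e-9)
})

test_that("the assembled rank-k operator equals the dense TSVD and obeys Eckart-Young", {
  kern <- small_ircpmg(7, 6, 5, 4)
  Kd <- dense_kron(kern)
  sd <- svd(Kd)
  so <- spectral_ordering(factor_svds(kern))
  for (k in c(3, 8, 15)) {
    op <- kron_tsvd(kern, k = k)
    # composite map f -> Uk Sk VkT f via the fast products, against dense TSVD
    Kk_dense <- sd$u[, 1:k] %*% diag(sd$d[1:k], k) %*% t(sd$v[, 1:k])
    set.seed(k)
    f <- rnorm(20)
    cc <- op$so$sv[1:k] * apply_VkT(op, matrix(f, 5, 4))
    # scatter through the left basis: uses the same machinery as compress_data
    got <- as.vector(op$fs$f1$u %*% {
      z <- numeric(op$so$r1 * op$so$r2); z[op$so$perm[1:k]] <- cc
      matrix(z, op$so$r1, op$so$r2)
    } %*% t(op$fs$f2$u))
    expect_equal(got, as.vector(Kk_dense %*% f), tolerance = 1e-9)
    # Eckart-Young: squared error of the rank-k approximation
    expect_equal(norm(Kd - Kk_dense, "F")^2, sum(so$sv[-(1:k)]^2), tolerance = 1e-8)
  }
})
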