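test_that("factor-wise truncation counts and compressed data are correct", {
  kern <- separable_kernel(diag(c(4, 2, 0.5)), diag(c(3, 0.8)))
  sub <- vsh_compress(kern, matrix(1, 3, 2), tau1 = 1, tau2 = 1)
  expect_equal(c(sub$k1, sub$k2), c(2L, 1L))
  expect_equal(dim(sub$C), c(2L, 1L))
  expect_error(vsh_compress(kern, matrix(1, 3, 2), tau1 = 10, tau2 = 1),
               "empty truncation")
  # compressed data equals the projection onto the retained left bases
  kern2 <- small_ircpmg()
  set.seed(2)
  S <- matrix(rnorm(56), 8, 7)
  fs <- factor_svds(kern2)
  sub2 <- vsh_compress(kern2, S, tau1 = 0.5, tau2 = 0.5)
  want <- crossprod(fs$f1$u[, 1:sub2$k1], S) %*% fs$f2$u[, 1:sub2$k2]
  expect_equal(sub2$C, want, tolerance = 1e-12)
})

test_that("a 1x1 compressed problem reproduces the scalar closed form", {
  kern <- separable_kernel(matrix(c(2, 0), 2, 1) %*% t(c(1)), diag(1) * 3)
  # single singular value sigma = 6; data projects to coefficient c
  S <- matrix(c(12, 6), 2, 1)
  alpha <- 2
  sub <- vsh_compress(kern, S, 1, 1)
  sigma <- sub$fs$f1$d[1] * sub$fs$f2$d[1]
  cc <- sub$C[1, 1]
  res <- vsh_solve(kern, S, vsh_config(tau1 = 1, tau2 = 1,
                                       inner = np_config(tol_np = 1e-13, kmax_np = 500)),
                   mode = "model", alpha = alpha)
  # the solution is supported on the single retained component
  got <- sum(res$F$F * (sub$fs$f1$v[, 1] %o% sub$fs$f2$v[, 1]))
  expect_equal(got, max(0, sigma * cc / (sigma^2 + alpha)), tolerance = 1e-8)
})

test_that("the retained index set can straddle the sorted spectrum", {
  # factor spectra chosen so the product ordering interleaves: truncating each
  # factor keeps a small product while dropping a larger one
  kern <- separable_kernel(diag(c(10, 2)), diag(c(8, 1)))
  fs <- factor_svds(kern)
  so <- spectral_ordering(fs)
  sub <- vsh_compress(kern, matrix(1, 2, 2), tau1 = 5, tau2 = 0.5)
  idx <- vsh_index_set(sub, so)
  expect_length(idx, sub$k1 * sub$k2)
  # products sorted (80, 16, 10, 2); truncating the factors keeps {80, 10}
  # but discards 16: a larger singular value than one that is retained
  expect_gt(max(so$sv[-idx]), min(so$sv[idx]))
})

test_that("VSH filter factors apply the Tikhonov factor on the retained set only", {
  kern <- separable_kernel(diag(c(3, 1)), diag(c(2, 1)))
  fs <- factor_svds(kern)
  so <- spectral_ordering(fs)
  sub <- vsh_compress(kern, matrix(1, 2, 2), tau1 = 1, tau2 = 1.5)  # k1=2, k2=1
  alpha <- 4
  ff <- vsh_filter_factors(sub, so, alpha)
  idx <- vsh_index_set(sub, so)
  expect_equal(ff$phi[idx], so$sv[idx]^2 / (so$sv[idx]^2 + alpha))
  expect_equal(ff$phi[-idx], rep(0, length(so$sv) - length(idx)))
  # breakpoint: sigma^2 = alpha -> 1/2
  sub_all <- vsh_compress(kern, matrix(1, 2, 2), 0.5, 0.5)
  ff2 <- vsh_filter_factors(sub_all, so, alpha = so$sv[2]^2)
  expect_equal(ff2$phi[2], 0.5)
})

test_that("model mode coincides with the hybrid solver when the subspaces align", {
  # equal factor thresholds selecting a leading block of the sorted spectrum
  kern <- separable_kernel(diag(c(8, 4)), diag(c(2, 1)))
  # products: (16, 8, 8, 4); tau1 = 4, tau2 = 1 keeps everything
  set.seed(6)
  S <- matrix(rnorm(4), 2, 2)
  cfgi <- np_config(tol_np = 1e-12, kmax_np = 1000)
  rv <- vsh_solve(kern, S, vsh_config(tau1 = 4, tau2 = 1, inner = cfgi),
                  mode = "model", alpha = 0.3)
  rh <- solve_hybrid(kron_tsvd(kern, k = 4), S, alpha = 0.3, cfg = cfgi)
  expect_equal(rv$F$F, rh$F$F, tolerance = 1e-7)
})

test_that("discrepancy-matching outer iteration tracks the known noise level", {
  kern <- small_ircpmg(12, 10, 6, 5)
  set.seed(9)
  F_true <- matrix(runif(30), 6, 5)
  clean <- data_surface(forward(kern, F_true), noise_sd = 0)
  noisy <- add_noise(clean$S, snr_db = 30, seed = 4)
  noisy <- data_surface(noisy$S, noise_sd = noisy$noise_sd)
  res <- vsh_solve(kern, noisy,
                   vsh_config(tau1 = 1e-6, tau2 = 1e-6, alpha0 = 1,
                              max_outer = 50))
  expect_true(res$outer_iters >= 1)
  expect_true(all(res$F$F >= 0))
  # the final compressed residual should sit near the noise target
  sub <- vsh_compress(kern, noisy, 1e-6, 1e-6)
  target <- noisy$noise_sd * sqrt(sub$k1 * sub$k2)
  V1 <- sub$fs$f1$v[, 1:sub$k1]; V2 <- sub$fs$f2$v[, 1:sub$k2]
  d12 <- outer(sub$fs$f1$d[1:sub$k1], sub$fs$f2$d[1:sub$k2])
  resid <- sqrt(sum((d12 * (crossprod(V1, res$F$F) %*% V2) - sub$C)^2))
  expect_lt(resid, 10 * target)
  # method mode requires a noise level
  expect_error(vsh_solve(kern, noisy$S, vsh_config()), "noise standard deviation")
})
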