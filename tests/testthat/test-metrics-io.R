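test_that("relative_error is a scaled Frobenius distance", {
  A <- matrix(runif(12), 4, 3)
  expect_equal(relative_error(A, A), 0)
  expect_equal(relative_error(A, matrix(0, 4, 3)), 1)
  expect_equal(relative_error(A, 2 * A), 1)
  expect_error(relative_error(matrix(0, 4, 3), A), "zero")
  expect_error(relative_error(A, matrix(1, 2, 2)), "equal shape")
})

test_that("projections are mass-conserving marginals", {
  set.seed(1)
  a <- runif(5); b <- runif(4)
  P <- projections(outer(a, b))
  expect_equal(P$T1 / sum(P$T1), a / sum(a), tolerance = 1e-12)
  expect_equal(P$T2 / sum(P$T2), b / sum(b), tolerance = 1e-12)
  expect_equal(sum(P$T1), sum(outer(a, b)))
  expect_equal(sum(P$T2), sum(outer(a, b)))
  spike <- matrix(0, 5, 4); spike[2, 3] <- 7
  Ps <- projections(spike)
  expect_equal(Ps$T1, c(0, 7, 0, 0, 0))
  expect_equal(Ps$T2, c(0, 0, 7, 0))
})

test_that("peak_report finds dominating nodes above the prominence floor", {
  rg <- relax_grid(logspace(1e-3, 3, 50), logspace(1e-3, 1, 50))
  one <- tibble::tibble(T1_ms = 50, T2_ms = 20, sd1 = 0.15, sd2 = 0.15, amplitude = 2)
  pk <- peak_report(gaussian_mixture(one, rg))
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(log10(pk$T1_ms) - log10(50)), 0.05)
  expect_equal(pk$height, 2, tolerance = 0.02)  # node offset from the center
  # all-zero map: empty report
  expect_equal(nrow(peak_report(t1t2_dist(matrix(0, 4, 4)))), 0L)
  # descending height order with several peaks
  pk3 <- peak_report(gaussian_mixture(default_peaks(), rg))
  expect_true(all(diff(pk3$height) <= 0))
})

test_that("an end-to-end small inversion localizes a single peak to within one node", {
  g <- make_grids(128, 32, c(1e-3, 3), c(1e-3, 1), 24, 24, c(1e-3, 3), c(1e-3, 1))
  kern <- build_kernels(g$time, g$relax)
  one <- tibble::tibble(T1_ms = 80, T2_ms = 15, sd1 = 0.15, sd2 = 0.15, amplitude = 1)
  truth <- gaussian_mixture(one, g$relax)
  noisy <- add_noise(forward(kern, truth), snr_db = 30, seed = 3)
  noisy$tg <- g$time
  op <- kron_tsvd(kern, tau = 1)
  res <- solve_hybrid(op, noisy)
  pk <- peak_report(res$F, floor = 0.2)
  truth_pk <- peak_report(truth)
  expect_gte(nrow(pk), 1L)
  expect_lte(abs(pk$i1[1] - truth_pk$i1[1]), 1L)
  expect_lte(abs(pk$i2[1] - truth_pk$i2[1]), 1L)
})

test_that("surface and distribution files round-trip through delimited text", {
  g <- make_grids(6, 5, c(1e-3, 3), c(1e-3, 1), 4, 3, c(1e-3, 3), c(1e-3, 1))
  kern <- build_kernels(g$time, g$relax)
  set.seed(2)
  F0 <- t1t2_dist(matrix(runif(12), 4, 3), g$relax)
  S0 <- data_surface(forward(kern, F0), g$time)
  fs_path <- withr::local_tempfile(fileext = ".csv")
  fd_path <- withr::local_tempfile(fileext = ".csv")
  write_surface(S0, fs_path)
  write_distribution(F0, fd_path)
  S1 <- read_surface(fs_path)
  F1 <- read_distribution(fd_path)
  expect_equal(S1$S, S0$S)
  expect_equal(S1$tg$t1, g$time$t1)
  expect_equal(F1$F, F0$F)
  expect_equal(F1$rg$T2, g$relax$T2)
})

test_that("the STELAR-like ascii reader parses times and the signal block", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment",
               "1 2 4",
               "0.5 1",
               "10 11", "20 21", "30 31"), path)
  ds <- read_stelar_ascii(path)
  expect_equal(ds$tg$t1, c(1, 2, 4))
  expect_equal(ds$S, rbind(c(10, 11), c(20, 21), c(30, 31)))
  ds_ms <- read_stelar_ascii(path, unit = "ms")
  expect_equal(ds_ms$tg$t2, c(0.5, 1) / 1000)
  writeLines(c("1 2", "1 2 3", "1 2 3"), path)
  expect_error(read_stelar_ascii(path), "rows")
})

test_that("run_sweep matches direct solver calls and is seed-deterministic", {
  kern <- small_ircpmg(24, 16, 8, 8)
  set.seed(11)
  truth <- t1t2_dist(matrix(runif(64), 8, 8))
  noisy <- add_noise(forward(kern, truth), snr_db = 25, seed = 8)
  sw <- run_sweep(kern, noisy, truth, methods = "hybrid", alphas = 0.5, tau = 1)
  direct <- solve_hybrid(kron_tsvd(kern, tau = 1), noisy, alpha = 0.5)
  expect_equal(sw$err, relative_error(truth, direct))
  expect_equal(sw$np_iters, direct$np_iters)
  # identical realization -> identical error columns
  sw2 <- run_sweep(kern, noisy, truth, methods = c("hybrid", "vsh"),
                   alphas = c(1, 0.1), tau = 1)
  sw3 <- run_sweep(kern, noisy, truth, methods = c("hybrid", "vsh"),
                   alphas = c(1, 0.1), tau = 1)
  expect_equal(sw2$err, sw3$err)
  expect_equal(nrow(sw2), 4L)
  expect_false(any(sw2$failed))
})

test_that("tidy and glance expose the fitted distribution and diagnostics", {
  kern <- small_ircpmg(12, 10, 5, 4)
  g <- make_grids(12, 10, c(1e-3, 3), c(1e-3, 1), 5, 4, c(1e-3, 3), c(1e-3, 1))
  set.seed(14)
  S <- forward(kern, matrix(runif(20), 5, 4))
  res <- solve_hybrid(kron_tsvd(kern, k = 10), S, alpha = 0.1)
  td <- tidy(res)
  expect_equal(nrow(td), 20L)
  expect_true(all(c("T1", "T2", "amplitude") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$method, "hybrid")
  expect_true(gl$residual >= 0)
})
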