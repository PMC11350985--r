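# adaptive Gabor kernels, DC removal and texture features

test_that("kernels match a brute-force evaluation of the defining formulas", {
  p <- gabor_params(2, 0.25, 90, k = 7)
  kern <- gabor_kernel(p)
  bf_re <- matrix(0, 15, 15); bf_im <- bf_re
  for (r in 1:15) for (cc in 1:15) {
    y <- r - 8; x <- cc - 8
    env <- exp(-(x^2 + y^2) / (2 * p$sigma^2)) / (2 * pi * p$sigma^2)
    ph <- 2 * pi * p$mu * (x * cos(pi / 2) + y * sin(pi / 2))
    bf_re[r, cc] <- env * cos(ph)
    bf_im[r, cc] <- env * sin(ph)
  }
  expect_lt(max(abs(kern$re - bf_re)), 1e-12)
  expect_lt(max(abs(kern$im - bf_im)), 1e-12)
})

test_that("kernel structure follows the analytic special cases", {
  k0 <- gabor_kernel(gabor_params(2, 0, 45, k = 5))
  expect_equal(max(abs(k0$im)), 0)                   # mu = 0: pure Gaussian
  expect_equal(k0$re[6, 6], 1 / (2 * pi * 4))        # centre of the envelope
  kc <- gabor_kernel(gabor_params(1.5, 0.2, 30, k = 4))
  expect_equal(kc$re[5, 5], 1 / (2 * pi * 1.5^2))
  expect_equal(kc$im[5, 5], 0)
})

test_that("DC removal zeroes the kernel sum exactly once", {
  kern <- gabor_kernel(gabor_params(2, 0.15, 60, k = 6))
  kd <- remove_dc(kern)
  expect_lt(abs(sum(kd$re)) + abs(sum(kd$im)), 1e-10)
  expect_lt(max(kd$re), max(kern$re))                # Gaussian peak shrinks
  expect_error(remove_dc(kd), "already")
})

test_that("filtering matches the brute-force correlation loop", {
  set.seed(20)
  img <- matrix(runif(18 * 18), 18)
  kd <- remove_dc(gabor_kernel(gabor_params(1.5, 0.2, 30, k = 3)))
  F1 <- retinograde:::conv2_reflect(img, kd)
  k <- 3
  ri <- retinograde:::reflect_idx(18, k)
  P <- img[ri, ri]
  bf <- matrix(0 + 0i, 18, 18)
  for (r in 1:18) for (cc in 1:18) {
    s <- 0 + 0i
    for (qr in -k:k) for (qc in -k:k) {
      s <- s + P[r + k + qr, cc + k + qc] *
        (kd$re[qr + k + 1, qc + k + 1] + 1i * kd$im[qr + k + 1, qc + k + 1])
    }
    bf[r, cc] <- s
  }
  expect_lt(max(Mod(F1 - bf)), 1e-12)
  # constant image: DC-free kernel gives an all-zero response
  expect_lt(max(Mod(retinograde:::conv2_reflect(matrix(3, 18, 18), kd))), 1e-10)
})

test_that("local parameter estimation recovers a synthetic grating", {
  n <- 32
  x <- matrix(1:n, n, n, byrow = TRUE); y <- matrix(1:n, n, n)
  th <- 30 * pi / 180; mu <- 0.1
  g <- cos(2 * pi * mu * (x * cos(th) + y * sin(th)))
  p <- estimate_local_params(g)
  expect_lt(min(abs(p$theta - 30), abs(p$theta - 210 %% 180)), 5)
  expect_lt(abs(p$mu - mu) / mu, 0.2)
  expect_false(attr(p, "degenerate"))

  g90 <- cos(2 * pi * mu * (x * cos(th + pi / 2) + y * sin(th + pi / 2)))
  p90 <- estimate_local_params(g90)
  expect_lt(abs(((p90$theta - p$theta) %% 180) - 90), 6)

  flat <- matrix(1, 32, 32)
  pf <- estimate_local_params(flat)
  expect_true(attr(pf, "degenerate"))
})

test_that("feature vectors are deterministic, named and finite", {
  set.seed(21)
  img <- matrix(runif(40 * 40), 40)
  bk <- gabor_bank(orientations = c(0, 90), frequencies = c(0.1, 0.2),
                   tiles = 2)
  f1 <- extract_gabor_features(img, bank = bk)
  f2 <- extract_gabor_features(img, bank = bk)
  expect_identical(f1, f2)
  expect_all_finite(f1)
  expect_true(all(nzchar(names(f1))))
})

test_that("features are illumination-offset invariant and scale linearly", {
  set.seed(22)
  img <- matrix(runif(40 * 40), 40)
  bk <- gabor_bank(orientations = c(0, 60, 120), frequencies = c(0.1, 0.2),
                   tiles = 2)
  f <- extract_gabor_features(img, bank = bk)
  f_off <- extract_gabor_features(img + 0.37, bank = bk)
  expect_lt(max(abs(f - f_off)), 1e-8)
  f_scaled <- extract_gabor_features(img * 2.5, bank = bk)
  expect_lt(max(abs(f_scaled - 2.5 * f)), 1e-8)
})

test_that("oriented bars respond strongest at the aligned orientation", {
  bars <- matrix(rep(c(0, 0, 1, 1), length.out = 40), 40, 40, byrow = TRUE)
  f <- extract_gabor_features(bars, bank = gabor_bank(
    orientations = c(0, 90), frequencies = 0.25, tiles = 1,
    adaptive = FALSE))
  expect_gt(f[["bank_th000_mu0.250_t11_energy"]],
            10 * f[["bank_th090_mu0.250_t11_energy"]])
})

test_that("segmentation summaries appear per class and stay in range", {
  set.seed(23)
  img <- matrix(runif(40 * 40), 40)
  seg <- matrix("background", 40, 40)
  seg[10:14, 10:14] <- "hard_exudate"
  seg[30:34, 5:9] <- "vessel"
  f <- extract_gabor_features(img, seg = seg,
                              bank = gabor_bank(orientations = 0,
                                                frequencies = 0.2,
                                                tiles = 1, adaptive = FALSE))
  expect_equal(f[["seg_hard_exudate_count"]], 1)
  expect_equal(f[["seg_hard_exudate_area"]], 25 / 1600)
  expect_equal(f[["seg_microaneurysm_area"]], 0)
  expect_equal(f[["seg_microaneurysm_minradial"]], 1.5)
  expect_gt(f[["seg_vessel_minradial"]], f[["seg_hard_exudate_minradial"]])
})
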