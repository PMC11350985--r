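# preprocessing: green channel, equalization, multilevel 2D DWT

test_that("green channel extraction keeps the green plane and resizes", {
  img <- array(0, c(32, 32, 3)); img[, , 2] <- 1
  expect_equal(to_green_channel(img), matrix(1, 32, 32))
  img_r <- array(0, c(32, 32, 3)); img_r[, , 1] <- 1
  expect_equal(to_green_channel(img_r), matrix(0, 32, 32))
  img2 <- array(runif(100 * 200 * 3), c(100, 200, 3))
  expect_equal(dim(to_green_channel(img2, 64)), c(64, 64))
  expect_error(to_green_channel(matrix(1, 5, 5)), "3 channels")
})

test_that("histogram equalization is monotone and spans the range", {
  const <- matrix(0.4, 10, 10)
  expect_equal(equalize_histogram(const), const)

  two <- matrix(rep(c(10, 20) / 255, each = 50), 10, 10)
  out <- equalize_histogram(two)
  expect_equal(sort(unique(as.numeric(out))), c(0, 1))

  ramp <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  eq <- equalize_histogram(ramp)
  # brute-force CDF oracle: for a ramp the empirical CDF of the output
  # should be close to uniform
  cdf_dev <- max(abs(sort(as.numeric(eq)) - seq(0, 1, length.out = 64 * 64)))
  expect_lt(cdf_dev, 0.05)
  # monotone remap
  o <- order(as.numeric(ramp))
  expect_true(all(diff(as.numeric(eq)[o]) >= 0))
})

test_that("multilevel DWT reconstructs exactly and matches shapes", {
  set.seed(10)
  for (fam in c("haar", "db4")) {
    spec <- wavelet_spec(fam, 2)
    for (n in c(64, 63, 37)) {
      x <- matrix(rnorm(n * n), n)
      dec <- dwt2_multilevel(x, spec)
      expect_lt(max(abs(idwt2_multilevel(dec) - x)), 1e-8)
      expect_equal(dim(dec$details[[1]]$H), rep(ceiling(n / 2), 2))
      expect_equal(dim(dec$details[[2]]$D), rep(ceiling(ceiling(n / 2) / 2), 2))
      expect_equal(dim(dec$A), dim(dec$details[[2]]$H))
    }
  }
})

test_that("orthogonal families conserve energy on even dyadic rasters", {
  set.seed(11)
  for (fam in c("haar", "db4")) {
    x <- matrix(rnorm(64 * 64), 64)
    dec <- dwt2_multilevel(x, wavelet_spec(fam, 3))
    e_img <- sum(x^2)
    e_coef <- sum(dec$A^2) +
      sum(vapply(dec$details, function(d) sum(unlist(d)^2), numeric(1)))
    expect_lt(abs(e_img - e_coef) / e_img, 1e-6)
  }
})

test_that("a constant image has zero detail coefficients", {
  dec <- dwt2_multilevel(matrix(5, 32, 32), wavelet_spec("db4", 2))
  expect_lt(max(abs(unlist(dec$details))), 1e-10)
})

test_that("one Haar level matches the brute-force separable filter", {
  set.seed(12)
  x <- matrix(rnorm(16), 4)
  dec <- dwt2_multilevel(x, wavelet_spec("haar", 1))
  h <- c(1, 1) / sqrt(2); g <- c(1, -1) / sqrt(2)
  # brute force: filter columns then rows with explicit loops + downsampling
  lo <- matrix(0, 2, 4); hi <- matrix(0, 2, 4)
  for (k in 0:1) for (j in 1:4) {
    lo[k + 1, j] <- sum(h * x[(2 * k + 0:1) %% 4 + 1, j])
    hi[k + 1, j] <- sum(g * x[(2 * k + 0:1) %% 4 + 1, j])
  }
  A <- matrix(0, 2, 2); H <- A; V <- A; D <- A
  for (k in 0:1) for (r in 1:2) {
    A[r, k + 1] <- sum(h * lo[r, (2 * k + 0:1) %% 4 + 1])
    V[r, k + 1] <- sum(g * lo[r, (2 * k + 0:1) %% 4 + 1])
    H[r, k + 1] <- sum(h * hi[r, (2 * k + 0:1) %% 4 + 1])
    D[r, k + 1] <- sum(g * hi[r, (2 * k + 0:1) %% 4 + 1])
  }
  expect_equal(dec$A, A, tolerance = 1e-12)
  expect_equal(dec$details[[1]]$H, H, tolerance = 1e-12)
  expect_equal(dec$details[[1]]$V, V, tolerance = 1e-12)
  expect_equal(dec$details[[1]]$D, D, tolerance = 1e-12)
})

test_that("sub-band additivity holds (linearity of the inverse)", {
  set.seed(13)
  x <- matrix(rnorm(32 * 32), 32)
  dec <- dwt2_multilevel(x, wavelet_spec("haar", 2))
  zero_all <- function(d, keep) {
    out <- d
    out$A <- d$A * 0
    out$details <- lapply(d$details, function(lv) lapply(lv, function(m) m * 0))
    if (keep == "A") out$A <- d$A
    out
  }
  parts <- idwt2_multilevel(zero_all(dec, "A"))
  for (lv in seq_along(dec$details)) for (nm in c("H", "V", "D")) {
    one <- zero_all(dec, "none")
    one$details[[lv]][[nm]] <- dec$details[[lv]][[nm]]
    parts <- parts + idwt2_multilevel(one)
  }
  expect_lt(max(abs(parts - x)), 1e-8)
})

test_that("too-deep decompositions fail with the feasible level", {
  expect_error(dwt2_multilevel(matrix(1, 8, 8), wavelet_spec("db4", 3)),
               "maximum feasible level")
})

test_that("thresholded reconstruction denoises and respects the rules", {
  set.seed(14)
  clean <- matrix(seq(0, 1, length.out = 64), 64, 64)
  noisy <- clean
  spots <- sample(length(noisy), 40)
  noisy[spots] <- noisy[spots] + sample(c(-0.8, 0.8), 40, TRUE)
  dec <- dwt2_multilevel(noisy, wavelet_spec("haar", 2))

  expect_lt(max(abs(denoise_reconstruct(dec, threshold = 0) - noisy)), 1e-10)

  big <- max(abs(unlist(dec$details))) + 1
  only_a <- denoise_reconstruct(dec, threshold = big)
  dec0 <- dec
  dec0$details <- lapply(dec0$details, function(d) lapply(d, function(m) m * 0))
  expect_equal(only_a, idwt2_multilevel(dec0), tolerance = 1e-10)

  den <- denoise_reconstruct(dec, rule = "soft")
  mse <- function(a, b) mean((a - b)^2)   # direct pixel-loop oracle inlined
  expect_lt(mse(den, clean), mse(noisy, clean))

  expect_error(denoise_reconstruct(dec, rule = "fancy"), "supported rules")
})
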