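# shift-add quantization and the piecewise-linear activation

test_that("single weights quantize to the printed shift-add values", {
  q1 <- quantize_weight(0.8735, S = 3)
  expect_equal(q1$value, 0.8750)
  expect_equal(q1$exponents, c(1L, 2L, 3L))

  q2 <- quantize_weight(0.3811, S = 3)
  expect_equal(q2$value, 0.3750)
  expect_equal(q2$exponents, c(2L, 3L))

  q3 <- quantize_weight(0.8000, S = 3)
  expect_equal(q3$value, 0.7500)
  expect_equal(q3$error, 0.0500)

  q0 <- quantize_weight(0, S = 5)
  expect_equal(q0$value, 0)
  expect_length(q0$exponents, 0)

  # negative weights mirror positive ones
  qn <- quantize_weight(-0.8735, S = 3)
  expect_equal(qn$value, -0.8750)
  expect_equal(qn$sign, -1)
})

test_that("no representable value is closer than the returned one", {
  for (S in c(2L, 3L, 4L)) {
    grid <- c(0, seq_len(2^S - 1)) / 2^S
    grid <- sort(unique(c(-grid, grid)))
    set.seed(41)
    for (w in c(stats::runif(50, -0.999, 0.999), 0.0625, -0.0625)) {
      q <- quantize_weight(w, S)
      expect_true(all(abs(w - grid) >= abs(w - q$value) - 1e-12))
      # reconstruction from exponents matches the value
      expect_equal(q$sign * sum(2^-q$exponents), q$value)
    }
  }
})

test_that("weights at or beyond unit magnitude are rejected", {
  expect_error(quantize_weight(1, 3), "pre-scale")
  expect_error(quantize_weight(-1.2, 3), "pre-scale")
  expect_error(quantize_with_diffusion(c(0.5, 1.01), 3), "pre-scale")
})

test_that("the three-weight sequence reproduces the worked averages", {
  ws <- c(0.8000, 0.4250, 0.4050)
  plain <- quantize_with_diffusion(ws, S = 3, diffusion = FALSE)
  expect_equal(plain$weights$quantized, c(0.7500, 0.3750, 0.3750))
  expect_equal(plain$weights$error, c(0.0500, 0.0500, 0.0300))
  expect_equal(plain$average_error, 0.13 / 3)
  expect_equal(round(plain$average_error, 4), 0.0433)

  diff <- quantize_with_diffusion(ws, S = 3, diffusion = TRUE)
  expect_equal(diff$weights$quantized, c(0.7500, 0.5000, 0.3750))
  expect_equal(diff$weights$error, c(0.0500, -0.0750, 0.0300))
  expect_equal(diff$average_error, 0.005 / 3)
  expect_lt(abs(diff$average_error - 0.0016), 1e-4)
  # diffusion shrinks the average signed error on this sequence
  expect_lt(abs(diff$average_error), abs(plain$average_error))
})

test_that("a single weight diffuses to the plain quantization", {
  for (w in c(0.8735, -0.41, 0.0)) {
    r <- quantize_with_diffusion(w, S = 3, diffusion = TRUE)
    q <- quantize_weight(w, S = 3)
    expect_equal(r$weights$quantized, q$value)
    expect_equal(r$average_error, q$error)
  }
})

test_that("diffusion reduces the average signed error on random sequences", {
  set.seed(7)
  gain <- replicate(200, {
    ws <- stats::runif(8, -0.95, 0.95)
    a <- abs(quantize_with_diffusion(ws, 3, diffusion = FALSE)$average_error)
    b <- abs(quantize_with_diffusion(ws, 3, diffusion = TRUE)$average_error)
    c(a, b)
  })
  expect_lt(mean(gain[2, ]), mean(gain[1, ]))
  # and diffusion wins in the overwhelming majority of cases
  expect_gt(mean(gain[2, ] <= gain[1, ] + 1e-12), 0.9)
})

test_that("piecewise tanh follows the printed branches and tracks tanh", {
  expect_equal(piecewise_tanh(0.25), 0.25)
  expect_equal(piecewise_tanh(0), 0)
  expect_equal(piecewise_tanh(-0.25), -0.25)
  expect_equal(piecewise_tanh(0.75), 0.5 + (0.75 - 0.5) / 2)
  expect_equal(piecewise_tanh(1.5), 0.75 + (1.5 - 1) / 4)
  expect_equal(piecewise_tanh(5), 1)

  x <- seq(-4, 4, by = 0.001)
  y <- piecewise_tanh(x)
  expect_true(all(abs(y - tanh(x)) <= 0.06))
  expect_equal(y, -piecewise_tanh(-x))          # odd
  expect_true(all(diff(y) >= 0))                # non-decreasing
  expect_true(all(abs(y) <= 1))                 # bounded
})
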