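# CNN forward passes, the chicken swarm optimizer and the grade classifier

test_that("convolution matches a quadruple-nested-loop oracle", {
  set.seed(40)
  inp <- array(runif(5 * 5 * 2), c(5, 5, 2))
  fil <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  out <- conv_forward(inp, fil, b)
  bf <- array(0, c(3, 3, 3))
  for (e in 1:3) for (r in 1:3) for (cc in 1:3) {
    s <- b[e]
    for (dr in 1:3) for (dc in 1:3) for (ch in 1:2) {
      s <- s + inp[r + dr - 1, cc + dc - 1, ch] * fil[dr, dc, ch, e]
    }
    bf[r, cc, e] <- s
  }
  expect_lt(max(abs(out - bf)), 1e-12)
})

test_that("convolution special cases and errors", {
  idk <- array(0, c(3, 3, 1, 1)); idk[2, 2, 1, 1] <- 1
  m <- matrix(runif(36), 6)
  expect_equal(conv_forward(m, idk)[, , 1], m[2:5, 2:5])

  zf <- array(0, c(3, 3, 1, 2))
  out <- conv_forward(m, zf, bias = c(1.5, -2), activation = "relu")
  expect_true(all(out[, , 1] == 1.5) && all(out[, , 2] == 0))

  expect_error(conv_forward(array(1, c(4, 4, 2)), array(1, c(3, 3, 1, 1))),
               "channels")
  expect_error(conv_forward(matrix(1, 2, 2), array(1, c(3, 3, 1, 1))),
               "larger")
})

test_that("pooling matches the loop oracle for both kinds", {
  expect_equal(pool_forward(matrix(c(1, 3, 2, 4), 2), "max")[1, 1, 1], 4)
  expect_equal(pool_forward(matrix(c(1, 3, 2, 4), 2), "average")[1, 1, 1], 2.5)
  expect_equal(pool_forward(matrix(7, 4, 4), "max"),
               array(7, c(2, 2, 1)))
  set.seed(41)
  x <- matrix(rnorm(36), 6)
  pf <- pool_forward(x, "max", 2)
  for (r in 1:3) for (cc in 1:3) {
    expect_equal(pf[r, cc, 1], max(x[(2 * r - 1):(2 * r), (2 * cc - 1):(2 * cc)]))
  }
  expect_error(pool_forward(matrix(1, 2, 2), window = 5), "window larger")
})

test_that("weight flatten/unflatten is a bijection", {
  cfg <- cnn_config(letters[1:4], input_mode = "grid",
                    modules = list(list(maps = 4L, kernel = 3L, pool = 2L,
                                        pool_kind = "max")), fc = c(8L))
  shapes <- retinograde:::cnn_shapes(cfg, 25)
  ds <- retinograde:::cnn_dim(shapes)
  set.seed(42)
  w <- rnorm(ds)
  W <- retinograde:::cnn_unflatten(w, shapes)
  flat <- unlist(lapply(W, as.numeric), use.names = FALSE)
  expect_equal(flat, w)
})

test_that("swarm initialization assigns roles by fitness", {
  sphere <- function(w) sum(w^2)
  s <- csa_init(sphere, ds = 5, n = 10, fractions = c(0.2, 0.6, 0.2),
                seed = 2)
  expect_equal(length(s$roosters), 2)
  expect_equal(length(s$hens), 6)
  expect_equal(length(s$chicks), 2)
  expect_true(which.min(s$fv) %in% s$roosters)
  expect_true(all(s$fv[s$chicks] >= max(s$fv[s$roosters])))
  s2 <- csa_init(sphere, ds = 5, n = 10, fractions = c(0.2, 0.6, 0.2),
                 seed = 2)
  expect_identical(s$pos, s2$pos)
  expect_error(csa_init(sphere, 5, n = 4, fractions = c(0.5, 0.1, 0.5)),
               "hens")
})

test_that("the rooster variance case split holds", {
  expect_equal(retinograde:::rooster_sigma2(1, 2), 1)      # m at least as fit
  expect_equal(retinograde:::rooster_sigma2(1, 1), 1)
  s2 <- retinograde:::rooster_sigma2(2, 1)
  expect_equal(s2, exp((1 - 2) / (2 + 1e-12)))
  expect_lt(s2, 1)
})

test_that("a hen worse than both attractors gets S2 < 1 < S1", {
  fv_m <- 3; fv_ro1 <- 1; fv_ro2 <- 2; eps <- 1e-12
  S1 <- exp((fv_m - fv_ro1) / (abs(fv_m) + eps))
  S2 <- exp(fv_ro2 - fv_m)
  expect_lt(S2, 1)
  expect_gt(S1, 1)
})

test_that("FL = 0 leaves a chick exactly at its previous position", {
  # the chick update is A + FL * (A_mother - A); with FL = 0 it is A
  A <- c(0.3, -0.2); Am <- c(0.9, 0.1)
  expect_equal(A + 0 * (Am - A), A)
})

test_that("the archive is elitist and the sphere benchmark converges", {
  sphere <- function(w) sum(w^2)
  res <- csa_optimize(sphere, ds = 10, n = 15, steps = 80, seed = 3)
  expect_true(all(diff(res$trace) <= 1e-15))
  init_best <- csa_init(sphere, 10, n = 15, seed = 3)$best_fv
  expect_lt(res$value, init_best)
})

test_that("the classifier fits separable blobs and predicts consistently", {
  set.seed(44)
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, -2), n), matrix(rnorm(n * 3, 2), n))
  colnames(X) <- paste0("f", 1:3)
  y <- factor(rep(c("a", "b"), each = n))
  m <- train_grade_classifier(X, y, steps = 80, seed = 1)
  expect_equal(mean(predict(m, X) == y), 1)

  m2 <- train_grade_classifier(X, y, steps = 80, seed = 1)
  expect_identical(m$weights, m2$weights)

  # elitism: final fitness no worse than the best initial member
  expect_true(all(diff(m$trace) <= 1e-15))

  # row permutation permutes predictions; duplicates duplicate
  perm <- sample(nrow(X))
  expect_equal(predict(m, X[perm, ]), predict(m, X)[perm])
  expect_equal(predict(m, X[c(1, 1), ])[1], predict(m, X[c(1, 1), ])[2])

  Xbad <- X[, 1:2]
  expect_error(predict(m, Xbad), "missing")
})

test_that("the grid-mode network runs a full forward pass", {
  set.seed(45)
  X <- matrix(rnorm(40 * 25), 40)
  colnames(X) <- paste0("g", 1:25)
  y <- factor(rep(c("p", "q"), 20))
  cfg <- cnn_config(levels(y), input_mode = "grid",
                    modules = list(list(maps = 3L, kernel = 3L, pool = 2L,
                                        pool_kind = "max")), fc = c(6L))
  m <- train_grade_classifier(X, y, cfg = cfg, steps = 10, n_swarm = 10,
                              seed = 2)
  p <- predict(m, X)
  expect_length(p, 40)
  expect_true(all(p %in% levels(y)))
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  pred <- c(rep("pos", 40), rep("neg", 10), rep("pos", 5), rep("neg", 45))
  tru <- c(rep("pos", 50), rep("neg", 50))
  m <- evaluate_metrics(pred, tru)
  pc <- m$per_class
  expect_equal(m$accuracy, 0.85)
  expect_equal(pc$sensitivity[pc$class == "pos"], 0.8)
  expect_equal(pc$specificity[pc$class == "pos"], 0.9)
  expect_equal(pc$precision[pc$class == "pos"], 8 / 9)

  perfect <- evaluate_metrics(tru, tru)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$macro == 1))

  allone <- evaluate_metrics(rep("a", 40), rep(c("a", "b", "c", "d"), 10))
  expect_equal(allone$accuracy, 0.25)

  expect_error(evaluate_metrics(c("a", "z"), c("a", "b"),
                                classes = c("a", "b")), "class map")
  expect_error(evaluate_metrics("a", c("a", "b")), "lengths differ")
})
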