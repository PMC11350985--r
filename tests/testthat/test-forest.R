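# Gini impurity, penalized forests and two-stage feature selection

test_that("gini impurity follows the class-fraction formula", {
  expect_equal(gini_impurity(1), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(0.25, 0.75)), 0.375)
  expect_error(gini_impurity(c(0.5, 0.4)), "sum to 1")
  expect_error(gini_impurity(c(-0.1, 1.1)), "non-negative")
})

test_that("gini gain is the weighted impurity reduction", {
  expect_equal(gini_gain(c(0.5, 0.5), c(1, 0), c(0, 1), 0.5), 0.5)
  expect_equal(gini_gain(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7), 0.4), 0)
})

test_that("the best split matches exhaustive enumeration", {
  set.seed(30)
  for (rep in 1:5) {
    n <- 20
    x <- rnorm(n)
    y <- as.integer(runif(n) < 0.5) + 1L
    if (length(unique(y)) < 2) next
    pg <- 1 - sum((tabulate(y, 2) / n)^2)
    sp <- retinograde:::best_split_feature(x, y, 2, pg)
    best <- -Inf
    for (t_ in sort(unique(x))[-n]) {
      l <- y[x <= t_]; r <- y[x > t_]
      g <- pg -
        length(l) / n * (1 - sum((tabulate(l, 2) / length(l))^2)) -
        length(r) / n * (1 - sum((tabulate(r, 2) / length(r))^2))
      best <- max(best, g)
    }
    expect_equal(unname(sp["gain"]), best, tolerance = 1e-12)
  }
})

test_that("importance behaves at the extremes", {
  set.seed(31)
  X <- matrix(rnorm(200), 50, 4)
  y <- factor(X[, 1] > 0)
  f <- fit_gini_forest(X, y, regularization_config(n_tree = 30, seed = 1))
  expect_equal(unname(f$importance_norm[1]), 1)
  expect_true(all(f$importance_norm[-1] < 0.5))

  # identical seeds give identical scores
  f2 <- fit_gini_forest(X, y, regularization_config(n_tree = 30, seed = 1))
  expect_identical(f$importance, f2$importance)

  expect_error(fit_gini_forest(X, factor(rep("a", 50)),
                               regularization_config()), "2 classes")
})

test_that("independent labels leave no feature above the permutation null", {
  set.seed(32)
  X <- matrix(rnorm(80 * 10), 80)
  y <- factor(rep(c("a", "b"), 40))
  f <- fit_gini_forest(X, y, regularization_config(n_tree = 60, seed = 2))
  # permutation null: refit on shuffled labels several times
  null_max <- replicate(5, {
    yp <- sample(y)
    max(fit_gini_forest(X, yp,
                        regularization_config(n_tree = 60,
                                              seed = sample.int(1000, 1))
        )$importance)
  })
  expect_lt(max(f$importance), max(null_max) * 1.5)
})

test_that("lambda coefficients follow the penalty formula", {
  set.seed(33)
  d <- simulate_feature_set(n = 80, p = 12, informative = 3, seed = 4)
  for (g in c(0, 0.5, 1)) {
    sel <- select_features(d$X, d$y, regularization_config(
      gamma = g, n_tree = 40, seed = 4))
    lam <- attr(sel, "lambda")
    s1 <- fit_gini_forest(d$X, d$y, regularization_config(
      gamma = g, n_tree = 40, seed = 4))
    expect_equal(unname(lam), unname(1 - g + g * s1$importance_norm))
    expect_true(all(lam >= 1 - g - 1e-12 & lam <= 1 + 1e-12))
  }
})

test_that("selection recovers an informative subset and ranks it", {
  d <- simulate_feature_set(seed = 9)
  sel <- select_features(d$X, d$y,
                         regularization_config(gamma = 0.7, seed = 9))
  expect_true(all(d$informative %in% sel))
  expect_lte(sum(!(sel %in% d$informative)), 3)
  imp <- attr(sel, "importance_norm")
  expect_true(all(diff(imp[sel]) <= 1e-12))   # ranked by importance
})

test_that("larger gamma never enlarges the selected set", {
  d <- simulate_feature_set(n = 90, p = 25, informative = 4, seed = 5)
  sizes <- vapply(c(0, 0.5, 1), function(g) {
    length(select_features(d$X, d$y, regularization_config(
      gamma = g, n_tree = 60, seed = 5)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("gini importance agrees with an independent implementation", {
  skip_if_not_installed("randomForest")
  d <- simulate_feature_set(n = 100, p = 15, informative = 4, seed = 6)
  mine <- fit_gini_forest(d$X, d$y,
                          regularization_config(n_tree = 100, seed = 6))
  theirs <- randomForest::randomForest(d$X, d$y, ntree = 100,
                                       importance = FALSE)
  rho <- stats::cor(mine$importance,
                    theirs$importance[, "MeanDecreaseGini"],
                    method = "spearman")
  expect_gt(rho, 0.7)
})
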