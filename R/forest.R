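#' Gini impurity of a class-fraction vector
#'
#' \deqn{Gini(v) = \sum_i f_i (1 - f_i)}
#' where `f_i` is the fraction of class-`i` records at node `v`.
#'
#' @param f Numeric vector of non-negative class fractions summing to 1.
#' @return The impurity, in `[0, 1)`.
#' @examples
#' gini_impurity(c(0.5, 0.5))   # 0.5
#' gini_impurity(c(0.25, 0.75)) # 0.375
#' @export
gini_impurity <- function(f) {
  if (!is.numeric(f) || any(f < 0) || abs(sum(f) - 1) > 1e-8) {
    stop("class fractions must be non-negative and sum to 1", call. = FALSE)
  }
  sum(f * (1 - f))
}

#' Gini gain of a split
#'
#' The impurity reduction of splitting node `v` into children `v^L`, `v^R`
#' holding fractions `W_L`, `W_R` of the records:
#' \deqn{gain = Gini(v) - (W_L\, Gini(v^L) + W_R\, Gini(v^R)).}
#'
#' @param parent,left,right Class-fraction vectors of the node and its
#'   children.
#' @param w_left Fraction of records sent left; `w_right = 1 - w_left`.
#' @return The gain (non-negative for the best split of a node).
#' @export
gini_gain <- function(parent, left, right, w_left) {
  stopifnot(w_left >= 0, w_left <= 1)
  gini_impurity(parent) -
    (w_left * gini_impurity(left) + (1 - w_left) * gini_impurity(right))
}

# best threshold for one feature at a node given the node's values already
# in sorted order: returns c(gain, threshold) or NULL when constant.
# y_s is the integer class vector (1..K) in the same order.
best_split_sorted <- function(xs, y_s, K, parent_gini) {
  xs <- unname(xs)          # row names would leak into the returned names
  n <- length(xs)
  valid <- which(xs[-n] < xs[-1])       # split between distinct values
  if (length(valid) == 0L) return(NULL)
  cum <- matrix(0, n, K)
  for (k in seq_len(K)) cum[, k] <- cumsum(y_s == k)
  nl <- valid
  left <- cum[valid, , drop = FALSE]
  right <- matrix(cum[n, ], length(valid), K, byrow = TRUE) - left
  gl <- 1 - rowSums(left^2) / nl^2
  gr <- 1 - rowSums(right^2) / (n - nl)^2
  gain <- parent_gini - (nl / n) * gl - ((n - nl) / n) * gr
  b <- which.max(gain)
  c(gain = gain[b], threshold = (xs[valid[b]] + xs[valid[b] + 1L]) / 2)
}

# convenience wrapper used by tests/oracles on unsorted input
best_split_feature <- function(xv, y, K, parent_gini) {
  ord <- order(xv)
  best_split_sorted(xv[ord], y[ord], K, parent_gini)
}

# grow one CART tree with per-feature penalty on the Gini gain.
# lambda[i] multiplies the gain of feature i only while i is outside the
# used set carried across the forest built so far (guided regularization);
# a feature joins the set the moment any split selects it. Importance is
# accumulated from RAW (unpenalized) gains, each weighted by the fraction
# of the tree's samples reaching the node, so a split's contribution is
# proportional to the records it affects. Returns list(gains, used,
# n_splits).
grow_gini_tree <- function(X, y, K, mtry, min_split, max_depth, lambda,
                           used = rep(FALSE, ncol(X))) {
  p <- ncol(X)
  n <- nrow(X)
  gains <- numeric(p)
  # presort every feature once; nodes then recover sorted order by filtering
  ord_all <- lapply(seq_len(p), function(j) order(X[, j]))
  member <- logical(n)
  stack <- list(list(idx = seq_len(n), depth = 0L))
  n_splits <- 0L
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- nd$idx
    counts <- tabulate(y[idx], K)
    parent_gini <- 1 - sum((counts / length(idx))^2)
    if (length(idx) < min_split || parent_gini == 0 || nd$depth >= max_depth) next
    feats <- sort(sample.int(p, min(mtry, p)))
    member[] <- FALSE
    member[idx] <- TRUE
    best <- NULL
    for (f in feats) {
      o <- ord_all[[f]]
      oi <- o[member[o]]
      sp <- best_split_sorted(X[oi, f], y[oi], K, parent_gini)
      if (is.null(sp)) next
      pen_gain <- if (used[f]) sp["gain"] else lambda[f] * sp["gain"]
      if (pen_gain <= 1e-12) next
      if (is.null(best) || pen_gain > best$pen_gain + 1e-12) {
        best <- list(feature = f, gain = sp[["gain"]], pen_gain = pen_gain,
                     threshold = sp[["threshold"]])
      }
    }
    if (is.null(best)) next
    gains[best$feature] <- gains[best$feature] +
      (length(idx) / n) * best$gain
    used[best$feature] <- TRUE
    n_splits <- n_splits + 1L
    go_left <- X[idx, best$feature] <= best$threshold
    stack[[length(stack) + 1L]] <- list(idx = idx[go_left], depth = nd$depth + 1L)
    stack[[length(stack) + 1L]] <- list(idx = idx[!go_left], depth = nd$depth + 1L)
  }
  list(gains = gains, used = used, n_splits = n_splits)
}

#' Regularization and forest configuration
#'
#' Settings for [fit_gini_forest()] and [select_features()]. The per-feature
#' penalty coefficients follow
#' \deqn{\lambda_i = 1 - \gamma + \gamma\, Imp^{norm}_i \in [1-\gamma, 1],}
#' where `Imp_norm` is the normalized importance of a preliminary
#' (unpenalized) forest and the importance coefficient `gamma` in `[0, 1]`
#' sets the regularization strength: `gamma = 0` disables the penalty,
#' `gamma = 1` gives the maximum penalty `lambda_i = Imp_norm_i`.
#'
#' @param gamma Importance coefficient in `[0, 1]`. Default 0.7.
#' @param threshold Normalized-importance selection cutoff. Default 0.05.
#' @param n_tree Ensemble size. Default 200.
#' @param max_depth Depth cap per tree (`Inf` = unlimited).
#' @param mtry Features tried per split; `NULL` for `floor(sqrt(p))`.
#' @param min_split Minimum node size eligible for splitting.
#' @param seed Integer seed.
#' @return A list of class `"regularization_config"`.
#' @export
regularization_config <- function(gamma = 0.7, threshold = 0.05,
                                  n_tree = 200L, max_depth = Inf,
                                  mtry = NULL, min_split = 5L, seed = 1L) {
  stopifnot(gamma >= 0, gamma <= 1, threshold >= 0, n_tree >= 1)
  structure(list(gamma = gamma, threshold = threshold,
                 n_tree = as.integer(n_tree), max_depth = max_depth,
                 mtry = mtry, min_split = as.integer(min_split),
                 seed = as.integer(seed)),
            class = "regularization_config")
}

#' Fit a bagged Gini forest and compute feature importance
#'
#' Grows `n_tree` CART trees on bootstrap samples with a random feature
#' subset (`mtry`) considered at every split. Feature importance is the
#' per-forest average of the raw Gini gains of all splits on a feature,
#' \deqn{Imp_i = \frac{1}{n_{tree}} \sum_{k \in S_{X_i}} gain(X_i, v_k),}
#' normalized by its maximum (`Imp_norm = Imp_i / Imp_max`; all zeros when
#' every gain is zero). When `penalties` are supplied, the split criterion
#' becomes the penalized gain `gain_G = lambda_i * gain` for features not
#' yet used by the current tree.
#'
#' @param X Numeric feature matrix (no missing values).
#' @param y Class labels (factor or coercible); at least 2 classes.
#' @param cfg A [regularization_config()].
#' @param penalties Optional per-feature `lambda` vector in `[0, 1]`.
#' @return An object of class `"gini_forest"`: list with `importance`,
#'   `importance_norm`, `used` (features used by any split), `n_tree`,
#'   `levels`.
#' @export
fit_gini_forest <- function(X, y, cfg = regularization_config(),
                            penalties = NULL) {
  X <- as.matrix(X)
  stopifnot(!anyNA(X))
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) {
    stop("y must contain at least 2 classes", call. = FALSE)
  }
  yi <- as.integer(droplevels(y))
  K <- max(yi)
  p <- ncol(X)
  lambda <- if (is.null(penalties)) rep(1, p) else {
    stopifnot(length(penalties) == p, all(penalties >= 0), all(penalties <= 1))
    penalties
  }
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(p))) else cfg$mtry
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(cfg$seed)
  gains <- numeric(p)
  used <- rep(FALSE, p)
  n <- nrow(X)
  for (t in seq_len(cfg$n_tree)) {
    boot <- sample.int(n, n, replace = TRUE)
    tr <- grow_gini_tree(X[boot, , drop = FALSE], yi[boot], K, mtry,
                         cfg$min_split, cfg$max_depth, lambda, used = used)
    gains <- gains + tr$gains
    used <- tr$used
  }
  imp <- gains / cfg$n_tree
  imp_norm <- if (max(imp) > 0) imp / max(imp) else rep(0, p)
  names(imp) <- names(imp_norm) <- colnames(X)
  structure(list(importance = imp, importance_norm = imp_norm, used = used,
                 n_tree = cfg$n_tree, levels = levels(droplevels(y))),
            class = "gini_forest")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Two-stage penalized-Gini feature selection
#'
#' Stage 1 fits an unpenalized forest to obtain normalized importances.
#' Stage 2 refits with penalty coefficients
#' `lambda_i = 1 - gamma + gamma * Imp_norm_i` applied to each feature's
#' Gini gain while it is unused in the forest grown so far, which steers
#' splits toward the informative subset and keeps the set of distinct
#' split features small. The penalized stage evaluates every feature at
#' each node (`mtry = p`, unless `cfg$mtry` is set explicitly): an
#' unpenalized, already-admitted feature is then always available to
#' outcompete penalized noise, which is what makes the admitted set
#' converge. Selected features are those used by
#' stage-2 splits whose stage-2 normalized importance exceeds the
#' configured threshold, ranked by decreasing importance.
#'
#' @inheritParams fit_gini_forest
#' @return Integer vector of selected feature indices (named when `X` has
#'   column names), ordered by decreasing stage-2 normalized importance,
#'   with attributes `"importance_norm"` (stage 2) and `"lambda"`.
#' @export
select_features <- function(X, y, cfg = regularization_config()) {
  stage1 <- fit_gini_forest(X, y, cfg)
  lambda <- 1 - cfg$gamma + cfg$gamma * stage1$importance_norm
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  if (is.null(cfg2$mtry)) cfg2$mtry <- ncol(as.matrix(X))
  stage2 <- fit_gini_forest(X, y, cfg2, penalties = lambda)
  keep <- which(stage2$used & stage2$importance_norm > cfg$threshold)
  sel <- keep[order(stage2$importance_norm[keep], decreasing = TRUE)]
  names(sel) <- colnames(X)[sel]
  attr(sel, "importance_norm") <- stage2$importance_norm
  attr(sel, "lambda") <- lambda
  sel
}

#' Synthetic feature-selection benchmark
#'
#' Generates a two-class feature matrix with a known informative subset:
#' the first `informative` columns are class-shifted Gaussians (shift
#' `effect` standard deviations), the rest are pure noise. Used to measure
#' recovery of the informative set by [select_features()].
#'
#' @param n Number of samples (split evenly across the classes).
#' @param p Total number of features.
#' @param informative Number of informative features (the first columns).
#' @param effect Class mean shift in SD units. Default 1.5.
#' @param seed Integer seed.
#' @return List with `X` (matrix with named columns), `y` (factor) and
#'   `informative` (indices of the informative columns).
#' @export
simulate_feature_set <- function(n = 120L, p = 50L, informative = 5L,
                                 effect = 1.5, seed = 1L) {
  stopifnot(informative <= p, n >= 4L)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- matrix(stats::rnorm(n * p), n, p)
  shift <- effect * (as.integer(y) - 1.5)       # -effect/2, +effect/2
  for (j in seq_len(informative)) X[, j] <- X[, j] + shift
  colnames(X) <- sprintf("f%03d", seq_len(p))
  list(X = X, y = y, informative = seq_len(informative))
}
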