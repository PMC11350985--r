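#' Convolution-layer forward pass
#'
#' Valid cross-correlation of a map stack with a filter bank, plus additive
#' bias and pointwise activation:
#' \deqn{x_e = f(FM_e * I + Bi_e).}
#' The correlation convention is `out[r, c] = sum_{dr, dc, ch}
#' input[r+dr-1, c+dc-1, ch] * filters[dr, dc, ch, e]` (no kernel flip).
#'
#' @param input Numeric array `H x W x C` (a matrix is treated as `C = 1`).
#' @param filters Numeric array `kh x kw x C x F`.
#' @param bias Numeric length-`F` vector (default zeros).
#' @param activation `"identity"`, `"relu"` or `"tanh"`, or a function.
#' @return Numeric array `(H-kh+1) x (W-kw+1) x F`.
#' @export
conv_forward <- function(input, filters, bias = NULL, activation = "identity") {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  di <- dim(input); df <- dim(filters)
  stopifnot(length(di) == 3L, length(df) == 4L)
  if (di[3] != df[3]) {
    stop(sprintf("input has %d channels but filters expect %d", di[3], df[3]),
         call. = FALSE)
  }
  if (df[1] > di[1] || df[2] > di[2]) {
    stop("filter larger than input map", call. = FALSE)
  }
  f <- activation_fun(activation)
  if (is.null(bias)) bias <- numeric(df[4])
  stopifnot(length(bias) == df[4])
  oh <- di[1] - df[1] + 1L
  ow <- di[2] - df[2] + 1L
  # im2col: rows = output positions (column-major), cols = kh*kw*C taps
  cols <- matrix(0, oh * ow, df[1] * df[2] * di[3])
  t <- 0L
  for (ch in seq_len(di[3])) for (dc in seq_len(df[2])) for (dr in seq_len(df[1])) {
    t <- t + 1L
    cols[, t] <- input[dr:(dr + oh - 1L), dc:(dc + ow - 1L), ch]
  }
  W <- matrix(filters, ncol = df[4])   # taps in the same (dr, dc, ch) order
  out <- cols %*% W
  out <- sweep(out, 2L, bias, "+")
  array(f(out), c(oh, ow, df[4]))
}

activation_fun <- function(activation) {
  if (is.function(activation)) return(activation)
  switch(activation,
    identity = function(x) x,
    relu = function(x) pmax(x, 0),
    tanh = tanh,
    piecewise_tanh = piecewise_tanh,
    stop("unknown activation ", deparse(activation), call. = FALSE)
  )
}

#' Pooling-layer forward pass
#'
#' Reduces the spatial resolution of each map by a square window; the
#' salient element of each field is kept with max pooling (the default),
#' or averaged with mean pooling. Maps whose sides are not multiples of the
#' window are edge-replicated up to the next multiple.
#'
#' @param input Numeric array `H x W x C` (or matrix).
#' @param kind `"max"` or `"average"`.
#' @param window Pooling window side (default 2).
#' @return Array `ceiling(H/window) x ceiling(W/window) x C`.
#' @export
pool_forward <- function(input, kind = c("max", "average"), window = 2L) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  if (is.matrix(input)) input <- array(input, c(dim(input), 1L))
  di <- dim(input)
  if (window > di[1] || window > di[2]) {
    stop("pooling window larger than map", call. = FALSE)
  }
  rows <- rep(seq_len(di[1]), length.out = ceiling(di[1] / window) * window)
  rows[rows > di[1]] <- di[1]
  ri <- c(seq_len(di[1]), rep(di[1], ceiling(di[1] / window) * window - di[1]))
  ci <- c(seq_len(di[2]), rep(di[2], ceiling(di[2] / window) * window - di[2]))
  x <- input[ri, ci, , drop = FALSE]
  dh <- dim(x)[1] %/% window
  dw <- dim(x)[2] %/% window
  out <- array(0, c(dh, dw, di[3]))
  agg <- if (kind == "max") max else mean
  for (ch in seq_len(di[3])) {
    m <- x[, , ch]
    dim(m) <- c(window, dh, window, dw)
    out[, , ch] <- apply(m, c(2, 4), agg)
  }
  out
}

#' Classifier network configuration
#'
#' Architecture of the grade classifier whose weights are optimized by the
#' chicken swarm. Two input modes are supported: `"grid"` reshapes the
#' selected feature vector into a zero-padded square map and applies the
#' convolution/pooling modules followed by the fully connected head;
#' `"mlp"` skips the convolutional modules and feeds the feature vector
#' straight into the fully connected head.
#'
#' @param classes Character vector of class labels (the output width).
#' @param input_mode `"mlp"` (default) or `"grid"`.
#' @param modules For `"grid"`: list of modules, each
#'   `list(maps =, kernel =, pool =, pool_kind =)`.
#' @param fc Hidden fully-connected widths (possibly empty).
#' @param activation Hidden activation name.
#' @return Object of class `"cnn_config"`.
#' @export
cnn_config <- function(classes,
                       input_mode = c("mlp", "grid"),
                       modules = list(
                         list(maps = 8L, kernel = 3L, pool = 2L, pool_kind = "max"),
                         list(maps = 16L, kernel = 3L, pool = 2L, pool_kind = "max")
                       ),
                       fc = c(24L),
                       activation = "tanh") {
  input_mode <- match.arg(input_mode)
  stopifnot(length(classes) >= 2L)
  if (input_mode == "grid" && length(modules) < 1L) {
    stop("grid mode needs at least one convolution module", call. = FALSE)
  }
  structure(list(classes = as.character(classes), input_mode = input_mode,
                 modules = modules, fc = as.integer(fc),
                 activation = activation),
            class = "cnn_config")
}

# shapes of every weight array for a config and input dimension d
cnn_shapes <- function(cfg, d) {
  shapes <- list()
  if (cfg$input_mode == "grid") {
    g <- ceiling(sqrt(d))
    h <- g; w <- g; ch <- 1L
    for (i in seq_along(cfg$modules)) {
      m <- cfg$modules[[i]]
      shapes[[paste0("conv", i)]] <- c(m$kernel, m$kernel, ch, m$maps)
      shapes[[paste0("convb", i)]] <- m$maps
      h <- h - m$kernel + 1L; w <- w - m$kernel + 1L
      if (h < 1L || w < 1L) stop("feature grid too small for the module stack",
                                 call. = FALSE)
      h <- ceiling(h / m$pool); w <- ceiling(w / m$pool)
      ch <- m$maps
    }
    d <- h * w * ch
  }
  widths <- c(d, cfg$fc, length(cfg$classes))
  for (i in seq_len(length(widths) - 1L)) {
    shapes[[paste0("fc", i)]] <- c(widths[i], widths[i + 1L])
    shapes[[paste0("fcb", i)]] <- widths[i + 1L]
  }
  shapes
}

# bijective flatten/unflatten between a weight list and one vector
cnn_unflatten <- function(w, shapes) {
  out <- list()
  at <- 0L
  for (nm in names(shapes)) {
    sz <- prod(shapes[[nm]])
    out[[nm]] <- array(w[at + seq_len(sz)], shapes[[nm]])
    at <- at + sz
  }
  stopifnot(at == length(w))
  out
}

cnn_dim <- function(shapes) sum(vapply(shapes, prod, numeric(1)))

# forward pass: X is n x d (rows = samples); returns n x K score matrix
cnn_scores <- function(X, weights, cfg) {
  act <- activation_fun(cfg$activation)
  if (cfg$input_mode == "grid") {
    g <- ceiling(sqrt(ncol(X)))
    feats <- t(apply(X, 1, function(row) {
      m <- matrix(0, g, g)
      m[seq_along(row)] <- row
      a <- array(m, c(g, g, 1L))
      for (i in seq_along(cfg$modules)) {
        mod <- cfg$modules[[i]]
        a <- conv_forward(a, weights[[paste0("conv", i)]],
                          weights[[paste0("convb", i)]], act)
        a <- pool_forward(a, mod$pool_kind, mod$pool)
      }
      as.numeric(a)
    }))
    X <- feats
  }
  n_fc <- sum(grepl("^fc[0-9]+$", names(weights)))
  a <- X
  for (i in seq_len(n_fc)) {
    a <- sweep(a %*% weights[[paste0("fc", i)]], 2L,
               weights[[paste0("fcb", i)]], "+")
    if (i < n_fc) a <- act(a)
  }
  a
}

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# per-feature ECDF rank transform to [-1, 1]; reference columns are the
# sorted training values (threshold-like features — counts, distances with
# out-of-field sentinels — become uniformly spread, which the tanh network
# handles far better than raw scales)
rank_transform <- function(X, ref) {
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- 2 * findInterval(X[, j], ref[[j]]) / length(ref[[j]]) - 1
  }
  out
}

# gradient pretraining of the fully-connected head (Adam on the softmax
# cross-entropy); returns the flattened weight vector
pretrain_head <- function(Xs, y, cfg, shapes, steps, decay, lr = 0.05) {
  widths <- c(ncol(Xs), cfg$fc, length(cfg$classes))
  L <- length(widths) - 1L
  W <- list(); B <- list()
  for (i in seq_len(L)) {
    W[[i]] <- matrix(stats::rnorm(widths[i] * widths[i + 1],
                                  0, 1 / sqrt(widths[i])),
                     widths[i], widths[i + 1])
    B[[i]] <- numeric(widths[i + 1])
  }
  n <- nrow(Xs); K <- widths[L + 1L]
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(B, function(b) b * 0); vB <- mB
  act <- activation_fun(cfg$activation)
  for (it in seq_len(steps)) {
    A <- list(Xs)
    for (i in seq_len(L)) {
      z <- sweep(A[[i]] %*% W[[i]], 2, B[[i]], "+")
      A[[i + 1L]] <- if (i < L) act(z) else z
    }
    Pr <- softmax_rows(A[[L + 1L]])
    delta <- (Pr - Y) / n
    for (i in rev(seq_len(L))) {
      gW <- t(A[[i]]) %*% delta + decay * W[[i]]
      gB <- colSums(delta)
      if (i > 1L) delta <- (delta %*% t(W[[i]])) * (1 - A[[i]]^2)
      mW[[i]] <- 0.9 * mW[[i]] + 0.1 * gW
      vW[[i]] <- 0.999 * vW[[i]] + 0.001 * gW^2
      W[[i]] <- W[[i]] - lr * (mW[[i]] / (1 - 0.9^it)) /
        (sqrt(vW[[i]] / (1 - 0.999^it)) + 1e-8)
      mB[[i]] <- 0.9 * mB[[i]] + 0.1 * gB
      vB[[i]] <- 0.999 * vB[[i]] + 0.001 * gB^2
      B[[i]] <- B[[i]] - lr * (mB[[i]] / (1 - 0.9^it)) /
        (sqrt(vB[[i]] / (1 - 0.999^it)) + 1e-8)
    }
  }
  w <- numeric(0)
  for (i in seq_len(L)) w <- c(w, as.numeric(W[[i]]), B[[i]])
  stopifnot(length(w) == cnn_dim(shapes))
  w
}

#' Train the swarm-optimized grade classifier
#'
#' Features are rank-transformed (per-feature ECDF to `[-1, 1]`, reference
#' stored in the model) and all network weights are flattened into one
#' vector. In the default fully-connected mode the head is first fitted by
#' gradient descent (Adam on the softmax cross-entropy), and the chicken
#' swarm then refines the weights: the swarm starts as a cloud around the
#' trained solution and minimizes the misclassification rate on an
#' internal stratified held-out fold with a small cross-entropy tie-break
#' (`fitness = error_rate + 0.01 * cross_entropy`). The best-ever position
#' is archived, so the returned weights are never worse (in fitness) than
#' either the trained solution or the best initial member. In `"grid"`
#' mode, where the convolutional stack has no gradient implementation, the
#' swarm searches from random positions alone.
#'
#' @param features Numeric matrix (rows = samples) with column names.
#' @param labels Factor (or coercible) of class labels per row.
#' @param cfg A [cnn_config()]; `NULL` builds an MLP config over the
#'   observed classes.
#' @param steps,n_swarm Chicken-swarm controls.
#' @param bounds Search box; `NULL` adapts to the pretrained weight range.
#' @param holdout Fraction of rows used as the internal fitness fold.
#' @param pretrain_steps Gradient steps before the swarm (MLP mode).
#' @param decay L2 penalty during pretraining.
#' @param seed Integer seed controlling the fold split, pretraining and
#'   the swarm.
#' @return Object of class `"grade_classifier"`.
#' @export
train_grade_classifier <- function(features, labels, cfg = NULL,
                                   steps = 150L, n_swarm = 30L,
                                   bounds = NULL, holdout = 0.25,
                                   pretrain_steps = 600L, decay = 5e-3,
                                   seed = 1L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(cfg)) cfg <- cnn_config(levels(labels), input_mode = "mlp")
  if (!setequal(cfg$classes, levels(labels))) {
    cfg$classes <- levels(labels)
  }
  set.seed(seed)
  rank_ref <- lapply(seq_len(ncol(features)),
                     function(j) sort(features[, j]))
  Xs <- rank_transform(features, rank_ref)
  y <- as.integer(labels)

  # stratified internal fold for the fitness
  fold <- unlist(lapply(split(seq_along(y), y), function(ix) {
    k <- max(1L, round(length(ix) * holdout))
    sample(ix, k)
  }), use.names = FALSE)
  if (length(fold) >= length(y)) fold <- fold[-1]
  Xf <- Xs[fold, , drop = FALSE]; yf <- y[fold]

  shapes <- cnn_shapes(cfg, ncol(Xs))
  ds <- cnn_dim(shapes)
  objective <- function(w) {
    W <- cnn_unflatten(w, shapes)
    sc <- cnn_scores(Xf, W, cfg)
    pred <- max.col(sc, ties.method = "first")
    pr <- softmax_rows(sc)
    ce <- -mean(log(pmax(pr[cbind(seq_along(yf), yf)], 1e-12)))
    mean(pred != yf) + 0.01 * ce
  }

  init <- NULL
  if (cfg$input_mode == "mlp" && pretrain_steps > 0L) {
    w0 <- pretrain_head(Xs, y, cfg, shapes, pretrain_steps, decay)
    if (is.null(bounds)) bounds <- max(1.5, 1.25 * max(abs(w0))) * c(-1, 1)
    init <- rbind(w0, t(w0 + 0.05 * max(abs(w0)) *
                          matrix(stats::rnorm(ds * (n_swarm - 1L)), ds)))
  }
  if (is.null(bounds)) bounds <- c(-1, 1)
  res <- csa_optimize(objective, ds, steps = steps, n = n_swarm,
                      bounds = bounds, init = init, seed = seed)
  structure(list(cfg = cfg, shapes = shapes,
                 weights = cnn_unflatten(res$par, shapes),
                 rank_ref = rank_ref,
                 feature_names = colnames(features),
                 fitness = res$value, trace = res$trace, seed = seed),
            class = "grade_classifier")
}

#' Predict grade labels
#'
#' @param object A `"grade_classifier"`.
#' @param features Feature matrix whose column names match training.
#' @param ... Unused.
#' @return Factor of predicted labels, one per row.
#' @export
predict.grade_classifier <- function(object, features, ...) {
  features <- as.matrix(features)
  if (!is.null(object$feature_names)) {
    missing <- setdiff(object$feature_names, colnames(features))
    if (length(missing) > 0L) {
      stop("features missing from input: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    features <- features[, object$feature_names, drop = FALSE]
  }
  Xs <- rank_transform(features, object$rank_ref)
  sc <- cnn_scores(Xs, object$weights, object$cfg)
  factor(object$cfg$classes[max.col(sc, ties.method = "first")],
         levels = object$cfg$classes)
}

#' Multi-class classification metrics
#'
#' Confusion matrix plus the five headline metrics: accuracy
#' (`trace / total`) and macro-averaged one-vs-rest sensitivity (recall),
#' specificity, precision and F1. Macro averages run over the classes
#' present in the truth; a class never predicted contributes precision 0.
#'
#' @param predicted,truth Equal-length label vectors (factor/character).
#' @param classes Optional class universe; defaults to the union of levels.
#' @return Object of class `"grade_metrics"`: list with `confusion`,
#'   `accuracy`, `macro` (named vector: sensitivity, specificity,
#'   precision, f1) and `per_class` data frame.
#' @export
evaluate_metrics <- function(predicted, truth, classes = NULL) {
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth lengths differ", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(predicted, truth)))
  if (!all(predicted %in% classes) || !all(truth %in% classes)) {
    stop("labels outside the class map", call. = FALSE)
  }
  p <- factor(predicted, levels = classes)
  t_ <- factor(truth, levels = classes)
  cm <- table(truth = t_, predicted = p)
  n <- length(truth)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- n - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  f1 <- ifelse(!is.na(sens) & (prec + sens) > 0,
               2 * prec * sens / (prec + sens), 0)
  present <- rowSums(cm) > 0
  per_class <- data.frame(class = classes, support = as.integer(rowSums(cm)),
                          sensitivity = as.numeric(sens),
                          specificity = as.numeric(spec),
                          precision = as.numeric(prec), f1 = as.numeric(f1))
  structure(list(
    confusion = cm,
    accuracy = sum(tp) / n,
    macro = c(sensitivity = mean(sens[present]),
              specificity = mean(spec[present]),
              precision = mean(prec[present]),
              f1 = mean(f1[present])),
    per_class = per_class
  ), class = "grade_metrics")
}

#' @export
print.grade_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro sensitivity %.4f specificity %.4f precision %.4f F1 %.4f\n",
              x$accuracy, x$macro["sensitivity"], x$macro["specificity"],
              x$macro["precision"], x$macro["f1"]))
  print(x$confusion)
  invisible(x)
}
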