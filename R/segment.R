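#' Multilayer-perceptron segmenter configuration
#'
#' A three-layer feed-forward network (input, hidden, output). The number
#' of multipliers a direct hardware realization needs is `M * W * N`
#' ([multiplier_count()]); replacing every weight by a signed sum of at
#' most `S` power-of-two terms turns each multiplier into a few shifters
#' and adders.
#'
#' @param M Input count (patch pixels plus positional inputs).
#' @param W Hidden-node count.
#' @param N Output count (segmentation classes).
#' @param S Maximum shift depth for quantization (default 3).
#' @return Object of class `"mlp_config"`.
#' @export
mlp_config <- function(M, W, N, S = 3L) {
  M <- as.integer(M); W <- as.integer(W); N <- as.integer(N); S <- as.integer(S)
  if (any(c(M, W, N) < 1L)) {
    stop("M, W and N must all be positive", call. = FALSE)
  }
  stopifnot(S >= 1L)
  structure(list(M = M, W = W, N = N, S = S), class = "mlp_config")
}

#' @rdname mlp_config
#' @param cfg An `"mlp_config"`.
#' @return For `multiplier_count()`, the integer `M * W * N`.
#' @examples
#' multiplier_count(mlp_config(4, 5, 3))  # 60
#' @export
multiplier_count <- function(cfg) {
  stopifnot(inherits(cfg, "mlp_config"))
  cfg$M * cfg$W * cfg$N
}

# im2col patch matrix with reflect padding + 2 positional inputs, rows in
# column-major pixel order
patch_matrix <- function(img, patch) {
  k <- (patch - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  P <- img[reflect_idx(nr, k), reflect_idx(nc, k)]
  X <- matrix(0, nr * nc, patch * patch + 2L)
  t <- 0L
  for (dc in seq_len(patch)) for (dr in seq_len(patch)) {
    t <- t + 1L
    X[, t] <- P[(dr - 1L) + seq_len(nr), (dc - 1L) + seq_len(nc)]
  }
  X[, patch * patch + 1L] <- rep((seq_len(nr) - (nr + 1) / 2) / (nr / 2), nc)
  X[, patch * patch + 2L] <- rep((seq_len(nc) - (nc + 1) / 2) / (nc / 2),
                                 each = nr)
  X
}

#' Train the pixel-wise fundus segmenter
#'
#' Trains a small MLP that classifies every pixel of a preprocessed fundus
#' image into the [seg_class_map()] classes from a sliding square patch
#' plus two normalized position inputs (the fovea and optic disc are
#' anatomically localized, so position disambiguates dark/bright blobs).
#' Training pixels are sampled from the ground-truth masks of the supplied
#' synthetic samples, with scarce lesion classes oversampled (with
#' replacement, up to `oversample_cap` times their pixel count per image)
#' and the cross-entropy additionally class-weighted by inverse frequency
#' to the power `weight_power`, so small lesions are learned without
#' drowning out the anatomy. The float weights are fitted by minibatch
#' Adam on the weighted softmax cross-entropy. Quantization is applied
#' afterwards with [quantize_segmenter()]. Deterministic for a fixed seed.
#'
#' @param samples List of `"fundus_sample"` objects carrying masks.
#' @param hidden Hidden-node count `W`. Default 48.
#' @param patch Patch side length (odd). Default 9.
#' @param per_class Training-pixel quota per class per image.
#' @param oversample_cap Maximum oversampling factor for scarce classes.
#' @param steps,batch,lr Adam minibatch iteration count, batch size and
#'   step size.
#' @param decay L2 weight-decay coefficient; keeps the weight dynamic
#'   range narrow, which the coarse shift-add grid rewards.
#' @param weight_power Exponent on the inverse class frequency used as the
#'   loss weight (0 = unweighted, 1 = fully balanced).
#' @param preprocess Function mapping an RGB array to the intensity raster
#'   the segmenter operates on; defaults to [preprocess_fundus()] at the
#'   sample's own resolution.
#' @param seed Integer seed.
#' @return Object of class `"fundus_segmenter"` with the float weights,
#'   the configuration and (initially `NULL`) quantized weights.
#' @export
train_segmenter <- function(samples, hidden = 48L, patch = 9L,
                            per_class = 250L, oversample_cap = 6L,
                            steps = 2500L, batch = 1024L, lr = 0.01,
                            decay = 2e-3, weight_power = 0.5,
                            preprocess = NULL, seed = 1L) {
  if (length(samples) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(patch %% 2L == 1L)
  if (is.null(preprocess)) {
    preprocess <- function(img) preprocess_fundus(img, target_size = dim(img)[1:2])
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  classes <- seg_class_map()
  Xs <- list(); ys <- list(); calib <- list()
  for (s in samples) {
    img <- preprocess(s$image)
    truth <- seg_truth(s)
    pm <- patch_matrix(img, patch)
    calib[[length(calib) + 1L]] <-
      pm[sample(nrow(pm), min(2500L, nrow(pm))), , drop = FALSE]
    for (ci in seq_along(classes)) {
      ix <- which(truth == classes[ci])
      if (length(ix) == 0L) next
      quota <- min(per_class, oversample_cap * length(ix))
      take <- if (length(ix) >= quota) sample(ix, quota)
              else sample(ix, quota, replace = TRUE)
      Xs[[length(Xs) + 1L]] <- pm[take, , drop = FALSE]
      ys[[length(ys) + 1L]] <- rep(ci, length(take))
    }
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  M <- ncol(X); W <- as.integer(hidden); N <- length(classes)
  cfg <- mlp_config(M, W, N)
  nobs <- nrow(X)
  batch <- min(batch, nobs)
  cw <- (nobs / (N * tabulate(y, N)))^weight_power
  cw[!is.finite(cw)] <- 0

  w1 <- matrix(stats::rnorm(M * W, 0, 1 / sqrt(M)), M, W)
  b1 <- numeric(W)
  w2 <- matrix(stats::rnorm(W * N, 0, 1 / sqrt(W)), W, N)
  b2 <- numeric(N)
  ms <- list(w1 = w1 * 0, b1 = b1, w2 = w2 * 0, b2 = b2)
  vs <- ms
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8
  for (it in seq_len(steps)) {
    bi <- sample.int(nobs, batch)
    Xb <- X[bi, , drop = FALSE]
    yb <- y[bi]
    rw <- cw[yb]; rw <- rw / sum(rw)
    Yb <- matrix(0, batch, N); Yb[cbind(seq_len(batch), yb)] <- 1
    H <- tanh(sweep(Xb %*% w1, 2, b1, "+"))
    Pr <- softmax_rows(sweep(H %*% w2, 2, b2, "+"))
    d2 <- (Pr - Yb) * rw
    dh <- (d2 %*% t(w2)) * (1 - H^2)
    g <- list(w1 = t(Xb) %*% dh + decay * w1, b1 = colSums(dh),
              w2 = t(H) %*% d2 + decay * w2, b2 = colSums(d2))
    for (nm in names(ms)) {
      ms[[nm]] <- b1m * ms[[nm]] + (1 - b1m) * g[[nm]]
      vs[[nm]] <- b2m * vs[[nm]] + (1 - b2m) * g[[nm]]^2
      step <- lr * (ms[[nm]] / (1 - b1m^it)) /
        (sqrt(vs[[nm]] / (1 - b2m^it)) + eps)
      if (nm == "w1") w1 <- w1 - step
      if (nm == "b1") b1 <- b1 - step
      if (nm == "w2") w2 <- w2 - step
      if (nm == "b2") b2 <- b2 - step
    }
  }
  structure(list(cfg = cfg, patch = as.integer(patch), classes = classes,
                 weights = list(w1 = w1, b1 = b1, w2 = w2, b2 = b2),
                 quantized = NULL, preprocess = preprocess,
                 calibration = do.call(rbind, calib), seed = seed),
            class = "fundus_segmenter")
}

#' Quantize every segmenter weight to shift-add form
#'
#' Every output neuron's incoming weight column (and each bias vector) is
#' pre-scaled by its own power of two — so the rescaling is itself a
#' bit-shift — such that all entries fall in `(-1, 1)`, then quantized with
#' [quantize_with_diffusion()], the errors diffusing along the column in
#' input order. The quantized forward pass additionally replaces `tanh` by
#' [piecewise_tanh()], so inference needs no multiplications beyond shifts
#' and adds.
#'
#' Two error-compensation steps keep the quantized forward pass close to
#' the float one (both computed from the calibration patches stored at
#' training time, when present): the expected pre-activation shift caused
#' by weight rounding is folded into each bias before the bias itself is
#' quantized, and the output layer is re-fitted in closed form (ridge
#' regression of the float model's logits on the quantized hidden
#' activations) before being quantized in turn. Set
#' `recalibrate = FALSE` for plain weight-by-weight quantization; weights
#' already on the shift-add grid then pass through unchanged.
#'
#' @param model A `"fundus_segmenter"`.
#' @param S Maximum shift depth. Default the config's `S` (3).
#' @param diffusion Carry quantization errors forward (default `TRUE`).
#' @param recalibrate Apply the calibration-based compensation (default
#'   `TRUE` when the model carries calibration patches).
#' @return The model with a `quantized` component: per-layer quantized
#'   weights (already rescaled), the power-of-two `scales` (one per output
#'   neuron), `S`, `diffusion` and `recalibrated`.
#' @export
quantize_segmenter <- function(model, S = NULL, diffusion = TRUE,
                               recalibrate = TRUE) {
  stopifnot(inherits(model, "fundus_segmenter"))
  if (is.null(S)) S <- model$cfg$S
  recalibrate <- recalibrate && !is.null(model$calibration)
  quant_vec <- function(v) {
    mx <- max(abs(v))
    sc <- if (mx == 0) 1 else 2^(floor(log2(mx)) + 1)
    q <- quantize_with_diffusion(v / sc, S = S, diffusion = diffusion)
    list(q = q$weights$quantized * sc, scale = sc)
  }
  quant_mat <- function(w) {
    sc <- numeric(ncol(w))
    for (j in seq_len(ncol(w))) {
      r <- quant_vec(w[, j])
      w[, j] <- r$q
      sc[j] <- r$scale
    }
    list(q = w, scale = sc)
  }
  w <- model$weights
  r1 <- quant_mat(w$w1)
  b1 <- w$b1
  w2 <- w$w2
  b2 <- w$b2
  if (recalibrate) {
    Xc <- model$calibration
    b1 <- b1 + as.numeric(colMeans(Xc) %*% (w$w1 - r1$q))
  }
  rb1 <- quant_vec(b1)
  if (recalibrate) {
    Xc <- model$calibration
    Sf <- sweep(tanh(sweep(Xc %*% w$w1, 2, w$b1, "+")) %*% w$w2, 2, w$b2, "+")
    Hq <- piecewise_tanh(sweep(Xc %*% r1$q, 2, rb1$q, "+"))
    A <- cbind(Hq, 1)
    co <- solve(t(A) %*% A + 1e-2 * nrow(A) * diag(ncol(A)), t(A) %*% Sf)
    w2 <- co[seq_len(ncol(Hq)), , drop = FALSE]
    b2 <- co[ncol(Hq) + 1L, ]
  }
  r2 <- quant_mat(w2)
  if (recalibrate) {
    b2 <- b2 + as.numeric(colMeans(Hq) %*% (w2 - r2$q))
  }
  rb2 <- quant_vec(b2)
  model$quantized <- list(
    weights = list(w1 = r1$q, b1 = rb1$q, w2 = r2$q, b2 = rb2$q),
    scales = list(w1 = r1$scale, b1 = rb1$scale,
                  w2 = r2$scale, b2 = rb2$scale),
    S = S, diffusion = diffusion, recalibrated = recalibrate)
  model
}

#' Segment a preprocessed fundus image
#'
#' Runs the pixel classifier over every pixel. With `quantized = TRUE` the
#' forward pass uses the shift-add quantized weights and the
#' piecewise-linear tanh only (the arithmetic contract of the hardware
#' formulation); the model must have been passed through
#' [quantize_segmenter()] first.
#'
#' @param image Preprocessed intensity matrix (see [preprocess_fundus()]).
#' @param model A `"fundus_segmenter"`.
#' @param quantized Use the quantized weights and activation.
#' @param min_confidence Lesion-class predictions (microaneurysm,
#'   haemorrhage, hard/soft exudate) whose softmax probability falls below
#'   this value are reassigned to background — uncertain isolated lesion
#'   pixels are segmentation noise that would otherwise corrupt
#'   count-based downstream features. Applied identically to the float and
#'   quantized passes (it post-processes the class scores; the network
#'   arithmetic itself stays shift-add in the quantized pass). `0` disables
#'   the mask.
#' @return Character label matrix over [seg_class_map()] with the image's
#'   dimensions.
#' @export
segment_fundus <- function(image, model, quantized = FALSE,
                           min_confidence = 0.5) {
  stopifnot(inherits(model, "fundus_segmenter"), is.matrix(image))
  X <- patch_matrix(image, model$patch)
  if (ncol(X) != model$cfg$M) {
    stop(sprintf("patch matrix has %d inputs but the model expects %d",
                 ncol(X), model$cfg$M), call. = FALSE)
  }
  if (quantized) {
    if (is.null(model$quantized)) {
      stop("model has no quantized weights; run quantize_segmenter() first",
           call. = FALSE)
    }
    w <- model$quantized$weights
    H <- piecewise_tanh(sweep(X %*% w$w1, 2, w$b1, "+"))
    Sc <- sweep(H %*% w$w2, 2, w$b2, "+")
  } else {
    w <- model$weights
    H <- tanh(sweep(X %*% w$w1, 2, w$b1, "+"))
    Sc <- sweep(H %*% w$w2, 2, w$b2, "+")
  }
  pd <- max.col(Sc, ties.method = "first")
  if (min_confidence > 0) {
    lesion <- which(!(model$classes %in%
                        c("background", "vessel", "optic_disc", "fovea")))
    pr <- softmax_rows(Sc)
    low <- pd %in% lesion & pr[cbind(seq_along(pd), pd)] < min_confidence
    pd[low] <- match("background", model$classes)
  }
  matrix(model$classes[pd], nrow(image), ncol(image))
}
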