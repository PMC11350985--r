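#' Orthogonal wavelet filter specification
#'
#' Defines the analysis/synthesis filter pair and decomposition depth used by
#' [dwt2_multilevel()]. Two orthogonal families are provided: `"haar"` (the
#' simplest orthogonal family, length 2) and `"db4"` (the length-4
#' Daubechies family with one additional vanishing moment). The highpass
#' (wavelet) sequence is derived from the lowpass (scaling) sequence by the
#' quadrature-mirror relation `g[m] = (-1)^m h[L-1-m]`.
#'
#' @param family `"haar"` or `"db4"`.
#' @param levels Decomposition depth `N >= 1`. Default 2.
#' @return An object of class `"wavelet_spec"` with elements `family`,
#'   `levels`, `h` (scaling sequence) and `g` (wavelet sequence).
#' @examples
#' wavelet_spec("haar", levels = 2)
#' @export
wavelet_spec <- function(family = c("haar", "db4"), levels = 2L) {
  family <- match.arg(family)
  levels <- as.integer(levels)
  stopifnot(levels >= 1L)
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db4  = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  )
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1) * rev(h)
  structure(list(family = family, levels = levels, h = h, g = g),
            class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  cat(sprintf("wavelet spec: %s, %d level(s), filter length %d\n",
              x$family, x$levels, length(x$h)))
  invisible(x)
}

# one level of the periodized analysis filter bank applied down the columns
# of a matrix with even row count; returns list(low, high), each n/2 x p
dwt_step_cols <- function(x, h, g) {
  n <- nrow(x)
  L <- length(h)
  k <- seq.int(0L, n / 2L - 1L)
  low <- matrix(0, n / 2L, ncol(x))
  high <- low
  for (m in seq_len(L)) {
    rows <- ((2L * k + (m - 1L)) %% n) + 1L
    low <- low + h[m] * x[rows, , drop = FALSE]
    high <- high + g[m] * x[rows, , drop = FALSE]
  }
  list(low = low, high = high)
}

# transpose of dwt_step_cols: reassemble n rows from n/2 coefficient rows
idwt_step_cols <- function(low, high, h, g) {
  n <- 2L * nrow(low)
  L <- length(h)
  k <- seq.int(0L, n / 2L - 1L)
  x <- matrix(0, n, ncol(low))
  for (m in seq_len(L)) {
    rows <- ((2L * k + (m - 1L)) %% n) + 1L  # distinct for even n
    x[rows, ] <- x[rows, , drop = FALSE] + h[m] * low + g[m] * high
  }
  x
}

# replicate-pad a matrix to even dimensions; returns padded matrix + original dims
pad_even <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  if (nr %% 2L == 1L) x <- rbind(x, x[nr, , drop = FALSE])
  if (nc %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  list(x = x, dim = c(nr, nc))
}

#' Multilevel separable 2D discrete wavelet transform
#'
#' Decomposes an intensity raster into an approximation sub-band `A` and
#' per-level horizontal/vertical/diagonal detail sub-bands `H`, `V`, `D`,
#' applying the 1D filter bank separately to every column and then every row
#' (periodized boundary). Level-`i` sub-bands have dimensions
#' `ceiling(dim / 2^i)`; odd intermediate sizes are replicate-padded to even
#' before filtering and cropped again on reconstruction, so
#' [idwt2_multilevel()] reconstructs the input exactly. For even dyadic
#' sizes the transform is orthogonal and conserves energy exactly.
#'
#' @param img Numeric matrix.
#' @param spec A [wavelet_spec()].
#' @return An object of class `"wavelet_decomposition"`: list with `A`
#'   (approximation at the deepest level), `details` (list of per-level
#'   lists with `H`, `V`, `D`), `dims` (per-level input dimensions used for
#'   cropping), `spec` and `source_dim`.
#' @examples
#' x <- matrix(rnorm(64 * 64), 64)
#' dec <- dwt2_multilevel(x, wavelet_spec("haar", 2))
#' max(abs(idwt2_multilevel(dec) - x))
#' @export
dwt2_multilevel <- function(img, spec = wavelet_spec()) {
  stopifnot(is.matrix(img), is.numeric(img))
  L <- length(spec$h)
  a <- img
  details <- vector("list", spec$levels)
  dims <- vector("list", spec$levels)
  for (lev in seq_len(spec$levels)) {
    if (min(dim(a)) < L) {
      stop(sprintf(
        "image too small for %d-level decomposition with filter length %d; maximum feasible level is %d",
        spec$levels, L, lev - 1L), call. = FALSE)
    }
    p <- pad_even(a)
    dims[[lev]] <- p$dim
    cs <- dwt_step_cols(p$x, spec$h, spec$g)
    lo <- dwt_step_cols(t(cs$low), spec$h, spec$g)    # rows of the lowpass
    hi <- dwt_step_cols(t(cs$high), spec$h, spec$g)   # rows of the highpass
    a <- t(lo$low)
    details[[lev]] <- list(H = t(hi$low), V = t(lo$high), D = t(hi$high))
  }
  structure(list(A = a, details = details, dims = dims, spec = spec,
                 source_dim = dim(img)),
            class = "wavelet_decomposition")
}

#' Inverse multilevel 2D discrete wavelet transform
#'
#' @param dec A `"wavelet_decomposition"` from [dwt2_multilevel()].
#' @return The reconstructed numeric matrix, equal to the decomposed input
#'   to floating-point precision.
#' @export
idwt2_multilevel <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  h <- dec$spec$h; g <- dec$spec$g
  a <- dec$A
  for (lev in rev(seq_along(dec$details))) {
    d <- dec$details[[lev]]
    low  <- t(idwt_step_cols(t(a), t(d$V), h, g))
    high <- t(idwt_step_cols(t(d$H), t(d$D), h, g))
    x <- idwt_step_cols(low, high, h, g)
    dm <- dec$dims[[lev]]
    a <- x[seq_len(dm[1]), seq_len(dm[2]), drop = FALSE]
  }
  a
}

#' Soft/hard threshold the detail sub-bands and reconstruct
#'
#' Applies wavelet-domain denoising: detail coefficients are shrunk by a
#' soft or hard threshold and the image is rebuilt with
#' [idwt2_multilevel()]. When `threshold` is `NULL` the universal threshold
#' `sigma * sqrt(2 log n)` is used, with the noise scale `sigma` estimated
#' robustly as `median(abs(D1)) / 0.6745` from the finest diagonal sub-band.
#'
#' @param dec A `"wavelet_decomposition"`.
#' @param rule `"soft"` (shrink toward zero, default) or `"hard"` (keep or
#'   kill).
#' @param threshold Non-negative threshold; `NULL` for the universal rule.
#'   A threshold of 0 reproduces the input exactly.
#' @return Denoised numeric matrix with the source dimensions.
#' @export
denoise_reconstruct <- function(dec, rule = "soft", threshold = NULL) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  rules <- c("soft", "hard")
  if (!is.character(rule) || length(rule) != 1L || !(rule %in% rules)) {
    stop("unknown threshold rule ", deparse(rule),
         "; supported rules: ", paste(rules, collapse = ", "), call. = FALSE)
  }
  if (is.null(threshold)) {
    d1 <- dec$details[[1]]$D
    sigma <- stats::median(abs(d1)) / 0.6745
    threshold <- sigma * sqrt(2 * log(prod(dec$source_dim)))
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  shrink <- function(w) {
    if (rule == "soft") sign(w) * pmax(abs(w) - threshold, 0)
    else w * (abs(w) > threshold)
  }
  dec$details <- lapply(dec$details, function(d) lapply(d, shrink))
  idwt2_multilevel(dec)
}
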