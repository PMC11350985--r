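#' Shift-add (power-of-two) weight quantization
#'
#' Neural-network multipliers can be replaced by adders and bit-shifters when
#' every weight is a signed sum of distinct negative powers of two. With a
#' shift depth of `S`, the available terms are `2^-1, ..., 2^-S`, so the
#' representable values are `k / 2^S` for `k = 0, ..., 2^S - 1`, with either
#' sign. [quantize_weight()] maps a fractional weight to the nearest
#' representable value; [quantize_with_diffusion()] additionally carries each
#' weight's signed quantization error into the quantization of the weights
#' that follow it, which shrinks the average signed error of a weight
#' sequence.
#'
#' Ties between two equidistant representable values are broken toward the
#' value of smaller magnitude, which is deterministic and avoids inflating
#' the carried error under diffusion.
#'
#' @param w A single numeric weight with `abs(w) < 1`. Layers whose weights
#'   exceed unit magnitude must be pre-scaled first (see
#'   [quantize_segmenter()], which uses power-of-two layer scales so the
#'   rescaling itself is a bit-shift).
#' @param S Maximum shift depth (number of available power-of-two terms),
#'   a positive integer. Default 3.
#' @return For `quantize_weight()`, an object of class `"quantized_weight"`:
#'   a list with `value` (the representable number nearest `w`), `sign`,
#'   `exponents` (the integer set `e` with `value = sign * sum(2^-e)`), and
#'   `error` (`w - value`).
#' @examples
#' quantize_weight(0.8735, S = 3)  # 0.8750 = 2^-1 + 2^-2 + 2^-3
#' quantize_weight(0.3811, S = 3)  # 0.3750 = 2^-2 + 2^-3
#' @seealso [quantize_with_diffusion()], [piecewise_tanh()]
#' @export
quantize_weight <- function(w, S = 3L) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w))
  S <- check_shift_depth(S)
  if (abs(w) >= 1) {
    stop("quantize_weight() requires |w| < 1 (got ", format(w),
         "); pre-scale the layer before quantizing", call. = FALSE)
  }
  k <- nearest_grid_index(abs(w), S)
  value <- sign(w) * k / 2^S
  structure(
    list(
      sign = if (value < 0) -1 else 1,
      exponents = exponents_of_index(k, S),
      value = value,
      error = w - value
    ),
    class = "quantized_weight"
  )
}

# index k in 0..2^S-1 of nearest multiple of 2^-S to a >= 0,
# ties toward smaller magnitude
nearest_grid_index <- function(a, S) {
  t <- a * 2^S
  k <- floor(t + 0.5)
  if ((t - floor(t)) == 0.5) k <- floor(t)  # tie: round down in magnitude
  min(k, 2^S - 1)
}

# distinct exponents e (subset of 1..S) with sum(2^-e) == k/2^S
exponents_of_index <- function(k, S) {
  e <- integer(0)
  for (j in seq_len(S)) {            # j = 1 -> term 2^-1 -> bit 2^(S-1)
    bit <- 2^(S - j)
    if (k >= bit) {
      e <- c(e, j)
      k <- k - bit
    }
  }
  e
}

#' @export
print.quantized_weight <- function(x, ...) {
  terms <- if (length(x$exponents) == 0L) "0" else
    paste(sprintf("2^-%d", x$exponents), collapse = " + ")
  cat(sprintf("quantized weight: %s%s = %.4f (error %+.4f)\n",
              if (x$sign < 0) "-" else "", terms, x$value, x$error))
  invisible(x)
}

#' Quantize a weight sequence with cumulative error diffusion
#'
#' Quantizes an ordered sequence of weights to the shift-add representable
#' set. Without diffusion each weight is quantized in isolation. With
#' diffusion, the value actually quantized for weight `i` is
#' `w_i + sum(w_j - q_j, j < i)` — the cumulative signed errors of all
#' earlier weights are added before rounding — while the error *recorded*
#' for weight `i` is always `w_i - q_i`, i.e. measured against the original
#' weight. Diffusion leaves each individual error of similar size but drives
#' the average signed error toward zero.
#'
#' @param ws Numeric vector of weights, each with `abs(w) < 1`.
#' @param S Maximum shift depth, as in [quantize_weight()].
#' @param diffusion Logical; carry errors forward (default `TRUE`).
#' @return An object of class `"quantization_report"`: a list with a
#'   `weights` data frame (columns `original`, `quantized`, `error`),
#'   `average_error` (mean signed error), `S` and `diffusion`.
#' @examples
#' # the canonical three-weight sequence
#' quantize_with_diffusion(c(0.8000, 0.4250, 0.4050), S = 3, diffusion = FALSE)
#' quantize_with_diffusion(c(0.8000, 0.4250, 0.4050), S = 3, diffusion = TRUE)
#' @export
quantize_with_diffusion <- function(ws, S = 3L, diffusion = TRUE) {
  stopifnot(is.numeric(ws), length(ws) >= 1L, all(is.finite(ws)))
  S <- check_shift_depth(S)
  if (any(abs(ws) >= 1)) {
    stop("quantize_with_diffusion() requires |w| < 1 for every weight; ",
         "pre-scale the layer first", call. = FALSE)
  }
  limit <- (2^S - 1) / 2^S
  n <- length(ws)
  q <- numeric(n)
  carry <- 0
  for (i in seq_len(n)) {
    target <- if (diffusion) ws[i] + carry else ws[i]
    # the diffused target can drift past the representable range; saturate
    target <- max(-limit, min(limit, target))
    k <- nearest_grid_index(abs(target), S)
    q[i] <- sign(target) * k / 2^S
    carry <- carry + (ws[i] - q[i])
  }
  err <- ws - q
  structure(
    list(
      weights = data.frame(original = ws, quantized = q, error = err),
      average_error = mean(err),
      S = S,
      diffusion = diffusion
    ),
    class = "quantization_report"
  )
}

#' @export
print.quantization_report <- function(x, ...) {
  cat(sprintf("shift-add quantization report (S = %d, diffusion %s)\n",
              x$S, if (x$diffusion) "on" else "off"))
  print(round(x$weights, 4))
  cat(sprintf("average signed error: %+.4f\n", x$average_error))
  invisible(x)
}

check_shift_depth <- function(S) {
  S <- as.integer(S)
  stopifnot(length(S) == 1L, !is.na(S), S >= 1L)
  if (S > 30L) stop("shift depth S > 30 is not representable exactly", call. = FALSE)
  S
}

#' Piecewise-linear approximation of the hyperbolic tangent
#'
#' A four-interval linear approximation of `tanh(x)` whose evaluation needs
#' only comparisons, additions and bit-shifts (the slopes are 1, 1/2, 1/4
#' and 0), intended for the quantized forward pass of the fundus segmenter.
#' The function is odd, continuous, non-decreasing and bounded by ±1, and
#' deviates from `tanh` by at most about 0.04:
#' \deqn{f(|x|) = |x| \;(|x|<0.5);\quad 0.5 + (|x|-0.5)/2 \;(0.5 \le |x|<1);}
#' \deqn{0.75 + (|x|-1)/4 \;(1 \le |x| < 2);\quad 1 \;(|x| \ge 2).}
#'
#' @param x Numeric vector.
#' @return `sign(x) * f(abs(x))`, vectorized.
#' @examples
#' piecewise_tanh(c(-0.25, 0.25, 0.75, 1.5, 5))
#' @export
piecewise_tanh <- function(x) {
  a <- abs(x)
  y <- ifelse(a < 0.5, a,
       ifelse(a < 1, 0.5 + (a - 0.5) / 2,
       ifelse(a < 2, 0.75 + (a - 1) / 4, 1)))
  sign(x) * y
}
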