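#' Extract and resize the green channel of a fundus photograph
#'
#' Fundus photography carries most vessel and lesion contrast in the green
#' channel, so preprocessing starts by dropping red and blue and resizing to
#' a uniform working resolution (bilinear, via \pkg{EBImage}).
#'
#' @param image Numeric array `H x W x 3` with values in `[0, 1]` (as read
#'   by [png::readPNG()]) or in `[0, 255]`.
#' @param target_size Output side length(s) in pixels: a single integer for
#'   square output or `c(rows, cols)`. `NULL` keeps the input size.
#' @return Numeric matrix on the same intensity scale as the input.
#' @examples
#' img <- array(runif(32 * 32 * 3), c(32, 32, 3))
#' dim(to_green_channel(img, 16))
#' @export
to_green_channel <- function(image, target_size = NULL) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("expected an RGB raster with 3 channels, got ",
         paste(dim(image), collapse = "x"), call. = FALSE)
  }
  g <- image[, , 2]
  if (!is.null(target_size)) {
    if (length(target_size) == 1L) target_size <- c(target_size, target_size)
    if (!all(dim(g) == target_size)) {
      g <- resize_raster(g, target_size[1], target_size[2])
    }
  }
  g
}

# bilinear resize of a matrix via EBImage (EBImage stores images x-by-y,
# i.e. transposed relative to R's row/col raster convention)
resize_raster <- function(m, nr, nc) {
  t(EBImage::resize(EBImage::Image(t(m)), w = nc, h = nr))@.Data
}

#' Histogram equalization of an intensity raster
#'
#' Cumulative-distribution remapping over 256 bins: intensities are
#' monotonically remapped so the output histogram is approximately uniform
#' and spans the full dynamic range whenever the input has at least two
#' distinct values. A constant image passes through unchanged. With a
#' finite `clip_limit` the histogram is clipped at `clip_limit` times the
#' uniform bin height and the excess redistributed before building the CDF
#' (clip-limited equalization, the usual choice for fundus contrast
#' enhancement): contrast is still stretched but sparse intensity tails —
#' the bright lesions — are not compressed onto each other.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param n_bins Number of grey levels (default 256).
#' @param clip_limit Histogram clip factor relative to the uniform height;
#'   `NULL` or `Inf` gives the classic unlimited equalization. Default 2.
#' @return Numeric matrix in `[0, 1]`.
#' @export
equalize_histogram <- function(img, n_bins = 256L, clip_limit = 2) {
  stopifnot(is.matrix(img), is.numeric(img))
  rng <- range(img)
  if (rng[1] == rng[2]) return(img)
  lev <- pmin(floor((img - rng[1]) / (rng[2] - rng[1]) * n_bins), n_bins - 1L)
  h <- tabulate(lev + 1L, nbins = n_bins)
  if (!is.null(clip_limit) && is.finite(clip_limit)) {
    cap <- clip_limit * length(img) / n_bins
    excess <- sum(pmax(h - cap, 0))
    h <- pmin(h, cap) + excess / n_bins
  }
  cdf <- cumsum(h) / sum(h)
  cdf_min <- cdf[which(cdf > 0)[1]]
  out <- (cdf[lev + 1L] - cdf_min) / (1 - cdf_min)
  matrix(pmax(out, 0), nrow(img), ncol(img))
}

#' Preprocess a fundus image for segmentation and feature extraction
#'
#' The preprocessing chain: resize, green-channel extraction, histogram
#' equalization, multilevel 2D DWT decomposition, detail-coefficient
#' thresholding and reconstruction (see [dwt2_multilevel()] and
#' [denoise_reconstruct()]).
#'
#' @param image RGB array (`H x W x 3`) or an intensity matrix.
#' @param target_size Working resolution (default 256).
#' @param spec A [wavelet_spec()]; default 2-level Haar.
#' @param rule,threshold Passed to [denoise_reconstruct()].
#' @return Intensity matrix in `[0, 1]` at the working resolution.
#' @export
preprocess_fundus <- function(image, target_size = 256L,
                              spec = wavelet_spec("haar", 2L),
                              rule = "soft", threshold = NULL) {
  g <- if (length(dim(image)) == 3L) to_green_channel(image, target_size)
       else {
         if (length(target_size) == 1L) target_size <- c(target_size, target_size)
         if (all(dim(image) == target_size)) image
         else resize_raster(image, target_size[1], target_size[2])
       }
  if (max(g) > 1) g <- g / 255
  eq <- equalize_histogram(g)
  den <- denoise_reconstruct(dwt2_multilevel(eq, spec), rule = rule,
                             threshold = threshold)
  pmin(pmax(den, 0), 1)
}
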