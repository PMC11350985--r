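#' Gabor filter parameters
#'
#' A Gabor kernel is a complex sinusoidal grating modulated by an isotropic
#' Gaussian envelope. Coordinates follow the package raster convention:
#' `x` is the column offset (rightward), `y` the row offset (downward),
#' both on the integer grid `-k..k`.
#'
#' @param sigma Gaussian envelope standard deviation in pixels (`> 0`).
#' @param mu Centre frequency in cycles/pixel (`>= 0`).
#' @param theta Orientation in degrees, reduced modulo 180.
#' @param k Half-size; the kernel support is `(2k+1) x (2k+1)`. `NULL`
#'   chooses the smallest `k` with `2k+1 >= 6 sigma`.
#' @return An object of class `"gabor_params"`.
#' @export
gabor_params <- function(sigma, mu, theta, k = NULL) {
  stopifnot(sigma > 0, mu >= 0)
  theta <- theta %% 180
  if (is.null(k)) k <- max(1L, as.integer(ceiling((6 * sigma - 1) / 2)))
  k <- as.integer(k)
  stopifnot(k >= 1L)
  structure(list(sigma = sigma, mu = mu, theta = theta, k = k),
            class = "gabor_params")
}

#' Construct a complex Gabor kernel
#'
#' Samples
#' \deqn{G(x,y) = g_\sigma(x,y) \exp\{2\pi j \mu (x\cos\theta + y\sin\theta)\}}
#' with Gaussian envelope
#' \eqn{g_\sigma(x,y) = \exp\{-(x^2+y^2)/(2\sigma^2)\} / (2\pi\sigma^2)}
#' on the integer grid centred at the origin. The real part responds to
#' ridges, the imaginary part to edges.
#'
#' @param p A [gabor_params()].
#' @return An object of class `"gabor_kernel"`: list with `params`, `re`,
#'   `im` (numeric `(2k+1) x (2k+1)` matrices) and `dc_removed` flag.
#' @export
gabor_kernel <- function(p) {
  stopifnot(inherits(p, "gabor_params"))
  k <- p$k
  off <- seq.int(-k, k)
  x <- matrix(off, 2 * k + 1, 2 * k + 1, byrow = TRUE)  # column offset
  y <- matrix(off, 2 * k + 1, 2 * k + 1)                # row offset
  env <- exp(-(x^2 + y^2) / (2 * p$sigma^2)) / (2 * pi * p$sigma^2)
  phase <- 2 * pi * p$mu * (x * cospi(p$theta / 180) + y * sinpi(p$theta / 180))
  structure(list(params = p, re = env * cos(phase), im = env * sin(phase),
                 dc_removed = FALSE),
            class = "gabor_kernel")
}

#' Remove the DC component of a Gabor kernel
#'
#' Subtracts the mean over all `(2k+1)^2` entries from every entry (real and
#' imaginary parts separately), so the kernel sum is zero and filtering
#' becomes insensitive to constant illumination offsets.
#'
#' @param kern A `"gabor_kernel"` that has not yet been DC-removed.
#' @return The DC-free kernel, with `dc_removed = TRUE`.
#' @export
remove_dc <- function(kern) {
  stopifnot(inherits(kern, "gabor_kernel"))
  if (kern$dc_removed) stop("kernel is already DC-removed", call. = FALSE)
  kern$re <- kern$re - mean(kern$re)
  kern$im <- kern$im - mean(kern$im)
  kern$dc_removed <- TRUE
  kern
}

# reflect-padded indices (edge not duplicated); requires pad <= n - 1
reflect_idx <- function(n, pad) {
  c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
}

# complex correlation sum_q img[p+q] * kern[q] over q in [-k,k]^2, computed
# by FFT on the reflect-padded image; returns an H x W complex matrix
conv2_reflect <- function(img, kern, pad = NULL, fft_pad = NULL) {
  k <- kern$params$k
  if (is.null(pad)) pad <- k
  stopifnot(pad >= k, pad <= min(dim(img)) - 1L)
  if (is.null(fft_pad)) {
    P <- img[reflect_idx(nrow(img), pad), reflect_idx(ncol(img), pad)]
    fft_pad <- stats::fft(P)
  }
  np <- dim(fft_pad)
  Ke <- matrix(0 + 0i, np[1], np[2])
  off <- seq.int(-k, k)
  Ke[(off %% np[1]) + 1L, (off %% np[2]) + 1L] <-
    kern$re[] + 1i * kern$im[]
  out <- stats::fft(fft_pad * Conj(stats::fft(Ke)), inverse = TRUE) / prod(np)
  Conj(out[pad + seq_len(nrow(img)), pad + seq_len(ncol(img))])
}

#' Estimate locally adapted Gabor parameters from a texture tile
#'
#' Gabor filtering discriminates best when the kernel orientation, centre
#' frequency and envelope width match the local texture. The dominant
#' orientation is taken from the structure tensor of the tile gradients,
#' the dominant frequency from the radial peak of the (mean-removed) 2D
#' amplitude spectrum, and the envelope follows an approximately one-octave
#' bandwidth rule `sigma = c / mu` (default `c = 0.56`).
#'
#' @param tile Numeric matrix, at least 16 x 16.
#' @param defaults `"gabor_params"` returned (with attribute
#'   `"degenerate" = TRUE`) for flat tiles with no texture.
#' @param sigma_factor Bandwidth constant `c` in `sigma = c / mu`.
#' @return A `"gabor_params"`; attribute `"degenerate"` is `TRUE` when the
#'   defaults were returned.
#' @export
estimate_local_params <- function(tile,
                                  defaults = gabor_params(2.8, 0.2, 0),
                                  sigma_factor = 0.56) {
  stopifnot(is.matrix(tile), nrow(tile) >= 16L, ncol(tile) >= 16L)
  if (stats::sd(tile) == 0) {
    attr(defaults, "degenerate") <- TRUE
    return(defaults)
  }
  nr <- nrow(tile); nc <- ncol(tile)
  gx <- (tile[, c(2:nc, nc)] - tile[, c(1, 1:(nc - 1))]) / 2
  gy <- (tile[c(2:nr, nr), ] - tile[c(1, 1:(nr - 1)), ]) / 2
  jxx <- mean(gx^2); jyy <- mean(gy^2); jxy <- mean(gx * gy)
  theta <- (0.5 * atan2(2 * jxy, jxx - jyy)) * 180 / pi

  ft <- abs(stats::fft(tile - mean(tile)))
  fr <- fft_freq(nr); fc <- fft_freq(nc)
  rad <- sqrt(outer(fr^2, fc^2, "+"))
  ft[rad == 0] <- 0
  peak <- which.max(ft)
  if (ft[peak] <= 1e-12) {
    attr(defaults, "degenerate") <- TRUE
    return(defaults)
  }
  mu <- rad[peak]
  sigma <- min(max(sigma_factor / mu, 0.75), min(nr, nc) / 2)
  p <- gabor_params(sigma, mu, theta,
                    k = min(gabor_params(sigma, mu, theta)$k, min(nr, nc) - 1L))
  attr(p, "degenerate") <- FALSE
  p
}

fft_freq <- function(n) {
  i <- seq_len(n) - 1L
  ifelse(i <= n %/% 2, i, i - n) / n
}

#' Gabor bank configuration
#'
#' The fixed fallback filter bank plus tiling and adaptation settings used
#' by [extract_gabor_features()].
#'
#' @param orientations Orientations in degrees.
#' @param frequencies Centre frequencies in cycles/pixel.
#' @param tiles Tiling grid side; the image is cut into `tiles x tiles`
#'   equal tiles (default 4).
#' @param adaptive Also emit per-tile adaptively parameterized features.
#' @param sigma_factor Bandwidth constant for `sigma = c / mu`.
#' @param max_k Cap on kernel half-size (keeps low-frequency kernels
#'   tractable on small rasters).
#' @return A list of class `"gabor_bank"`.
#' @export
gabor_bank <- function(orientations = c(0, 30, 60, 90, 120, 150),
                       frequencies = c(0.05, 0.1, 0.2),
                       tiles = 4L, adaptive = TRUE,
                       sigma_factor = 0.56, max_k = 40L) {
  stopifnot(length(orientations) >= 1L, length(frequencies) >= 1L,
            all(frequencies > 0), tiles >= 1L)
  structure(list(orientations = orientations, frequencies = frequencies,
                 tiles = as.integer(tiles), adaptive = isTRUE(adaptive),
                 sigma_factor = sigma_factor, max_k = as.integer(max_k)),
            class = "gabor_bank")
}

#' Illumination-robust Gabor texture features
#'
#' Correlates the image with DC-removed Gabor kernels — the fixed fallback
#' bank over all configured orientation/frequency pairs, plus (optionally)
#' one locally adapted kernel per tile — and summarizes the response
#' magnitude `|F|` per tile as mean, standard deviation and energy (root
#' mean square). When a segmentation label mask is supplied, per-class
#' summaries of the aggregate bank magnitude are appended: area fraction,
#' mean and standard deviation of `|F|`, and the mean radial distance of
#' class pixels from the raster centre (normalized by half the short side).
#' Feature names are deterministic for a fixed configuration, and all
#' magnitude features are invariant to constant intensity offsets.
#'
#' @param image Numeric intensity matrix (preprocessed).
#' @param seg Optional label mask from [segment_fundus()] (factor/character/
#'   integer matrix matching `image`), a *named list* of such masks (each
#'   list element contributes its own per-class summary block, prefixed
#'   with the element name — e.g. a confidence-masked and a raw
#'   segmentation side by side), or `NULL`.
#' @param bank A [gabor_bank()].
#' @return Named numeric feature vector of fixed length for a fixed
#'   configuration.
#' @export
extract_gabor_features <- function(image, seg = NULL, bank = gabor_bank()) {
  stopifnot(is.matrix(image), is.numeric(image))
  nr <- nrow(image); nc <- ncol(image)
  tl <- tile_bounds(nr, bank$tiles)
  tc <- tile_bounds(nc, bank$tiles)

  kerns <- list()
  for (th in bank$orientations) for (mu in bank$frequencies) {
    sigma <- min(max(bank$sigma_factor / mu, 0.75), min(nr, nc) / 3)
    p <- gabor_params(sigma, mu, th)
    p$k <- min(p$k, bank$max_k, min(nr, nc) - 1L)
    kerns[[sprintf("th%03d_mu%.3f", as.integer(round(th)), mu)]] <-
      remove_dc(gabor_kernel(p))
  }
  pad <- max(vapply(kerns, function(kk) kk$params$k, integer(1)))
  P <- image[reflect_idx(nr, pad), reflect_idx(nc, pad)]
  fft_pad <- stats::fft(P)

  feats <- numeric(0)
  agg <- matrix(0, nr, nc)
  for (nm in names(kerns)) {
    mag <- Mod(conv2_reflect(image, kerns[[nm]], pad = pad, fft_pad = fft_pad))
    agg <- agg + mag
    feats <- c(feats, tile_stats(mag, tl, tc, prefix = paste0("bank_", nm)))
  }
  agg <- agg / length(kerns)

  if (bank$adaptive) {
    for (i in seq_len(bank$tiles)) for (j in seq_len(bank$tiles)) {
      tile <- image[tl[[i]], tc[[j]], drop = FALSE]
      p <- if (min(dim(tile)) >= 16L) {
        estimate_local_params(tile, sigma_factor = bank$sigma_factor)
      } else gabor_params(2.8, 0.2, 0)  # tile too small to adapt reliably
      p$k <- min(p$k, bank$max_k, min(dim(tile)) - 1L)
      kern <- remove_dc(gabor_kernel(p))
      mag <- Mod(conv2_reflect(tile, kern))
      v <- c(mean(mag), stats::sd(as.numeric(mag)), sqrt(mean(mag^2)))
      names(v) <- sprintf("agf_t%d%d_%s", i, j, c("mean", "sd", "energy"))
      feats <- c(feats, v)
    }
  }

  if (!is.null(seg)) {
    segs <- if (is.list(seg) && !is.matrix(seg)) seg else list(seg)
    if (is.null(names(segs))) names(segs) <- rep("", length(segs))
    for (si in seq_along(segs)) {
      feats <- c(feats,
                 seg_class_features(segs[[si]], image, agg, nr, nc,
                                    prefix = paste0("seg", names(segs)[si])))
    }
  }
  feats
}

# per-class summary block for one segmentation labeling
seg_class_features <- function(seg, image, agg, nr, nc, prefix = "seg") {
  feats <- numeric(0)
  {
    cls <- matrix(as.character(as.vector(seg)), nr, nc)
    r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
    radial <- sqrt(outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+")) /
      (min(nr, nc) / 2)
    for (cl in seg_class_map()) {
      inside <- cls == cl
      v <- c(0, 0, 0, 1.5, 1.5, 0)     # 1.5 = "beyond the field" sentinel
      if (any(inside)) {
        # despeckle: single/double-pixel components are segmentation noise,
        # not structures — drop them before summarizing
        lab <- EBImage::bwlabel(EBImage::Image(inside * 1))@.Data
        sizes <- tabulate(lab[lab > 0L])
        keep <- which(sizes >= 3L)
        inside <- matrix(lab %in% keep, nr, nc)
        if (any(inside)) {
          v <- c(mean(inside), mean(agg[inside]),
                 if (sum(inside) > 1) stats::sd(agg[inside]) else 0,
                 mean(radial[inside]), min(radial[inside]), length(keep))
        }
      }
      names(v) <- sprintf("%s_%s_%s", prefix, cl,
                          c("area", "mag", "magsd", "radial", "minradial",
                            "count"))
      feats <- c(feats, v)
    }
    # vessel density close to the (predicted) optic disc: neovascular cue
    disc <- cls == "optic_disc"
    nv <- 0
    if (any(disc)) {
      w <- which(disc, arr.ind = TRUE)
      dctr <- colMeans(w)
      drad <- sqrt(sum(disc) / pi)
      dd <- sqrt(outer((seq_len(nr) - dctr[1])^2,
                       (seq_len(nc) - dctr[2])^2, "+"))
      nv <- mean((cls == "vessel")[dd <= 1.5 * drad])
    }
    feats <- c(feats, stats::setNames(nv, paste0(prefix, "_vessel_neardisc")))
  }
  feats
}

tile_bounds <- function(n, tiles) {
  cuts <- floor(seq(0, n, length.out = tiles + 1))
  lapply(seq_len(tiles), function(i) (cuts[i] + 1):cuts[i + 1])
}

tile_stats <- function(mag, tl, tc, prefix) {
  out <- numeric(0)
  for (i in seq_along(tl)) for (j in seq_along(tc)) {
    m <- mag[tl[[i]], tc[[j]]]
    v <- c(mean(m), stats::sd(as.numeric(m)), sqrt(mean(m^2)))
    names(v) <- sprintf("%s_t%d%d_%s", prefix, i, j, c("mean", "sd", "energy"))
    out <- c(out, v)
  }
  out
}
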