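#' Image-quality metrics between two rasters
#'
#' The four preprocessing comparison metrics: mean squared error, its root,
#' peak signal-to-noise ratio `10 log10(L^2 / MSE)` for dynamic range `L`
#' (reported as `Inf` when the rasters are identical), and the mean local
#' structural similarity index (uniform 8x8 windows,
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`).
#'
#' @param ref,test Equal-shaped numeric matrices.
#' @param dynamic_range Intensity range `L` (255 for 8-bit data; use 1 for
#'   unit-scale rasters).
#' @param window SSIM window side (default 8).
#' @return List of class `"quality_metrics"` with `mse`, `rmse`, `psnr`,
#'   `ssim`.
#' @examples
#' a <- matrix(runif(64), 8)
#' compute_quality(a, a, dynamic_range = 1)$ssim  # 1
#' @export
compute_quality <- function(ref, test, dynamic_range = 255, window = 8L) {
  if (!all(dim(ref) == dim(test))) {
    stop("ref and test must have the same shape", call. = FALSE)
  }
  err <- ref - test
  mse <- mean(err^2)
  psnr <- if (mse == 0) Inf else 10 * log10(dynamic_range^2 / mse)
  structure(list(mse = mse, rmse = sqrt(mse),
                 psnr = psnr,
                 ssim = mean_ssim(ref, test, dynamic_range, window)),
            class = "quality_metrics")
}

# mean SSIM over all valid window positions, via integral-image box sums
mean_ssim <- function(x, y, L, w) {
  w <- min(w, dim(x))
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  box <- function(m) {
    S <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    S <- t(S)
    n <- nrow(m); p <- ncol(m)
    S0 <- matrix(0, n + 1, p + 1)
    S0[-1, -1] <- S
    (S0[(w + 1):(n + 1), (w + 1):(p + 1)] - S0[1:(n - w + 1), (w + 1):(p + 1)]
      - S0[(w + 1):(n + 1), 1:(p - w + 1)] + S0[1:(n - w + 1), 1:(p - w + 1)]) / w^2
  }
  mx <- box(x); my <- box(y)
  sxx <- box(x * x) - mx^2
  syy <- box(y * y) - my^2
  sxy <- box(x * y) - mx * my
  mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("MSE %.4f | RMSE %.4f | PSNR %s dB | SSIM %.4f\n",
              x$mse, x$rmse,
              if (is.infinite(x$psnr)) "Inf" else sprintf("%.2f", x$psnr),
              x$ssim))
  invisible(x)
}

#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations and the global seed. The stage list
#' must be a prefix of the full chain
#' `generate, preprocess, segment, extract, select, train, evaluate`;
#' truncating it stops the run after the last named stage.
#'
#' @param generator A [generator_config()]; its `seed` is overridden by
#'   `seed`.
#' @param n_samples Dataset size. Default 200.
#' @param wavelet,levels Wavelet family and decomposition depth for
#'   preprocessing.
#' @param segmenter List of [train_segmenter()] arguments plus
#'   `n_train_images` (images used to fit the segmenter) and
#'   `use_quantized` (segment with the shift-add weights).
#' @param bank A [gabor_bank()].
#' @param selection A [regularization_config()]; `n_tree` defaults to 60
#'   here to keep the high-dimensional penalized stage tractable.
#' @param classifier List: `fc` hidden widths, `steps`, `n_swarm`,
#'   `input_mode`.
#' @param train_fraction Stratified train share. Default 0.8.
#' @param stages Stage prefix to execute.
#' @param output_dir Optional directory for artifacts (PNG dataset,
#'   manifest, feature CSV, selected-feature CSV, JSON report).
#' @param seed Global seed propagated to every stochastic stage.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(image_size = 96L),
                            n_samples = 200L,
                            wavelet = "haar", levels = 2L,
                            segmenter = list(),
                            bank = gabor_bank(),
                            selection = regularization_config(n_tree = 60L),
                            classifier = list(),
                            train_fraction = 0.8,
                            stages = c("generate", "preprocess", "segment",
                                       "extract", "select", "train",
                                       "evaluate"),
                            output_dir = NULL,
                            seed = 1L) {
  all_stages <- c("generate", "preprocess", "segment", "extract", "select",
                  "train", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)])) {
    stop("stages must form a prefix of: ", paste(all_stages, collapse = ", "),
         call. = FALSE)
  }
  seg_defaults <- list(hidden = 48L, patch = 9L, per_class = 250L,
                       oversample_cap = 6L, steps = 4000L, batch = 1024L,
                       decay = 2e-3, weight_power = 0.5,
                       n_train_images = 24L, S = 3L, diffusion = TRUE,
                       use_quantized = FALSE)
  seg_defaults[names(segmenter)] <- segmenter
  cls_defaults <- list(fc = 32L, steps = 150L, n_swarm = 30L,
                       input_mode = "mlp")
  cls_defaults[names(classifier)] <- classifier
  structure(list(generator = generator, n_samples = as.integer(n_samples),
                 wavelet = wavelet, levels = as.integer(levels),
                 segmenter = seg_defaults, bank = bank,
                 selection = selection, classifier = cls_defaults,
                 train_fraction = train_fraction, stages = stages,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

#' Run the DR/DME grading pipeline end to end
#'
#' Executes generate, preprocess (green channel + equalization + DWT
#' denoising), segment (shift-add quantized ANN, trained on the first
#' training images), extract (adaptive Gabor features with per-class
#' summaries), select (penalized-Gini forest), train (chicken-swarm
#' classifier on the selected features) and evaluate (held-out accuracy,
#' macro sensitivity/specificity/precision/F1), logging per-stage timings.
#' Everything is reproducible from `(config, seed)`.
#'
#' @param cfg A [pipeline_config()].
#' @return A run report list: `config_summary`, `seed`, per-stage `timings`
#'   (seconds), `class_counts`, `selected_features`, `preprocess_quality`
#'   (mean PSNR/SSIM of denoised vs equalized input), `segmenter_agreement`
#'   (pooled quantized/float pixel agreement over the test images),
#'   `metrics` (accuracy + macro metrics + confusion matrix) and
#'   `versions`. Stages not run are `NULL`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t_all <- Sys.time()
  timings <- list()
  report <- list(config_summary = list(
    n_samples = cfg$n_samples, image_size = cfg$generator$image_size,
    wavelet = cfg$wavelet, levels = cfg$levels,
    gamma = cfg$selection$gamma, n_tree = cfg$selection$n_tree,
    classifier = cfg$classifier, stages = cfg$stages),
    seed = cfg$seed)

  run_stage <- function(name) name %in% cfg$stages
  tick <- function(name, t0) {
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    stage_log(name, "done in %.1fs", timings[[name]])
  }

  # --- generate -------------------------------------------------------------
  t0 <- Sys.time()
  gen <- cfg$generator
  gen$seed <- cfg$seed
  ds <- generate_fundus_dataset(gen, cfg$n_samples, write_dir =
    if (!is.null(cfg$output_dir)) file.path(cfg$output_dir, "images"))
  labels <- factor(paste(ds$manifest$dr_grade, ds$manifest$dme_grade,
                         sep = ":"))
  report$class_counts <- as.list(table(labels))
  tick("generate", t0)
  if (!run_stage("preprocess")) {
    report$timings <- timings
    return(finish_report(report, cfg))
  }

  # --- preprocess -----------------------------------------------------------
  t0 <- Sys.time()
  spec <- wavelet_spec(cfg$wavelet, cfg$levels)
  sz <- dim(ds$samples[[1]]$image)[1:2]
  pre <- lapply(ds$samples, function(s)
    preprocess_fundus(s$image, target_size = sz, spec = spec))
  # quality of the DWT-denoised raster against the equalized input
  qs <- lapply(ds$samples[seq_len(min(20, length(pre)))], function(s) {
    eq <- equalize_histogram(to_green_channel(s$image, sz))
    den <- denoise_reconstruct(dwt2_multilevel(eq, spec))
    compute_quality(eq * 255, pmin(pmax(den, 0), 1) * 255)
  })
  report$preprocess_quality <- list(
    mean_psnr = mean(vapply(qs, `[[`, numeric(1), "psnr")),
    mean_ssim = mean(vapply(qs, `[[`, numeric(1), "ssim")))
  tick("preprocess", t0)
  if (!run_stage("segment")) {
    report$timings <- timings
    return(finish_report(report, cfg))
  }

  # --- split & segment ------------------------------------------------------
  t0 <- Sys.time()
  set.seed(cfg$seed + 1L)
  test_ix <- sort(unlist(lapply(split(seq_along(labels), labels),
    function(ix) sample(ix, max(1L, round(length(ix) * (1 - cfg$train_fraction)))))))
  train_ix <- setdiff(seq_along(labels), test_ix)

  sgc <- cfg$segmenter
  seg_model <- train_segmenter(
    ds$samples[train_ix[seq_len(min(sgc$n_train_images, length(train_ix)))]],
    hidden = sgc$hidden, patch = sgc$patch, per_class = sgc$per_class,
    oversample_cap = sgc$oversample_cap, steps = sgc$steps,
    batch = sgc$batch, decay = sgc$decay, weight_power = sgc$weight_power,
    preprocess = function(img) preprocess_fundus(img, target_size = sz,
                                                 spec = spec),
    seed = cfg$seed + 2L)
  seg_model <- quantize_segmenter(seg_model, S = sgc$S,
                                  diffusion = sgc$diffusion)
  # confidence-masked labeling for count/distance summaries, raw labeling
  # alongside it; downstream selection picks whichever block informs
  segs <- lapply(pre, segment_fundus, model = seg_model,
                 quantized = sgc$use_quantized)
  segs_raw <- lapply(pre, segment_fundus, model = seg_model,
                     quantized = sgc$use_quantized, min_confidence = 0)
  # quantized/float agreement pooled over (up to 10) test images
  agree_ix <- test_ix[seq_len(min(10, length(test_ix)))]
  agree <- vapply(agree_ix, function(i) {
    f <- segment_fundus(pre[[i]], seg_model, quantized = FALSE)
    q <- segment_fundus(pre[[i]], seg_model, quantized = TRUE)
    mean(f == q)
  }, numeric(1))
  report$segmenter_agreement <- mean(agree)
  tick("segment", t0)
  if (!run_stage("extract")) {
    report$timings <- timings
    return(finish_report(report, cfg))
  }

  # --- extract --------------------------------------------------------------
  t0 <- Sys.time()
  seg_in <- function(i) list(segs[[i]], raw = segs_raw[[i]])
  feats <- t(vapply(seq_along(pre), function(i)
    extract_gabor_features(pre[[i]], seg_in(i), cfg$bank),
    extract_gabor_features(pre[[1]], seg_in(1), cfg$bank)))
  rownames(feats) <- sprintf("sample_%04d", seq_len(nrow(feats)))
  if (!is.null(cfg$output_dir)) {
    utils::write.csv(data.frame(label = labels, feats),
                     file.path(cfg$output_dir, "features.csv"))
  }
  tick("extract", t0)
  if (!run_stage("select")) {
    report$timings <- timings
    return(finish_report(report, cfg))
  }

  # --- select ---------------------------------------------------------------
  t0 <- Sys.time()
  selc <- cfg$selection
  selc$seed <- cfg$seed + 3L
  sel <- select_features(feats[train_ix, , drop = FALSE], labels[train_ix],
                         selc)
  if (length(sel) < 2L) {  # degenerate guard: keep the top-importance pair
    imp <- attr(sel, "importance_norm")
    sel <- order(imp, decreasing = TRUE)[1:2]
    names(sel) <- colnames(feats)[sel]
  }
  report$selected_features <- names(sel)
  if (!is.null(cfg$output_dir)) {
    utils::write.csv(
      data.frame(name = names(sel),
                 importance_norm = attr(sel, "importance_norm")[sel],
                 rank = seq_along(sel)),
      file.path(cfg$output_dir, "selected_features.csv"), row.names = FALSE)
  }
  tick("select", t0)
  if (!run_stage("train")) {
    report$timings <- timings
    return(finish_report(report, cfg))
  }

  # --- train ----------------------------------------------------------------
  t0 <- Sys.time()
  clc <- cfg$classifier
  ccfg <- cnn_config(levels(labels), input_mode = clc$input_mode,
                     fc = clc$fc)
  model <- train_grade_classifier(feats[train_ix, names(sel), drop = FALSE],
                                  labels[train_ix], cfg = ccfg,
                                  steps = clc$steps, n_swarm = clc$n_swarm,
                                  seed = cfg$seed + 4L)
  tick("train", t0)
  if (!run_stage("evaluate")) {
    report$timings <- timings
    return(finish_report(report, cfg))
  }

  # --- evaluate -------------------------------------------------------------
  t0 <- Sys.time()
  pred <- predict(model, feats[test_ix, names(sel), drop = FALSE])
  met <- evaluate_metrics(pred, labels[test_ix], classes = levels(labels))
  report$metrics <- list(
    accuracy = met$accuracy,
    sensitivity = unname(met$macro["sensitivity"]),
    specificity = unname(met$macro["specificity"]),
    precision = unname(met$macro["precision"]),
    f1 = unname(met$macro["f1"]),
    n_test = length(test_ix),
    confusion = as.data.frame.matrix(met$confusion))
  tick("evaluate", t0)

  report$timings <- timings
  report$total_seconds <- round(as.numeric(Sys.time() - t_all,
                                           units = "secs"), 2)
  finish_report(report, cfg)
}

finish_report <- function(report, cfg) {
  report$versions <- list(
    package = tryCatch(as.character(utils::packageVersion("retinograde")),
                       error = function(e) "dev"),
    r = paste(R.version$major, R.version$minor, sep = "."))
  if (!is.null(cfg$output_dir)) {
    if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir,
                                                recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }
  report
}
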