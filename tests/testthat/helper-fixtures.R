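# shared small fixtures, built in code at load time

fixture_generator <- function(size = 96L, seed = 1L) {
  generator_config(image_size = size, seed = seed)
}

# one cached tiny training set + segmenter, reused by segmentation and
# pipeline tests (training is the slow part)
.fixture_env <- new.env()

fixture_segmenter <- function() {
  if (is.null(.fixture_env$seg)) {
    cfg <- fixture_generator()
    keys <- names(cfg$class_mix)
    samples <- lapply(seq_len(8), function(i)
      generate_fundus_sample(cfg, keys[i], 7000 + i))
    .fixture_env$seg_samples <- samples
    .fixture_env$seg <- quantize_segmenter(
      train_segmenter(samples, seed = 11L))
  }
  list(model = .fixture_env$seg, samples = .fixture_env$seg_samples)
}

expect_all_finite <- function(x) {
  expect_true(all(is.finite(x)))
}
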