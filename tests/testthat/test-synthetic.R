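# the synthetic fundus generator and its grading rules

test_that("labels validate their enums and consistency", {
  l <- grade_label("moderate_NPDR", "severe")
  expect_s3_class(l, "grade_label")
  expect_error(grade_label("healthy", "mild"), "healthy")
  expect_error(grade_label("bad_grade"), "arg")
  expect_equal(dr_grades()[1], "healthy")
  expect_length(dr_grades(), 5)
  expect_length(dme_grades(), 4)
})

test_that("configs validate mixes and thresholds", {
  expect_error(generator_config(image_size = 32), ">= 64")
  expect_error(generator_config(class_mix = c("healthy:none" = 0.5)),
               "sum to 1")
  expect_error(generator_config(
    dme_thresholds = c(severe = 0.4, moderate = 0.2)), "decreasing")
})

test_that("identical config and seed give bit-identical samples", {
  cfg <- fixture_generator()
  a <- generate_fundus_sample(cfg, "mild_NPDR:none", 3)
  b <- generate_fundus_sample(cfg, "mild_NPDR:none", 3)
  expect_identical(a, b)
  # 8-bit quantized image in [0, 1]
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_identical(a$image, round(a$image * 255) / 255)
})

test_that("healthy samples carry no lesions", {
  cfg <- fixture_generator()
  s <- generate_fundus_sample(cfg, grade_label("healthy"), 7)
  lesions <- s$masks[c("microaneurysm", "haemorrhage", "hard_exudate",
                       "soft_exudate")]
  expect_false(any(unlist(lesions)))
  expect_error(generate_fundus_sample(cfg,
    structure(list(dr_grade = "healthy", dme_grade = "mild"),
              class = "grade_label"), 1), "healthy")
})

test_that("masks live inside the circular field and vessels touch the disc", {
  cfg <- fixture_generator()
  s <- generate_fundus_sample(cfg, "severe_NPDR:none", 11)
  n <- cfg$image_size
  ctr <- (n + 1) / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  for (m in s$masks) {
    expect_true(all(d[m] <= 0.47 * n + 0.01))
    expect_equal(dim(m), dim(s$image)[1:2])
  }
  expect_true(retinograde:::mask_connected_8(s$masks$vessel,
                                             s$masks$optic_disc))
})

test_that("severe DME pins a hard exudate inside the severe band", {
  cfg <- fixture_generator()
  s <- generate_fundus_sample(cfg, "moderate_NPDR:severe", 13)
  n <- cfg$image_size; ctr <- (n + 1) / 2; Rf <- 0.47 * n
  he <- which(s$masks$hard_exudate, arr.ind = TRUE)
  dmin <- min(sqrt((he[, 1] - ctr)^2 + (he[, 2] - ctr)^2))
  expect_lt(dmin, cfg$dme_thresholds[["severe"]] * Rf)
})

test_that("the grade recomputed from the masks matches the request", {
  cfg <- fixture_generator()
  keys <- names(cfg$class_mix)
  for (k in keys) for (sd in 1:3) {
    s <- generate_fundus_sample(cfg, k, 300 + sd)
    g <- grade_from_masks(s)
    expect_equal(paste(g$dr_grade, g$dme_grade, sep = ":"), k,
                 info = sprintf("%s seed %d", k, sd))
  }
})

test_that("datasets follow the class mix and write a manifest", {
  cfg <- fixture_generator(seed = 5)
  d8 <- generate_fundus_dataset(cfg, 8)
  key <- paste(d8$manifest$dr_grade, d8$manifest$dme_grade, sep = ":")
  expect_equal(sort(key), sort(names(cfg$class_mix)))
  expect_equal(nrow(d8$manifest), 8)

  # two-class healthy-vs-infected design: 75/75
  cfg2 <- generator_config(image_size = 96,
    class_mix = c("healthy:none" = 0.5, "moderate_NPDR:none" = 0.5),
    seed = 6)
  d150 <- generate_fundus_dataset(cfg2, 150)
  expect_equal(unname(table(d150$manifest$dr_grade)),
               c(75L, 75L), ignore_attr = TRUE)
  expect_equal(nrow(d150$manifest), 150)

  expect_error(generate_fundus_dataset(cfg, 4), "smaller")
})

test_that("written datasets round-trip through PNG and CSV", {
  cfg <- generator_config(image_size = 96,
    class_mix = c("healthy:none" = 0.5, "mild_NPDR:none" = 0.5), seed = 7)
  dir <- withr::local_tempdir()
  d <- generate_fundus_dataset(cfg, 2, write_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- png::readPNG(d$manifest$path[1])
  expect_equal(dim(img), c(96, 96, 3))
  expect_equal(img, d$samples[[1]]$image, tolerance = 1e-7)
})

test_that("segmentation ground truth prioritizes lesions over anatomy", {
  cfg <- fixture_generator()
  s <- generate_fundus_sample(cfg, "moderate_NPDR:severe", 17)
  truth <- seg_truth(s)
  expect_true(all(truth[s$masks$hard_exudate] == "hard_exudate"))
  expect_true(all(truth %in% seg_class_map()))
})
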