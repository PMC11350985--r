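Package: retinograde
Title: Automated Grading of Diabetic Retinopathy and Macular Edema from Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale, fully testable implementation of an automatic
    diabetic retinopathy (DR) and diabetic macular edema (DME) grading
    pipeline for retinal fundus photographs. Provides a labelled synthetic
    fundus image generator (vessels, optic disc, fovea, microaneurysms,
    haemorrhages, hard and soft exudates), multilevel 2D discrete wavelet
    transform preprocessing and denoising, a feed-forward neural-network
    pixel segmenter whose multipliers are replaced by shift-add
    (power-of-two) quantized weights with error diffusion and a
    piecewise-linear tanh, adaptive Gabor filter-bank feature extraction
    with DC removal for illumination invariance, penalized-Gini regularized
    random-forest feature selection, and a chicken-swarm-optimized neural
    classifier, together with image-quality metrics (RMSE, PSNR, SSIM, MSE)
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse,
    withr
Config/testthat/edition: 3
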