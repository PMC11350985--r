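#' DR/DME grade label
#'
#' The diabetic retinopathy grade takes one of five values (healthy, mild,
#' moderate and severe non-proliferative DR, proliferative DR); diabetic
#' macular edema is graded none/mild/moderate/severe by how close hard
#' exudates sit to the fovea. A healthy eye cannot carry a DME grade.
#'
#' @param dr_grade One of [dr_grades()].
#' @param dme_grade One of [dme_grades()].
#' @return Object of class `"grade_label"`.
#' @export
grade_label <- function(dr_grade, dme_grade = "none") {
  dr_grade <- match.arg(dr_grade, dr_grades())
  dme_grade <- match.arg(dme_grade, dme_grades())
  if (dr_grade == "healthy" && dme_grade != "none") {
    stop("a healthy eye cannot carry a DME grade (got dme_grade = ",
         dme_grade, ")", call. = FALSE)
  }
  structure(list(dr_grade = dr_grade, dme_grade = dme_grade),
            class = "grade_label")
}

#' @rdname grade_label
#' @export
dr_grades <- function() {
  c("healthy", "mild_NPDR", "moderate_NPDR", "severe_NPDR", "proliferative_DR")
}

#' @rdname grade_label
#' @export
dme_grades <- function() c("none", "mild", "moderate", "severe")

label_key <- function(label) paste(label$dr_grade, label$dme_grade, sep = ":")

parse_label <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  grade_label(parts[1], parts[2])
}

#' @export
print.grade_label <- function(x, ...) {
  cat(sprintf("grade: DR %s, DME %s\n", x$dr_grade, x$dme_grade))
  invisible(x)
}

#' Segmentation class map
#'
#' The pixel classes the segmenter distinguishes: retinal background, blood
#' vessels, optic disc, fovea and the four lesion types.
#' @return Character vector of class names, background first.
#' @export
seg_class_map <- function() {
  c("background", "vessel", "optic_disc", "fovea",
    "microaneurysm", "haemorrhage", "hard_exudate", "soft_exudate")
}

#' Synthetic fundus generator configuration
#'
#' Encodes the grading rules the generator enforces: DR grade is driven by
#' lesion load (counts of microaneurysms, haemorrhages, soft exudates, and
#' neovascular vessel growth), DME grade by the minimum distance from any
#' hard-exudate pixel to the fovea centre, with thresholds expressed as
#' fractions of the fundus-field radius `R` (severe below `R/6`, moderate
#' below `R/3`, mild beyond — severity strictly increases as the distance
#' shrinks).
#'
#' @param image_size Side length in pixels (`>= 64`). Default 128.
#' @param class_mix Named proportions per joint label (`"dr:dme"` keys)
#'   summing to 1. Default: uniform over the 8 study classes — the five DR
#'   grades without DME plus moderate NPDR with mild/moderate/severe DME.
#' @param lesion_counts Per-grade count ranges, see the default for the
#'   structure (each entry `c(min, max)` component counts).
#' @param dme_thresholds `c(severe =, moderate =)` distance cutoffs as
#'   fractions of `R`, strictly increasing.
#' @param hard_exudate_count Range of hard-exudate components when DME is
#'   present.
#' @param noise_sd Additive Gaussian pixel noise SD on the `[0, 1]` scale.
#' @param nv_density Vessel-pixel density within 1.5 disc radii of the
#'   disc centre above which growth counts as neovascular (proliferative).
#' @param seed Integer master seed for [generate_fundus_dataset()].
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(image_size = 128L,
                             class_mix = NULL,
                             lesion_counts = NULL,
                             dme_thresholds = c(severe = 1 / 6, moderate = 1 / 3),
                             hard_exudate_count = c(2L, 5L),
                             noise_sd = 0.02,
                             nv_density = 0.48,
                             seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) stop("image_size must be >= 64", call. = FALSE)
  if (is.null(class_mix)) {
    keys <- c("healthy:none", "mild_NPDR:none", "moderate_NPDR:none",
              "severe_NPDR:none", "proliferative_DR:none",
              "moderate_NPDR:mild", "moderate_NPDR:moderate",
              "moderate_NPDR:severe")
    class_mix <- stats::setNames(rep(1 / 8, 8), keys)
  }
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    stop("class_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  }
  for (k in names(class_mix)) parse_label(k)  # validates keys
  if (is.null(lesion_counts)) {
    lesion_counts <- list(
      mild_NPDR        = list(ma = c(1L, 5L), hg = c(0L, 0L), se = c(0L, 0L)),
      moderate_NPDR    = list(ma = c(1L, 4L), hg = c(1L, 3L), se = c(0L, 2L)),
      severe_NPDR      = list(ma = c(5L, 8L), hg = c(4L, 6L), se = c(1L, 2L)),
      proliferative_DR = list(ma = c(5L, 8L), hg = c(4L, 6L), se = c(1L, 2L))
    )
  }
  if (!(dme_thresholds["severe"] < dme_thresholds["moderate"])) {
    stop("DME thresholds must increase from severe to moderate ",
         "(severity strictly decreasing with distance)", call. = FALSE)
  }
  structure(list(image_size = image_size, class_mix = class_mix,
                 lesion_counts = lesion_counts,
                 dme_thresholds = dme_thresholds,
                 hard_exudate_count = as.integer(hard_exudate_count),
                 noise_sd = noise_sd, nv_density = nv_density,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# --- low-level raster painting ----------------------------------------------

# paint a filled disc into channel matrices and a mask, clipped to the field
stamp_disc <- function(canvas, center, radius, color, alpha = 1,
                       soft = FALSE, mask_name = NULL) {
  n <- nrow(canvas$r)
  r0 <- center[1]; c0 <- center[2]
  rr <- max(1L, floor(r0 - radius - 1)):min(n, ceiling(r0 + radius + 1))
  cc <- max(1L, floor(c0 - radius - 1)):min(n, ceiling(c0 + radius + 1))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  inside <- d2 <= radius^2 & canvas$field[rr, cc]
  if (!any(inside)) return(canvas)
  a <- if (soft) alpha * exp(-d2 / (2 * (0.6 * radius)^2)) else
    matrix(alpha, length(rr), length(cc))
  a[!inside] <- 0
  for (ch in c("r", "g", "b")) {
    i <- match(ch, c("r", "g", "b"))
    canvas[[ch]][rr, cc] <- (1 - a) * canvas[[ch]][rr, cc] + a * color[i]
  }
  if (!is.null(mask_name)) {
    canvas$masks[[mask_name]][rr, cc] <-
      canvas$masks[[mask_name]][rr, cc] | inside
  }
  canvas
}

# grow one vessel branch as a correlated random walk; every step stamps a
# small disc so the drawn path is 8-connected back to its origin
grow_vessel <- function(canvas, start, angle, length, width, color,
                        wobble = 0.25, branch_p = 0.025, depth = 0L) {
  pos <- start
  n <- nrow(canvas$r)
  ctr <- (n + 1) / 2
  Rf <- canvas$R
  for (step in seq_len(length)) {
    w <- max(0.7, width * (1 - 0.6 * step / length))
    canvas <- stamp_disc(canvas, pos, w, color, alpha = 0.85,
                         mask_name = "vessel")
    angle <- angle + stats::rnorm(1, 0, wobble)
    pos <- pos + c(sin(angle), cos(angle))
    if (sqrt(sum((pos - ctr)^2)) > 0.93 * Rf) break
    if (depth < 2L && stats::runif(1) < branch_p) {
      canvas <- grow_vessel(canvas, pos, angle + sample(c(-1, 1), 1) * 0.7,
                            ceiling((length - step) * 0.7), w * 0.85, color,
                            wobble, branch_p, depth + 1L)
    }
  }
  canvas
}

# sample a lesion centre inside the field with distance constraints; if the
# raster is too crowded to respect separation from every earlier lesion,
# fall back to separation from same-class lesions only (cross-class overlap
# does not disturb per-mask component counts)
sample_position <- function(n, Rf, d_range, taken_all, taken_class, min_sep,
                            avoid = NULL, avoid_r = 0, quadrant = NULL,
                            max_try = 300L) {
  ctr <- (n + 1) / 2
  for (pass in 1:2) {
    taken <- if (pass == 1L) taken_all else taken_class
    for (i in seq_len(max_try)) {
      d <- stats::runif(1, d_range[1], d_range[2])
      a <- stats::runif(1, 0, 2 * pi)
      pos <- ctr + d * c(sin(a), cos(a))
      if (!is.null(quadrant)) {
        q <- 1L + (pos[1] > ctr) + 2L * (pos[2] > ctr)
        if (q != quadrant) next
      }
      if (!is.null(avoid) &&
          sqrt(sum((pos - avoid)^2)) < avoid_r) next
      ok <- TRUE
      for (t_ in taken) if (sqrt(sum((pos - t_)^2)) < min_sep) { ok <- FALSE; break }
      if (ok) return(pos)
    }
  }
  stop("could not place lesion under the distance constraints", call. = FALSE)
}

rint <- function(lo, hi) if (hi <= lo) as.integer(lo) else
  sample(seq.int(lo, hi), 1L)

# --- the generator ----------------------------------------------------------

#' Generate one labelled synthetic fundus image
#'
#' Renders a circular fundus field with a red-dominant background, a
#' branching dark vessel tree rooted at a bright optic disc, a dark fovea
#' at the raster centre, and grade-consistent pathology: microaneurysm,
#' haemorrhage and soft-exudate counts drawn from the configured per-grade
#' ranges (severe grades span at least two quadrants, proliferative adds
#' dense neovascular growth at the disc), and hard exudates placed so the
#' minimum pixel distance to the fovea centre falls inside the requested
#' DME band. The green channel carries the strongest vessel/lesion
#' contrast, as in real fundus photography. Fully reproducible from
#' `(config, label, seed)`.
#'
#' @param config A [generator_config()].
#' @param label A [grade_label()] (or a `"dr:dme"` key string).
#' @param seed Integer seed for this sample.
#' @return Object of class `"fundus_sample"`: list with `image`
#'   (`H x W x 3` array in `[0, 1]`, 8-bit quantized), `masks` (named list
#'   of logical `H x W` matrices per structure), `label`, and `provenance`
#'   (generator parameters and seed).
#' @export
generate_fundus_sample <- function(config, label, seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  if (is.character(label)) label <- parse_label(label)
  stopifnot(inherits(label, "grade_label"))
  grade_label(label$dr_grade, label$dme_grade)  # re-validate consistency
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  n <- config$image_size
  ctr <- (n + 1) / 2
  Rf <- 0.47 * n
  sc <- n / 128                      # lesion radii scale with the raster

  coord <- seq_len(n)
  d_ctr <- sqrt(outer((coord - ctr)^2, (coord - ctr)^2, "+"))
  field <- d_ctr <= Rf

  masks <- stats::setNames(
    lapply(seg_class_map()[-1], function(cl) matrix(FALSE, n, n)),
    seg_class_map()[-1])
  canvas <- list(
    r = matrix(0.06, n, n), g = matrix(0.05, n, n), b = matrix(0.04, n, n),
    field = field, masks = masks, R = Rf)

  # red-dominant background with a mild radial vignette
  vig <- 1 - 0.35 * (d_ctr / Rf)^2
  canvas$r[field] <- (0.72 * vig)[field]
  canvas$g[field] <- (0.38 * vig)[field]
  canvas$b[field] <- (0.13 * vig)[field]

  # optic disc on a randomly chosen side, fovea at the centre
  disc_r <- 0.16 * Rf
  side <- sample(c(-1, 1), 1)
  disc_c <- c(ctr + stats::rnorm(1, 0, 0.03 * Rf),
              ctr + side * 0.6 * Rf)
  canvas <- stamp_disc(canvas, disc_c, disc_r, c(0.95, 0.82, 0.45),
                       mask_name = "optic_disc")

  # main vessel arcades leave the disc rim
  vessel_col <- c(0.42, 0.12, 0.08)
  n_main <- rint(5L, 7L)
  for (i in seq_len(n_main)) {
    a0 <- 2 * pi * i / n_main + stats::rnorm(1, 0, 0.2)
    start <- disc_c + disc_r * c(sin(a0), cos(a0))
    canvas <- grow_vessel(canvas, start, a0, ceiling(1.8 * Rf),
                          width = 1.8 * sc, color = vessel_col)
  }

  # neovascular tufts for proliferative disease: short, dense, tortuous
  if (label$dr_grade == "proliferative_DR") {
    for (i in seq_len(14L)) {
      a0 <- stats::runif(1, 0, 2 * pi)
      start <- disc_c + stats::runif(1, 0.2, 1) * disc_r * c(sin(a0), cos(a0))
      canvas <- grow_vessel(canvas, start, a0, ceiling(0.5 * Rf),
                            width = 1.1 * sc, color = vessel_col,
                            wobble = 0.8, branch_p = 0.12, depth = 2L)
    }
  }

  fovea_r <- 0.09 * Rf
  canvas <- stamp_disc(canvas, c(ctr, ctr), fovea_r, c(0.40, 0.16, 0.06),
                       alpha = 0.9, soft = TRUE, mask_name = "fovea")

  # ---- pathology -----------------------------------------------------------
  taken <- list()
  taken_by_class <- list()
  place <- function(canvas, count, radius, color, mask_name, d_range,
                    quadrants = NULL, soft = FALSE) {
    for (i in seq_len(count)) {
      q <- if (!is.null(quadrants)) quadrants[1 + (i - 1) %% length(quadrants)]
      pos <- sample_position(n, Rf, d_range, taken,
                             taken_by_class[[mask_name]],
                             min_sep = 2 * radius + 3,
                             avoid = disc_c, avoid_r = disc_r + radius + 2,
                             quadrant = q)
      taken[[length(taken) + 1L]] <<- pos
      taken_by_class[[mask_name]] <<- c(taken_by_class[[mask_name]], list(pos))
      canvas <- stamp_disc(canvas, pos, radius, color, soft = soft,
                           alpha = if (soft) 0.95 else 1,
                           mask_name = mask_name)
    }
    canvas
  }

  if (label$dr_grade != "healthy") {
    cnt <- config$lesion_counts[[label$dr_grade]]
    n_ma <- rint(cnt$ma[1], cnt$ma[2])
    n_hg <- rint(cnt$hg[1], cnt$hg[2])
    n_se <- rint(cnt$se[1], cnt$se[2])
    severe_like <- label$dr_grade %in% c("severe_NPDR", "proliferative_DR")
    quads <- if (severe_like) sample(4L, 4L) else NULL
    lesion_floor <- 0.16 * Rf        # keep counted lesions off the fovea
    canvas <- place(canvas, n_ma, max(1, 1.4 * sc), c(0.30, 0.07, 0.05),
                    "microaneurysm", c(lesion_floor, 0.85 * Rf), quads)
    canvas <- place(canvas, n_hg, 3.2 * sc, c(0.33, 0.06, 0.05),
                    "haemorrhage", c(lesion_floor, 0.85 * Rf), quads)
    canvas <- place(canvas, n_se, 4.5 * sc, c(0.88, 0.82, 0.62),
                    "soft_exudate", c(lesion_floor, 0.85 * Rf), quads,
                    soft = TRUE)
  }

  if (label$dme_grade != "none") {
    he_r <- max(1, 1.9 * sc)
    th <- config$dme_thresholds * Rf          # c(severe, moderate) in px
    band <- switch(label$dme_grade,
      severe   = c(0, th[["severe"]] - he_r - 1),
      moderate = c(th[["severe"]] + he_r + 1, th[["moderate"]] - he_r - 1),
      mild     = c(th[["moderate"]] + he_r + 1, 0.8 * Rf))
    floor_d <- band[1]
    n_he <- rint(config$hard_exudate_count[1], config$hard_exudate_count[2])
    # first exudate pins the DME band; the rest may lie anywhere farther out
    canvas <- place(canvas, 1L, he_r, c(0.97, 0.92, 0.40), "hard_exudate",
                    band)
    if (n_he > 1L) {
      canvas <- place(canvas, n_he - 1L, he_r, c(0.97, 0.92, 0.40),
                      "hard_exudate", c(max(floor_d, 0.3 * Rf), 0.8 * Rf))
    }
  }

  # pixel noise inside the field, then 8-bit quantization
  img <- array(0, c(n, n, 3))
  for (i in 1:3) {
    ch <- canvas[[c("r", "g", "b")[i]]]
    ch[field] <- ch[field] + stats::rnorm(sum(field), 0, config$noise_sd)
    img[, , i] <- round(pmin(pmax(ch, 0), 1) * 255) / 255
  }

  structure(list(image = img, masks = canvas$masks, label = label,
                 provenance = list(config = config, seed = as.integer(seed))),
            class = "fundus_sample")
}

#' @export
print.fundus_sample <- function(x, ...) {
  cat(sprintf("fundus sample %dx%d | DR %s, DME %s | seed %d\n",
              dim(x$image)[1], dim(x$image)[2],
              x$label$dr_grade, x$label$dme_grade, x$provenance$seed))
  invisible(x)
}

#' Recompute the grade of a sample from its masks
#'
#' Applies the generator's own grading rules to the structure masks,
#' independent of the label the sample was generated with: lesion
#' components are counted with [EBImage::bwlabel()]; proliferative DR is
#' detected as excess vessel density near the optic disc; severe NPDR as at
#' least 10 lesion components spanning at least 2 quadrants; moderate as
#' the presence of haemorrhages or soft exudates; mild as microaneurysms
#' only. The DME grade is banded by the minimum distance from any
#' hard-exudate pixel to the fovea centre.
#'
#' @param sample A `"fundus_sample"` (or a bare named mask list plus
#'   `config`).
#' @param config A [generator_config()]; defaults to the sample's own.
#' @return A [grade_label()].
#' @export
grade_from_masks <- function(sample, config = NULL) {
  masks <- if (inherits(sample, "fundus_sample")) sample$masks else sample
  if (is.null(config) && inherits(sample, "fundus_sample")) {
    config <- sample$provenance$config
  }
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(masks$vessel)
  ctr <- (n + 1) / 2
  Rf <- 0.47 * n

  comp_count <- function(m) max(EBImage::bwlabel(EBImage::Image(m * 1)))
  centroids <- function(m) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))@.Data
    k <- max(lab)
    if (k == 0) return(matrix(0, 0, 2))
    t(vapply(seq_len(k), function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      colMeans(w)
    }, numeric(2)))
  }

  n_ma <- comp_count(masks$microaneurysm)
  n_hg <- comp_count(masks$haemorrhage)
  n_se <- comp_count(masks$soft_exudate)
  n_lesions <- n_ma + n_hg + n_se

  # neovascular check: vessel density close to the disc
  dc <- centroids(masks$optic_disc)
  nv <- FALSE
  if (nrow(dc) > 0) {
    disc_ctr <- colMeans(dc)
    disc_r <- sqrt(sum(masks$optic_disc) / pi)
    coord <- seq_len(n)
    dd <- sqrt(outer((coord - disc_ctr[1])^2, (coord - disc_ctr[2])^2, "+"))
    near <- dd <= 1.5 * disc_r
    nv <- mean(masks$vessel[near]) > config$nv_density
  }

  cents <- rbind(centroids(masks$microaneurysm),
                 centroids(masks$haemorrhage),
                 centroids(masks$soft_exudate))
  quads <- if (nrow(cents) > 0) {
    length(unique(1L + (cents[, 1] > ctr) + 2L * (cents[, 2] > ctr)))
  } else 0L

  dr <- if (nv) "proliferative_DR"
    else if (n_lesions >= 10L && quads >= 2L) "severe_NPDR"
    else if (n_hg >= 1L || n_se >= 1L) "moderate_NPDR"
    else if (n_ma >= 1L) "mild_NPDR"
    else "healthy"

  dme <- "none"
  if (any(masks$hard_exudate)) {
    he <- which(masks$hard_exudate, arr.ind = TRUE)
    dmin <- min(sqrt((he[, 1] - ctr)^2 + (he[, 2] - ctr)^2))
    th <- config$dme_thresholds * Rf
    dme <- if (dmin < th[["severe"]]) "severe"
      else if (dmin < th[["moderate"]]) "moderate"
      else "mild"
  }
  grade_label(dr, dme)
}

#' Generate a labelled synthetic fundus dataset
#'
#' Draws `n` samples whose joint-label counts follow the configured class
#' mix (largest-remainder rounding), each from its own sub-seed derived
#' from the master seed, and builds a manifest. Optionally writes the
#' images as PNG plus a `manifest.csv`.
#'
#' @param config A [generator_config()].
#' @param n Number of samples (`>=` the number of classes with nonzero
#'   mix).
#' @param write_dir Optional directory for PNG output and the manifest.
#' @return List with `samples` (list of `"fundus_sample"`) and `manifest`
#'   (data frame with `path`, `dr_grade`, `dme_grade`, `seed`).
#' @export
generate_fundus_dataset <- function(config, n, write_dir = NULL) {
  stopifnot(inherits(config, "generator_config"), n >= 1L)
  mix <- config$class_mix[config$class_mix > 0]
  if (n < length(mix)) {
    stop(sprintf("n = %d is smaller than the %d classes with nonzero mix",
                 n, length(mix)), call. = FALSE)
  }
  # largest-remainder apportionment
  raw <- mix * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(counts), counts)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- sample(labels)            # shuffle class order

  samples <- vector("list", n)
  paths <- character(n)
  for (i in seq_len(n)) {
    samples[[i]] <- generate_fundus_sample(config, labels[i], seeds[i])
    if (!is.null(write_dir)) {
      if (!dir.exists(write_dir)) dir.create(write_dir, recursive = TRUE)
      paths[i] <- file.path(write_dir, sprintf("sample_%04d.png", i))
      png::writePNG(samples[[i]]$image, paths[i])
    }
  }
  manifest <- data.frame(
    path = paths,
    dr_grade = vapply(samples, function(s) s$label$dr_grade, character(1)),
    dme_grade = vapply(samples, function(s) s$label$dme_grade, character(1)),
    seed = seeds,
    stringsAsFactors = FALSE
  )
  if (!is.null(write_dir)) {
    utils::write.csv(manifest, file.path(write_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

# TRUE iff every TRUE pixel of `mask` is 8-connected (through mask|seed)
# to some TRUE pixel of `seed`; used by the vessel-connectivity invariant
mask_connected_8 <- function(mask, seed) {
  un <- mask | seed
  reach <- seed
  repeat {
    grown <- reach
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_mask(reach, dr, dc)
    }
    grown <- grown & un
    if (identical(grown, reach)) break
    reach <- grown
  }
  all(reach[mask])
}

shift_mask <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= p
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Ground-truth segmentation label mask of a synthetic sample
#'
#' Collapses the per-structure masks into a single character label matrix,
#' giving lesions priority over anatomy where masks overlap.
#'
#' @param sample A `"fundus_sample"`.
#' @return Character matrix over [seg_class_map()].
#' @export
seg_truth <- function(sample) {
  stopifnot(inherits(sample, "fundus_sample"))
  m <- sample$masks
  n <- nrow(m$vessel)
  out <- matrix("background", n, n)
  for (cl in c("vessel", "optic_disc", "fovea", "soft_exudate",
               "haemorrhage", "microaneurysm", "hard_exudate")) {
    out[m[[cl]]] <- cl
  }
  out
}
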