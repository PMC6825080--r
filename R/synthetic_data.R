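# Synthetic speckle-phantom cohorts: four tissue classes whose grey-level
# histogram shape (gamma speckle -> skewness/kurtosis) and spatial correlation
# structure differ, grouped into patients with several images per lesion.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Texture parameters for one tissue class
#'
#' Describes the speckle model of one class: a gamma-distributed multiplicative
#' noise field (shape `skew_shape`, so smaller values give more right-skewed,
#' heavier-tailed histograms) smoothed by a Gaussian kernel of standard
#' deviation `correlation_length_px`, then affinely mapped so the masked
#' histogram has mean `mean_level` and spread `contrast_scale` on the 0-255
#' grey scale.
#'
#' @param class_label one of `"malignant"`, `"benign"`, `"fat"`, `"glandular"`.
#' @param mean_level target mean grey level, in (0, 255).
#' @param contrast_scale target grey-level standard deviation (> 0).
#' @param correlation_length_px Gaussian blur standard deviation in pixels
#'   (> 0); larger values give coarser, more spatially correlated speckle.
#' @param skew_shape gamma shape parameter (> 0) of the raw speckle;
#'   controls histogram skewness/kurtosis before smoothing.
#' @return an object of class `class_texture_params`.
#' @export
class_texture_params <- function(class_label, mean_level, contrast_scale,
                                 correlation_length_px, skew_shape) {
  class_label <- match.arg(class_label, c("malignant", "benign", "fat", "glandular"))
  check_scalar_positive(mean_level, "mean_level")
  if (mean_level >= 255) stop_param("'mean_level' must be in (0, 255)")
  check_scalar_positive(contrast_scale, "contrast_scale")
  check_scalar_positive(correlation_length_px, "correlation_length_px")
  check_scalar_positive(skew_shape, "skew_shape")
  structure(list(class_label = class_label, mean_level = mean_level,
                 contrast_scale = contrast_scale,
                 correlation_length_px = correlation_length_px,
                 skew_shape = skew_shape),
            class = "class_texture_params")
}

#' Default four-class texture parameters
#'
#' A fixed, strongly separated parameterisation of the four tissue classes:
#' malignant lesions are dark (hypoechoic), coarse and heavily skewed; benign
#' lesions intermediate; fat bright and smooth-histogrammed; glandular tissue
#' brightest with the finest speckle. Skewness decreases monotonically with
#' `skew_shape` from malignant to glandular.
#'
#' @return named list of [class_texture_params()], one per class.
#' @export
default_class_params <- function() {
  list(
    malignant = class_texture_params("malignant", 60, 30, 3.0, 0.7),
    benign    = class_texture_params("benign",   110, 25, 1.5, 2.0),
    fat       = class_texture_params("fat",      150, 20, 4.0, 5.0),
    glandular = class_texture_params("glandular", 190, 18, 1.0, 10.0)
  )
}

#' Cohort specification
#'
#' @param class_params named list of [class_texture_params()]; names must
#'   match each element's `class_label` and be unique. May be a subset of the
#'   four classes (the full pipeline requires all four).
#' @param n_patients_per_class patients simulated per class.
#' @param images_per_lesion integer range `c(lo, hi)`; the number of images
#'   of each lesion is drawn uniformly from this range (default 2-16,
#'   mirroring clinical series with a handful of images per lesion).
#' @param n_images_per_tissue images per fat/glandular patient (default 2).
#' @param image_shape `c(rows, cols)` of each image (default 64 x 64).
#' @param lesion_radius_px integer range of lesion radii in pixels.
#' @param seed integer; identical spec + seed reproduces the cohort exactly.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(class_params = default_class_params(),
                        n_patients_per_class = 20,
                        images_per_lesion = c(2L, 16L),
                        n_images_per_tissue = 2L,
                        image_shape = c(64L, 64L),
                        lesion_radius_px = c(8L, 14L),
                        seed = 1L) {
  if (is.null(names(class_params)) || anyDuplicated(names(class_params))) {
    stop_param("'class_params' must be a uniquely named list")
  }
  for (nm in names(class_params)) {
    p <- class_params[[nm]]
    if (!inherits(p, "class_texture_params") || p$class_label != nm) {
      stop_param("each element of 'class_params' must be class_texture_params with matching name")
    }
  }
  if (n_patients_per_class < 1) stop_param("'n_patients_per_class' must be >= 1")
  if (length(images_per_lesion) != 2L || any(images_per_lesion < 1) ||
      images_per_lesion[1] > images_per_lesion[2]) {
    stop_param("'images_per_lesion' must be an increasing range of positive integers")
  }
  if (any(image_shape < 16)) stop_param("'image_shape' must be at least 16 x 16")
  if (length(lesion_radius_px) != 2L || lesion_radius_px[1] > lesion_radius_px[2] ||
      lesion_radius_px[1] < 3) {
    stop_param("'lesion_radius_px' must be a range with minimum radius >= 3")
  }
  structure(list(class_params = class_params,
                 n_patients_per_class = as.integer(n_patients_per_class),
                 images_per_lesion = as.integer(images_per_lesion),
                 n_images_per_tissue = as.integer(n_images_per_tissue),
                 image_shape = as.integer(image_shape),
                 lesion_radius_px = as.integer(lesion_radius_px),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' One image + mask + metadata sample
#'
#' @param image numeric matrix of grey values in 0-255.
#' @param mask logical matrix, same shape, at least 16 TRUE pixels.
#' @param class_label,patient_id,image_id,reader_id metadata; `reader_id`
#'   may be `NULL`.
#' @return an object of class `roi_sample`.
#' @export
roi_sample <- function(image, mask, class_label, patient_id, image_id,
                       reader_id = NULL) {
  if (!is.matrix(image) || !is.matrix(mask) || !identical(dim(image), dim(mask))) {
    stop_param("'image' and 'mask' must be matrices of identical shape")
  }
  if (sum(mask) < 16L) stop_param("mask must contain at least 16 pixels")
  structure(list(image = image, mask = mask, class_label = class_label,
                 patient_id = patient_id, image_id = image_id,
                 reader_id = reader_id),
            class = "roi_sample")
}

# Separable Gaussian blur with replicated edges.
#' @noRd
gaussian_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) { # along rows (first index)
    n <- nrow(m)
    pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * pad[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(x))))
}

#' Generate one speckle texture field
#'
#' Draws i.i.d. gamma multiplicative speckle (shape = `skew_shape`, unit
#' mean), smooths it with a Gaussian kernel of standard deviation
#' `correlation_length_px`, then affinely maps the field to mean
#' `mean_level` and standard deviation `contrast_scale`, clips to
#' \[0, 255\] and rounds to integer grey values.
#'
#' @param params a [class_texture_params()].
#' @param shape `c(rows, cols)`, each at least 16.
#' @param seed integer seed; the same params + seed give identical fields.
#' @return numeric matrix of integers in \[0, 255\].
#' @export
generate_texture_field <- function(params, shape, seed) {
  if (!inherits(params, "class_texture_params")) stop_param("'params' must be class_texture_params")
  if (any(shape < 16)) stop_param("'shape' must be at least 16 x 16")
  with_seed(seed, {
    raw <- matrix(rgamma(prod(shape), shape = params$skew_shape,
                         rate = params$skew_shape),
                  nrow = shape[1], ncol = shape[2])
    sm <- gaussian_blur(raw, params$correlation_length_px)
    s <- sd(as.vector(sm))
    if (s < .Machine$double.eps) s <- 1
    z <- (sm - mean(sm)) / s
    round(pmin(pmax(params$mean_level + params$contrast_scale * z, 0), 255))
  })
}

#' Generate a single-blob lesion mask
#'
#' Rasterises a randomly perturbed ellipse: radii drawn from `radius_range`,
#' the boundary modulated by two low-order sinusoids of relative amplitude
#' `perturb`. The blob is centred with jitter but always kept at least two
#' pixels away from the image border, and is 8-connected by construction
#' (the perturbed boundary stays star-convex for `perturb` <= 0.25).
#'
#' @param shape `c(rows, cols)`.
#' @param radius_range integer range `c(lo, hi)`, `lo >= 3`.
#' @param seed integer seed.
#' @param perturb relative boundary perturbation amplitude in \[0, 0.25\].
#' @return logical matrix with a single connected blob of >= 16 pixels.
#' @export
generate_lesion_mask <- function(shape, radius_range, seed, perturb = 0.15) {
  if (length(radius_range) != 2L || radius_range[1] > radius_range[2] ||
      radius_range[1] < 3) {
    stop_param("'radius_range' must be an increasing range with minimum >= 3")
  }
  if (perturb < 0 || perturb > 0.25) stop_param("'perturb' must be in [0, 0.25]")
  rmax_eff <- ceiling(radius_range[2] * (1 + perturb)) + 2L
  if (2L * rmax_eff >= min(shape)) {
    stop_param("maximum lesion radius does not fit inside the image shape")
  }
  with_seed(seed, {
    rx <- runif(1, radius_range[1], radius_range[2])
    ry <- runif(1, radius_range[1], radius_range[2])
    slack_r <- shape[1] - 2 * rmax_eff
    slack_c <- shape[2] - 2 * rmax_eff
    cx <- rmax_eff + runif(1, 0, slack_r)
    cy <- rmax_eff + runif(1, 0, slack_c)
    amp <- if (perturb > 0) runif(2, 0, perturb) else c(0, 0)
    ph <- runif(2, 0, 2 * pi)
    ii <- matrix(seq_len(shape[1]), shape[1], shape[2])
    jj <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    u <- (ii - cx) / rx
    v <- (jj - cy) / ry
    d <- sqrt(u^2 + v^2)
    th <- atan2(v, u)
    bound <- 1 + amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2])
    m <- d <= bound
    if (sum(m) < 16L) stop_param("generated mask smaller than 16 pixels")
    m
  })
}

#' @noRd
shift_mask <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Simulate a second reader's mask
#'
#' Morphologically dilates or erodes the true mask by one pixel (3 x 3
#' structuring element), the direction chosen at random; emulates
#' inter-reader delineation variability for ICC analyses. The border margin
#' is preserved and erosions that would fall below 16 pixels are discarded.
#'
#' @param mask logical matrix.
#' @param seed integer seed.
#' @return logical matrix.
#' @export
reader_variant_mask <- function(mask, seed) {
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  with_seed(seed, {
    dilate <- runif(1) < 0.5
    acc <- if (dilate) matrix(FALSE, nrow(mask), ncol(mask)) else matrix(TRUE, nrow(mask), ncol(mask))
    for (k in seq_len(nrow(offs))) {
      s <- shift_mask(mask, offs$dr[k], offs$dc[k])
      acc <- if (dilate) acc | s else acc & s
    }
    # keep masks off the border so every matrix direction is defined
    acc[c(1L, nrow(acc)), ] <- FALSE
    acc[, c(1L, ncol(acc))] <- FALSE
    if (sum(acc) < 16L) mask else acc
  })
}

#' Generate a synthetic cohort
#'
#' Lesion classes (malignant, benign) get one lesion per patient rendered as
#' a textured blob composited into a neutral background field, with a
#' per-image mask; tissue classes (fat, glandular) get whole-field texture
#' with a large rectangular mask covering the image interior. All images of
#' one lesion share a patient id; tissue patients have their own ids.
#'
#' @param spec a [cohort_spec()].
#' @param second_reader if `TRUE`, each sample carries a `reader2_mask`
#'   element (a perturbed delineation, see [reader_variant_mask()]).
#' @return list of [roi_sample()] objects.
#' @export
generate_cohort <- function(spec, second_reader = FALSE) {
  if (!inherits(spec, "cohort_spec")) stop_param("'spec' must be a cohort_spec")
  shp <- spec$image_shape
  background <- class_texture_params("fat", 128, 15, 2.0, 4.0)
  samples <- list()
  # deterministic per-image sub-seeds derived from the cohort seed
  ctr <- 0L
  next_seed <- function() {
    ctr <<- ctr + 1L
    as.integer((as.numeric(spec$seed) * 10007 + ctr * 7919) %% 2147483629)
  }
  for (cls in names(spec$class_params)) {
    p <- spec$class_params[[cls]]
    lesional <- cls %in% c("malignant", "benign")
    for (pat in seq_len(spec$n_patients_per_class)) {
      pid <- sprintf("%s_p%03d", cls, pat)
      n_img <- if (lesional) {
        choices <- seq(spec$images_per_lesion[1], spec$images_per_lesion[2])
        with_seed(next_seed(), choices[sample.int(length(choices), 1L)])
      } else {
        spec$n_images_per_tissue
      }
      for (img_i in seq_len(n_img)) {
        iid <- sprintf("%s_i%02d", pid, img_i)
        if (lesional) {
          bg <- generate_texture_field(background, shp, next_seed())
          fg <- generate_texture_field(p, shp, next_seed())
          mask <- generate_lesion_mask(shp, spec$lesion_radius_px, next_seed())
          img <- bg
          img[mask] <- fg[mask]
        } else {
          img <- generate_texture_field(p, shp, next_seed())
          mask <- matrix(FALSE, shp[1], shp[2])
          mask[3:(shp[1] - 2L), 3:(shp[2] - 2L)] <- TRUE
        }
        s <- roi_sample(img, mask, cls, pid, iid,
                        reader_id = if (second_reader) "reader1" else NULL)
        if (second_reader) s$reader2_mask <- reader_variant_mask(mask, next_seed())
        samples[[length(samples) + 1L]] <- s
      }
    }
  }
  samples
}
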