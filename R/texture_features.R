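# The 47-feature texture engine. Canonical order (see feature_names()):
#   hist  (4): histogram entropy, variance, skewness, excess kurtosis
#   cooc1 (4): GLCM contrast, correlation, energy, homogeneity at distance 1
#   cooc2 (4): the same four at distance 2
#   rlm_a (11): run-length features, counts summed over 4 directions
#   rlm_b (11): the same eleven, horizontal runs only
#   szm  (13): size-zone features, 8-connectivity
# Co-occurrence features are computed per direction (0/45/90/135 degrees,
# symmetric matrices) and averaged.

rlm_feature_names <- c("sre", "lre", "gln", "rln", "rp",
                       "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge")
szm_feature_names <- c("sze", "lze", "gln", "zsn", "zp",
                       "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
                       "glv", "zsv")

#' Canonical names of the 47 texture features
#'
#' @return character vector of length 47 in canonical order.
#' @export
feature_names <- function() {
  c(paste0("hist_", c("entropy", "variance", "skewness", "kurtosis")),
    paste0("cooc1_", c("contrast", "correlation", "energy", "homogeneity")),
    paste0("cooc2_", c("contrast", "correlation", "energy", "homogeneity")),
    paste0("rlm_a_", rlm_feature_names),
    paste0("rlm_b_", rlm_feature_names),
    paste0("szm_", szm_feature_names))
}

#' First-order histogram features
#'
#' Entropy is computed from an equal-width histogram of the normalized
#' grey values (`-sum p log2 p` over non-empty bins, in bits); variance,
#' skewness and excess kurtosis are the population central moments of the
#' values themselves (a normal sample has excess kurtosis ~ 0).
#'
#' @param norm a `normalization_result` from [normalize_roi()].
#' @param n_bins number of histogram bins for the entropy (default 64).
#' @return named numeric vector: `entropy`, `variance`, `skewness`,
#'   `kurtosis`.
#' @export
first_order_features <- function(norm, n_bins = 64L) {
  v <- norm$values
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) {
    stop_degenerate("constant ROI: histogram features undefined")
  }
  bin <- pmin(n_bins, floor((v - rng[1]) / diff(rng) * n_bins) + 1L)
  p <- tabulate(bin, n_bins) / length(v)
  p <- p[p > 0]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  c(entropy = -sum(p * log2(p)),
    variance = m2,
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3)
}

#' Haralick features of a co-occurrence matrix
#'
#' contrast = sum (i-j)^2 p(i,j); correlation = sum (i-mu_i)(j-mu_j) p / (s_i s_j);
#' energy = sum p^2 (angular second moment); homogeneity = sum p / (1 + |i-j|).
#' When a marginal standard deviation is zero the correlation is undefined;
#' by convention 0 is returned with a warning so feature vectors stay finite.
#'
#' @param g a `glcm` from [build_glcm()].
#' @return named numeric vector: `contrast`, `correlation`, `energy`,
#'   `homogeneity`.
#' @export
glcm_features <- function(g) {
  p <- g$matrix
  Ng <- nrow(p)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  pi_m <- rowSums(p)
  pj_m <- colSums(p)
  mu_i <- sum(seq_len(Ng) * pi_m)
  mu_j <- sum(seq_len(Ng) * pj_m)
  s_i <- sqrt(sum((seq_len(Ng) - mu_i)^2 * pi_m))
  s_j <- sqrt(sum((seq_len(Ng) - mu_j)^2 * pj_m))
  corr <- if (s_i * s_j < .Machine$double.eps) {
    warning("degenerate GLCM: marginal variance is zero, correlation set to 0")
    0
  } else {
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  }
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))))
}

#' Run-length features
#'
#' Standard run-length statistics: short/long-run emphasis (inverse/direct
#' squared run-length weights), grey-level and run-length non-uniformity,
#' run percentage, low/high grey-level run emphasis (inverse/direct squared
#' level weights) and the four joint emphases.
#'
#' @param r a `glrlm` from [build_glrlm()].
#' @return named numeric vector of the 11 run-length features.
#' @export
glrlm_features <- function(r) {
  cnt <- r$counts
  Nr <- r$n_runs
  i <- matrix(seq_len(nrow(cnt)), nrow(cnt), ncol(cnt))
  j <- matrix(seq_len(ncol(cnt)), nrow(cnt), ncol(cnt), byrow = TRUE)
  c(sre  = sum(cnt / j^2) / Nr,
    lre  = sum(cnt * j^2) / Nr,
    gln  = sum(rowSums(cnt)^2) / Nr,
    rln  = sum(colSums(cnt)^2) / Nr,
    rp   = Nr / (r$n_pixels * r$n_directions),
    lgre = sum(cnt / i^2) / Nr,
    hgre = sum(cnt * i^2) / Nr,
    srlge = sum(cnt / (i^2 * j^2)) / Nr,
    srhge = sum(cnt * i^2 / j^2) / Nr,
    lrlge = sum(cnt * j^2 / i^2) / Nr,
    lrhge = sum(cnt * i^2 * j^2) / Nr)
}

#' Size-zone features
#'
#' Size-zone analogues of the run-length statistics with zone size in place
#' of run length, plus grey-level variance (GLV) and zone-size variance
#' (ZSV): the variances of level and size under the zone probability
#' distribution p(i,j) = counts / n_zones.
#'
#' @param z a `glszm` from [build_glszm()].
#' @return named numeric vector of the 13 size-zone features.
#' @export
glszm_features <- function(z) {
  cnt <- z$counts
  Nz <- z$n_zones
  i <- matrix(seq_len(nrow(cnt)), nrow(cnt), ncol(cnt))
  j <- matrix(seq_len(ncol(cnt)), nrow(cnt), ncol(cnt), byrow = TRUE)
  p <- cnt / Nz
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  c(sze  = sum(cnt / j^2) / Nz,
    lze  = sum(cnt * j^2) / Nz,
    gln  = sum(rowSums(cnt)^2) / Nz,
    zsn  = sum(colSums(cnt)^2) / Nz,
    zp   = Nz / z$n_pixels,
    lgze = sum(cnt / i^2) / Nz,
    hgze = sum(cnt * i^2) / Nz,
    szlge = sum(cnt / (i^2 * j^2)) / Nz,
    szhge = sum(cnt * i^2 / j^2) / Nz,
    lzlge = sum(cnt * j^2 / i^2) / Nz,
    lzhge = sum(cnt * i^2 * j^2) / Nz,
    glv  = sum((i - mu_i)^2 * p),
    zsv  = sum((j - mu_j)^2 * p))
}

#' @noRd
mean_glcm_features <- function(q, distance) {
  f <- vapply(names(direction_offsets), function(d) {
    glcm_features(build_glcm(q, distance = distance, directions = d,
                             symmetric = TRUE))
  }, numeric(4))
  rowMeans(f)
}

#' Extract the 47-feature texture vector of one ROI
#'
#' Runs the full per-ROI pipeline: mu +/- 3 sigma normalization, linear
#' quantization to `Ng` grey levels, then histogram, co-occurrence
#' (distances 1 and 2, direction-averaged), run-length (direction-summed
#' and horizontal-only) and size-zone features, assembled in the canonical
#' order of [feature_names()].
#'
#' @param sample a [roi_sample()].
#' @param Ng number of grey levels (default 64).
#' @param n_bins histogram bins for the first-order entropy (default `Ng`).
#' @param mask_element which element of `sample` holds the mask; set to
#'   `"reader2_mask"` to extract a second reader's measurements.
#' @return named numeric vector of length 47, all finite.
#' @export
extract_features <- function(sample, Ng = 64L, n_bins = Ng,
                             mask_element = "mask") {
  if (mask_element != "mask") {
    if (is.null(sample[[mask_element]])) stop_param(paste("sample has no element", mask_element))
    sample$mask <- sample[[mask_element]]
  }
  norm <- normalize_roi(sample)
  q <- quantize(norm, Ng)
  fo <- first_order_features(norm, n_bins)
  cooc1 <- mean_glcm_features(q, 1L)
  cooc2 <- mean_glcm_features(q, 2L)
  rlm_a <- glrlm_features(build_glrlm(q, directions = c("0", "45", "90", "135")))
  rlm_b <- glrlm_features(build_glrlm(q, directions = "0"))
  szm <- glszm_features(build_glszm(q, connectivity = 8L))
  out <- c(fo, cooc1, cooc2, rlm_a, rlm_b, szm)
  names(out) <- feature_names()
  stopifnot(length(out) == 47L, all(is.finite(out)))
  out
}

#' Extract a feature table for a cohort
#'
#' @param samples list of [roi_sample()] objects.
#' @param Ng number of grey levels.
#' @param mask_element mask element to use (see [extract_features()]).
#' @return data frame: `image_id`, `patient_id`, `class`, `reader_id`, then
#'   the 47 canonical feature columns.
#' @export
extract_feature_table <- function(samples, Ng = 64L, mask_element = "mask") {
  feats <- t(vapply(samples, extract_features, numeric(47L),
                    Ng = Ng, mask_element = mask_element))
  meta <- data.frame(
    image_id = vapply(samples, `[[`, character(1), "image_id"),
    patient_id = vapply(samples, `[[`, character(1), "patient_id"),
    class = vapply(samples, `[[`, character(1), "class_label"),
    reader_id = vapply(samples, function(s)
      if (is.null(s$reader_id)) NA_character_ else s$reader_id, character(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}
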