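# First texture-analysis step: per-ROI grey-level normalization to the
# masked-pixel mean +/- three standard deviations, then linear quantization
# to Ng grey levels.

#' Normalize a masked ROI to the mean +/- three standard deviations
#'
#' Computes mu and sigma over the masked pixels only (sigma is the sample,
#' n - 1, standard deviation) and clips every masked value outside
#' \[mu - 3 sigma, mu + 3 sigma\] to the nearer bound. Values already inside
#' the range are unchanged and the masked-pixel count is preserved.
#'
#' @param sample a [roi_sample()] (or any list with `image` and `mask`).
#' @return a `normalization_result`: `mu`, `sigma` (pre-clip moments),
#'   `values` (clipped masked values, mask order), `levels` (matrix cropped
#'   to the mask bounding box, `NA` outside the mask), `mask` (cropped
#'   logical matrix), `n_pixels`.
#' @export
normalize_roi <- function(sample) {
  mask <- sample$mask
  if (sum(mask) < 16L) stop_param("mask must contain at least 16 pixels")
  v <- sample$image[mask]
  mu <- mean(v)
  sigma <- sd(v)
  if (!is.finite(sigma) || sigma < .Machine$double.eps) {
    stop_degenerate("constant ROI: sigma = 0, the mu +/- 3 sigma range is undefined")
  }
  lo <- mu - 3 * sigma
  hi <- mu + 3 * sigma
  clipped <- pmin(pmax(sample$image, lo), hi)
  # crop to the mask bounding box; cells outside the mask are NA and excluded
  # from all downstream statistics
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  cmask <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  cvals <- clipped[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  cvals[!cmask] <- NA_real_
  structure(list(mu = mu, sigma = sigma, values = cvals[cmask],
                 grid = cvals, mask = cmask, n_pixels = sum(cmask)),
            class = "normalization_result")
}

#' Quantize normalized ROI values to Ng grey levels
#'
#' Linear equal-width binning of the \[min, max\] range of the clipped
#' values into `Ng` bins mapped to 1..Ng: bins are upper-half-open, the
#' minimum maps to level 1 and the maximum is forced into level Ng. Cells
#' outside the mask are 0 and excluded from all statistics.
#'
#' @param norm a `normalization_result` from [normalize_roi()].
#' @param Ng number of grey levels (>= 2), default 64.
#' @return a `quantized_roi`: `levels` (integer matrix, 0 outside the mask),
#'   `mask`, `Ng`, `n_pixels`.
#' @export
quantize <- function(norm, Ng = 64L) {
  if (!is.numeric(Ng) || length(Ng) != 1L || Ng < 2) stop_param("'Ng' must be an integer >= 2")
  Ng <- as.integer(Ng)
  v <- norm$values
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) {
    stop_degenerate("zero grey-level range: cannot quantize a constant ROI")
  }
  lev_of <- function(x) pmin(Ng, as.integer(floor((x - rng[1]) / diff(rng) * Ng)) + 1L)
  levels <- matrix(0L, nrow(norm$grid), ncol(norm$grid))
  levels[norm$mask] <- lev_of(norm$grid[norm$mask])
  structure(list(levels = levels, mask = norm$mask, Ng = Ng,
                 n_pixels = norm$n_pixels),
            class = "quantized_roi")
}
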