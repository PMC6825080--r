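# Grey-level matrix builders. All operate on a quantized_roi whose `levels`
# matrix holds 1..Ng inside the mask and 0 outside; out-of-mask cells break
# pixel pairs, runs and zones.

# offsets are (dr, dc) on the matrix grid; angles follow image convention
# (0 deg = horizontal, 90 deg = vertical "up")
direction_offsets <- list(
  "0"   = c(0L,  1L),
  "45"  = c(-1L, 1L),
  "90"  = c(-1L, 0L),
  "135" = c(-1L, -1L)
)

#' @noRd
resolve_directions <- function(directions) {
  directions <- as.character(directions)
  unknown <- setdiff(directions, names(direction_offsets))
  if (length(unknown)) stop_param(paste("unknown direction(s):", paste(unknown, collapse = ", ")))
  direction_offsets[directions]
}

#' Build a grey-level co-occurrence matrix
#'
#' Counts pairs of masked pixels (p, p + distance * offset) with both ends
#' inside the mask, accumulated over the requested directions, optionally
#' symmetrized (pair counted in both orders), and normalized to sum 1.
#'
#' @param q a `quantized_roi` from [quantize()].
#' @param distance pixel offset distance (>= 1).
#' @param directions subset of `c("0", "45", "90", "135")` (degrees).
#' @param symmetric count each pair in both orders (default `TRUE`).
#' @return a `glcm`: `matrix` (Ng x Ng, sums to 1), `distance`,
#'   `directions`, `symmetric`, `n_pairs`.
#' @export
build_glcm <- function(q, distance = 1L, directions = c("0", "45", "90", "135"),
                       symmetric = TRUE) {
  if (distance < 1) stop_param("'distance' must be >= 1")
  offs <- resolve_directions(directions)
  L <- q$levels
  Ng <- q$Ng
  counts <- matrix(0, Ng, Ng)
  n <- nrow(L); p <- ncol(L)
  for (off in offs) {
    dr <- off[1] * distance; dc <- off[2] * distance
    if (max(1, 1 - dr) > min(n, n - dr) || max(1, 1 - dc) > min(p, p - dc)) next
    r1 <- max(1, 1 - dr):min(n, n - dr)
    c1 <- max(1, 1 - dc):min(p, p - dc)
    a <- L[r1, c1, drop = FALSE]
    b <- L[r1 + dr, c1 + dc, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    idx <- (a[ok] - 1L) * Ng + b[ok]
    counts <- counts + matrix(tabulate(idx, Ng * Ng), Ng, Ng, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0) stop_degenerate("no valid in-mask pixel pairs at this offset")
  structure(list(matrix = counts / tot, distance = as.integer(distance),
                 directions = as.character(directions), symmetric = symmetric,
                 n_pairs = tot),
            class = "glcm")
}

#' @noRd
mask_lines <- function(L, direction) {
  # returns a list of integer vectors: level sequences along collinear lines,
  # 0 marking out-of-mask breaks
  switch(direction,
    "0"   = split(L, row(L)),
    "90"  = split(L, col(L)),
    "45"  = split(L, row(L) + col(L)),   # anti-diagonals, column-major order
    "135" = split(L, row(L) - col(L)),   # main diagonals
    stop_param(paste("unknown direction:", direction))
  )
}

#' Build a grey-level run-length matrix
#'
#' Counts maximal runs of equal grey level along each direction, restricted
#' to in-mask collinear segments; multi-direction mode sums run counts over
#' directions.
#'
#' @param q a `quantized_roi`.
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return a `glrlm`: `counts` (Ng x Rmax), `n_runs`, `n_pixels`,
#'   `n_directions`.
#' @export
build_glrlm <- function(q, directions = "0") {
  directions <- as.character(directions)
  resolve_directions(directions)
  Ng <- q$Ng
  lv <- integer(0); ln <- integer(0)
  for (d in directions) {
    for (line in mask_lines(q$levels, d)) {
      r <- rle(as.integer(line))
      keep <- r$values > 0L
      lv <- c(lv, r$values[keep])
      ln <- c(ln, r$lengths[keep])
    }
  }
  if (!length(lv)) stop_degenerate("empty mask: no runs")
  rmax <- max(ln)
  counts <- matrix(tabulate((lv - 1L) * rmax + ln, Ng * rmax), Ng, rmax, byrow = TRUE)
  structure(list(counts = counts, n_runs = sum(counts), n_pixels = q$n_pixels,
                 n_directions = length(directions)),
            class = "glrlm")
}

#' Build a grey-level size-zone matrix
#'
#' Zones are connected components of equal-level masked pixels
#' (8-connectivity by default, following the original size-zone definition);
#' `counts[level, size]` is incremented once per zone. Zones partition the
#' masked pixels, so the size-weighted count total equals `n_pixels`.
#'
#' @param q a `quantized_roi`.
#' @param connectivity 4 or 8 (default 8).
#' @return a `glszm`: `counts` (Ng x Smax), `n_zones`, `n_pixels`.
#' @export
build_glszm <- function(q, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop_param("'connectivity' must be 4 or 8")
  L <- q$levels
  Ng <- q$Ng
  masked <- which(L > 0L)
  if (!length(masked)) stop_degenerate("empty mask: no zones")
  vid <- matrix(0L, nrow(L), ncol(L))
  vid[masked] <- seq_along(masked)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  n <- nrow(L); p <- ncol(L)
  from <- integer(0); to <- integer(0)
  for (off in offs) {
    dr <- off[1]; dc <- off[2]
    if (max(1, 1 - dr) > min(n, n - dr) || max(1, 1 - dc) > min(p, p - dc)) next
    r1 <- max(1, 1 - dr):min(n, n - dr)
    c1 <- max(1, 1 - dc):min(p, p - dc)
    a <- L[r1, c1, drop = FALSE]
    b <- L[r1 + dr, c1 + dc, drop = FALSE]
    ok <- a > 0L & b > 0L & a == b
    if (!any(ok)) next
    from <- c(from, vid[r1, c1, drop = FALSE][ok])
    to <- c(to, vid[r1 + dr, c1 + dc, drop = FALSE][ok])
  }
  g <- igraph::make_empty_graph(n = length(masked), directed = FALSE)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  comp <- igraph::components(g)
  sizes <- comp$csize
  zone_level <- L[masked][match(seq_len(comp$no), comp$membership)]
  smax <- max(sizes)
  counts <- matrix(tabulate((zone_level - 1L) * smax + sizes, Ng * smax),
                   Ng, smax, byrow = TRUE)
  structure(list(counts = counts, n_zones = comp$no, n_pixels = q$n_pixels),
            class = "glszm")
}
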