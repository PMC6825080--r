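# Brute-force oracles, written as plain loops independent of the package's
# vectorized implementations, plus small fixture builders.

oracle_offsets <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0), "135" = c(-1, -1))

# enumerate every in-mask pixel pair at the offset and count co-occurrences
oracle_glcm <- function(levels, Ng, distance, direction, symmetric = TRUE) {
  off <- oracle_offsets[[direction]] * distance
  counts <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (a > 0 && b > 0) counts[a, b] <- counts[a, b] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# walk every collinear line pixel by pixel and record maximal runs
oracle_runs <- function(levels, direction) {
  off <- oracle_offsets[[direction]]
  nr <- nrow(levels); nc <- ncol(levels)
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  runs <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!inb(r - off[1], c - off[2])) { # line start
        cr <- r; cc <- c
        cur_lev <- 0; cur_len <- 0
        while (inb(cr, cc)) {
          lv <- levels[cr, cc]
          if (lv > 0 && lv == cur_lev) {
            cur_len <- cur_len + 1
          } else {
            if (cur_lev > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
            cur_lev <- lv; cur_len <- if (lv > 0) 1 else 0
          }
          cr <- cr + off[1]; cc <- cc + off[2]
        }
        if (cur_lev > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
      }
    }
  }
  do.call(rbind, runs) # matrix: level, length
}

oracle_glrlm_counts <- function(levels, Ng, directions) {
  runs <- do.call(rbind, lapply(directions, function(d) oracle_runs(levels, d)))
  rmax <- max(runs[, 2])
  counts <- matrix(0, Ng, rmax)
  for (k in seq_len(nrow(runs))) {
    counts[runs[k, 1], runs[k, 2]] <- counts[runs[k, 1], runs[k, 2]] + 1
  }
  counts
}

# recursive-free flood fill over equal-level 8-neighbours
oracle_zones <- function(levels, connectivity = 8) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  neigh <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  zones <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (levels[r, c] > 0 && !seen[r, c]) {
        lv <- levels[r, c]
        stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          size <- size + 1
          for (k in seq_len(nrow(neigh))) {
            r2 <- p[1] + neigh[k, 1]; c2 <- p[2] + neigh[k, 2]
            if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
                !seen[r2, c2] && levels[r2, c2] == lv) {
              seen[r2, c2] <- TRUE
              stack[[length(stack) + 1]] <- c(r2, c2)
            }
          }
        }
        zones[[length(zones) + 1]] <- c(lv, size)
      }
    }
  }
  do.call(rbind, zones) # matrix: level, size
}

oracle_glszm_counts <- function(levels, Ng, connectivity = 8) {
  z <- oracle_zones(levels, connectivity)
  smax <- max(z[, 2])
  counts <- matrix(0, Ng, smax)
  for (k in seq_len(nrow(z))) counts[z[k, 1], z[k, 2]] <- counts[z[k, 1], z[k, 2]] + 1
  counts
}

# direct double-sum feature formulas over a counts/probability matrix
oracle_rlm_features <- function(counts, n_pixels, n_directions) {
  Nr <- sum(counts)
  s <- c(sre = 0, lre = 0, gln = 0, rln = 0, rp = 0, lgre = 0, hgre = 0,
         srlge = 0, srhge = 0, lrlge = 0, lrhge = 0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      v <- counts[i, j]
      s["sre"] <- s["sre"] + v / j^2
      s["lre"] <- s["lre"] + v * j^2
      s["lgre"] <- s["lgre"] + v / i^2
      s["hgre"] <- s["hgre"] + v * i^2
      s["srlge"] <- s["srlge"] + v / (i^2 * j^2)
      s["srhge"] <- s["srhge"] + v * i^2 / j^2
      s["lrlge"] <- s["lrlge"] + v * j^2 / i^2
      s["lrhge"] <- s["lrhge"] + v * i^2 * j^2
    }
  }
  for (i in seq_len(nrow(counts))) s["gln"] <- s["gln"] + sum(counts[i, ])^2
  for (j in seq_len(ncol(counts))) s["rln"] <- s["rln"] + sum(counts[, j])^2
  out <- s / Nr
  out["rp"] <- Nr / (n_pixels * n_directions)
  out
}

glcm_of_matrix <- function(m) {
  structure(list(matrix = m, distance = 1L, directions = "0",
                 symmetric = TRUE, n_pairs = 1), class = "glcm")
}

# zone-probability variances of level and size by double loops
oracle_szm_variances <- function(counts) {
  Nz <- sum(counts)
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    mu_i <- mu_i + i * counts[i, j] / Nz
    mu_j <- mu_j + j * counts[i, j] / Nz
  }
  glv <- 0; zsv <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    glv <- glv + (i - mu_i)^2 * counts[i, j] / Nz
    zsv <- zsv + (j - mu_j)^2 * counts[i, j] / Nz
  }
  c(glv = glv, zsv = zsv)
}

oracle_auc <- function(scores, y01) {
  sp <- scores[y01 == 1]; sn <- scores[y01 == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# empirical lag-1 autocorrelation by direct summation over horizontal pairs
oracle_lag1_autocorr <- function(img) {
  a <- img[, -ncol(img)]; b <- img[, -1]
  sum((a - mean(img)) * (b - mean(img))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# random small quantized ROI (levels 0 outside a random mask)
random_qroi <- function(seed, max_dim = 12, Ng = NULL) {
  set.seed(seed)
  nr <- sample(4:max_dim, 1); nc <- sample(4:max_dim, 1)
  if (is.null(Ng)) Ng <- sample(2:6, 1)
  mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
  while (sum(mask) < 5) mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
  levels <- matrix(0L, nr, nc)
  levels[mask] <- sample.int(Ng, sum(mask), replace = TRUE)
  structure(list(levels = levels, mask = mask, Ng = Ng, n_pixels = sum(mask)),
            class = "quantized_roi")
}

# a small well-formed roi_sample with textured content
fixture_sample <- function(seed = 1, n = 24, class_label = "benign",
                           patient_id = "p1", image_id = "i1") {
  set.seed(seed)
  img <- matrix(round(runif(n * n, 0, 255)), n, n)
  mask <- matrix(FALSE, n, n)
  mask[4:(n - 3), 4:(n - 3)] <- TRUE
  roi_sample(img, mask, class_label, patient_id, image_id)
}

# patient-grouped synthetic feature table (for ML-layer tests): n_pat
# patients per group, n_img images each, informative features shifted by
# `shift` between groups, the rest pure noise
synthetic_feature_table <- function(seed, n_pat = 10, n_img = 3,
                                    n_informative = 5, shift = 2,
                                    n_features = 47) {
  set.seed(seed)
  fn <- feature_names()[seq_len(n_features)]
  rows <- list()
  for (grp in c("neg", "pos")) {
    for (p in seq_len(n_pat)) {
      for (i in seq_len(n_img)) {
        x <- rnorm(n_features)
        if (grp == "pos") x[seq_len(n_informative)] <- x[seq_len(n_informative)] + shift
        row <- as.data.frame(as.list(stats::setNames(x, fn)))
        row$patient_id <- paste0(grp, "_p", p)
        row$image_id <- paste0(grp, "_p", p, "_i", i)
        row$label <- grp
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  df <- do.call(rbind, rows)
  df$label <- factor(df$label, levels = c("neg", "pos"))
  df
}
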