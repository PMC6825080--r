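# Evaluation layer: per-feature group statistics, ROC/AUC with DeLong
# confidence intervals, DeLong comparison of correlated ROC curves,
# confusion-matrix metrics, two-reader ICC(2,1) and the feature correlation
# matrix.

#' @noRd
as_binary01 <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[nlevels(labels)])
  else as.integer(labels == max(labels))
}

# Placement values: V10[i] = P(score_neg < s_i) + 0.5 P(score_neg = s_i)
# for each positive i, and symmetrically V01[j] for each negative j.
#' @noRd
placement_values <- function(scores, y01) {
  sp <- scores[y01 == 1]; sn <- scores[y01 == 0]
  v10 <- vapply(sp, function(s) mean(sn < s) + 0.5 * mean(sn == s), numeric(1))
  v01 <- vapply(sn, function(s) mean(sp > s) + 0.5 * mean(sp == s), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve and AUC with a DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative (ties counted with weight 1/2); the 95% CI uses
#' the DeLong placement-value variance, applied on the logit scale so the
#' bounds stay inside \[0, 1\] (degenerate AUCs of exactly 0 or 1 get a
#' clamped normal-scale interval).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (factor with the positive level last, or
#'   numeric 0/1).
#' @return a `roc_result`: `thresholds`, `sensitivity`, `fpr` (1 -
#'   specificity), `auc`, `se`, `ci95`, `n_pos`, `n_neg`.
#' @export
roc_with_ci <- function(scores, labels) {
  y <- as_binary01(labels)
  if (length(unique(y)) < 2L) stop_param("both classes must be present")
  pl <- placement_values(scores, y)
  m <- sum(y == 1); n <- sum(y == 0)
  v <- if (m > 1) var(pl$v10) / m else 0
  v <- v + if (n > 1) var(pl$v01) / n else 0
  se <- sqrt(v)
  auc <- pl$auc
  if (auc > 0 && auc < 1 && se > 0) {
    lse <- se / (auc * (1 - auc))
    lo <- plogis(qlogis(auc) - 1.96 * lse)
    hi <- plogis(qlogis(auc) + 1.96 * lse)
  } else {
    lo <- max(0, auc - 1.96 * se)
    hi <- min(1, auc + 1.96 * se)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[y == 0] >= t), numeric(1))
  structure(list(thresholds = th, sensitivity = sens, fpr = fpr,
                 auc = auc, se = se, ci95 = c(lo, hi),
                 n_pos = m, n_neg = n),
            class = "roc_result")
}

#' DeLong test comparing two correlated (or independent) AUCs
#'
#' Computes both AUCs from placement values; in paired mode (the default,
#' both score vectors over the same samples) the variance of the AUC
#' difference uses the placement-value covariance, and a two-sided normal
#' test is reported.
#'
#' @param scores_a,scores_b two score vectors.
#' @param labels binary labels shared by both (paired mode) or a list of
#'   two label vectors (unpaired).
#' @param paired logical, default `TRUE`.
#' @return a `delong_result`: `auc_a`, `auc_b`, `delta`, `var_delta`, `z`,
#'   `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, paired = TRUE) {
  if (paired) {
    y <- as_binary01(labels)
    if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
      stop_param("paired mode requires both score vectors over the same samples")
    }
    pa <- placement_values(scores_a, y)
    pb <- placement_values(scores_b, y)
    m <- sum(y == 1); n <- sum(y == 0)
    v <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  } else {
    ya <- as_binary01(labels[[1]]); yb <- as_binary01(labels[[2]])
    pa <- placement_values(scores_a, ya)
    pb <- placement_values(scores_b, yb)
    v <- var(pa$v10) / sum(ya == 1) + var(pa$v01) / sum(ya == 0) +
      var(pb$v10) / sum(yb == 1) + var(pb$v01) / sum(yb == 0)
  }
  delta <- pa$auc - pb$auc
  if (v < .Machine$double.eps) {
    if (abs(delta) < .Machine$double.eps) {
      z <- 0; p <- 1
    } else {
      stop_degenerate("degenerate DeLong variance with non-zero AUC difference")
    }
  } else {
    z <- delta / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 var_delta = v, z = z, p_value = p, paired = paired),
            class = "delong_result")
}

#' Two-reader intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement, from the
#' ANOVA mean squares of the subjects-by-readers table; the 95% CI follows
#' the standard F-based construction. The verbal category uses the
#' Landis-Koch bands: <= 0.40 poor/fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-1.0 almost perfect.
#'
#' @param values_reader1,values_reader2 paired measurements (n >= 3).
#' @return an `icc_result`: `icc`, `ci95`, `category`, mean squares.
#' @export
icc_two_reader <- function(values_reader1, values_reader2) {
  x <- cbind(values_reader1, values_reader2)
  n <- nrow(x); k <- 2L
  if (n < 3L) stop_param("need at least 3 paired measurements")
  if (var(as.vector(x)) < .Machine$double.eps) {
    stop_degenerate("zero total variance: ICC undefined")
  }
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- (msr - mse) / denom
  alpha <- 0.05
  if (mse < .Machine$double.eps && msc - mse < .Machine$double.eps / n) {
    ci <- c(1, 1)
  } else {
    r0 <- min(icc, 1 - 1e-12)
    a <- (k * r0) / (n * (1 - r0))
    b <- 1 + (k * r0 * (n - 1)) / (n * (1 - r0))
    vdf <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, vdf)
    fu <- stats::qf(1 - alpha / 2, vdf, n - 1)
    lo <- (n * (msr - fl * mse)) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- (n * (fu * msr - mse)) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(lo, hi)
  }
  category <- if (icc <= 0.40) "poor/fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "substantial"
  else "almost perfect"
  structure(list(icc = icc, ci95 = ci, category = category,
                 msr = msr, msc = msc, mse = mse, n = n),
            class = "icc_result")
}

#' Confusion-matrix metrics
#'
#' @param predicted,actual binary labels (factors with the positive level
#'   last, or comparable vectors).
#' @param positive optional positive-class value; defaults to the last
#'   factor level of `actual` (or its maximum).
#' @return a `confusion_report`: `counts` (TP, FN, FP, TN), `accuracy`,
#'   `sensitivity`, `specificity`, `n`.
#' @export
confusion_metrics <- function(predicted, actual, positive = NULL) {
  if (!length(actual)) stop_param("empty input")
  if (is.null(positive)) {
    positive <- if (is.factor(actual)) levels(actual)[nlevels(actual)] else max(actual)
  }
  p <- predicted == positive
  a <- actual == positive
  tp <- sum(p & a); fn <- sum(!p & a); fp <- sum(p & !a); tn <- sum(!p & !a)
  structure(list(counts = c(TP = tp, FN = fn, FP = fp, TN = tn),
                 accuracy = (tp + tn) / length(actual),
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 n = length(actual), positive = positive),
            class = "confusion_report")
}

#' Per-feature one-way ANOVA across the four tissue classes
#'
#' Classic one-way F test per feature with the fixed significance gate
#' p < 1e-4 (Bonferroni-style rule). Features that are constant both within
#' and between groups get p = 1 by convention.
#'
#' @param table feature table with a `class` column.
#' @param alpha significance gate (default 1e-4).
#' @return data frame: `feature`, `F`, `p`, `significant`.
#' @export
anova_per_feature <- function(table, alpha = 1e-4) {
  g <- factor(table$class)
  if (nlevels(g) < 2L || min(table(g)) < 2L) {
    stop_param("need >= 2 groups with >= 2 samples each")
  }
  cols <- feature_columns(table)
  res <- lapply(cols, function(cn) {
    v <- table[[cn]]
    gm <- tapply(v, g, mean)
    nn <- tapply(v, g, length)
    ssb <- sum(nn * (gm - mean(v))^2)
    ssw <- sum((v - gm[g])^2)
    df1 <- nlevels(g) - 1L
    df2 <- length(v) - nlevels(g)
    if (ssw < .Machine$double.eps) {
      if (ssb < .Machine$double.eps) {
        f <- 0; p <- 1
      } else {
        f <- Inf; p <- 0
      }
    } else {
      f <- (ssb / df1) / (ssw / df2)
      p <- pf(f, df1, df2, lower.tail = FALSE)
    }
    data.frame(feature = cn, F = f, p = p, significant = p < alpha)
  })
  do.call(rbind, res)
}

#' Per-feature unpaired two-sample t test
#'
#' Two-sided pooled-variance t test per feature. Zero pooled variance with
#' equal means gives t = 0, p = 1 by convention.
#'
#' @param table feature table.
#' @param group_col column defining the two groups (default `label`, falls
#'   back to `class`).
#' @return data frame: `feature`, `t`, `p`.
#' @export
ttest_per_feature <- function(table, group_col = if ("label" %in% colnames(table)) "label" else "class") {
  g <- factor(table[[group_col]])
  if (nlevels(g) != 2L || min(table(g)) < 2L) {
    stop_param("need exactly 2 groups with >= 2 samples each")
  }
  cols <- feature_columns(table)
  res <- lapply(cols, function(cn) {
    v1 <- table[[cn]][g == levels(g)[1]]
    v2 <- table[[cn]][g == levels(g)[2]]
    n1 <- length(v1); n2 <- length(v2)
    sp2 <- ((n1 - 1) * var(v1) + (n2 - 1) * var(v2)) / (n1 + n2 - 2)
    d <- mean(v1) - mean(v2)
    if (sp2 < .Machine$double.eps) {
      if (abs(d) < .Machine$double.eps) {
        tt <- 0; p <- 1
      } else {
        tt <- sign(d) * Inf; p <- 0
      }
    } else {
      tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * pt(-abs(tt), n1 + n2 - 2)
    }
    data.frame(feature = cn, t = tt, p = p)
  })
  do.call(rbind, res)
}

#' Pearson correlation matrix of the feature columns
#'
#' @param table feature table with >= 3 rows.
#' @return symmetric correlation matrix with unit diagonal; correlations of
#'   constant columns are 0 (flagged in the `constant` attribute, with a
#'   warning).
#' @export
feature_correlation_matrix <- function(table) {
  if (nrow(table) < 3L) stop_param("need at least 3 rows")
  cols <- feature_columns(table)
  x <- as.matrix(table[cols])
  sds <- apply(x, 2, sd)
  constant <- colnames(x)[sds < .Machine$double.eps]
  cm <- suppressWarnings(cor(x))
  if (length(constant)) {
    warning("constant feature column(s), correlations set to 0: ",
            paste(constant, collapse = ", "))
    cm[constant, ] <- 0
    cm[, constant] <- 0
  }
  diag(cm) <- 1
  attr(cm, "constant") <- constant
  cm
}
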