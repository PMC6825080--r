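# Machine-learning layer: standardization fitted on training data only,
# balanced binary sub-datasets, patient-disjoint stratified splitting,
# RBF-SVM grid search with patient-grouped fivefold CV, and recursive
# feature elimination with cross-validation.

default_c_grid <- function() c(1, 10, 100, 1000)
default_gamma_grid <- function() c(1e-5, 1e-4, 1e-3)

#' @noRd
feature_columns <- function(table) intersect(feature_names(), colnames(table))

#' Standardize feature columns (fit on training rows only)
#'
#' Removes the training mean and scales to unit population variance (the
#' StandardScaler convention, so a two-point column {1, 3} maps to
#' {-1, +1}); the same transform is applied to any other rows. Constant
#' training columns get scale 1 and are flagged.
#'
#' @param train training-partition data frame (metadata + feature columns).
#' @param other optional further rows (e.g. the validation partition).
#' @return list with `train`, `other` (transformed copies), `center`,
#'   `scale`, `constant` (names of flagged constant columns).
#' @export
standardize <- function(train, other = NULL) {
  if (is.null(train) || nrow(train) < 2L) stop_param("need at least 2 training rows")
  cols <- feature_columns(train)
  if (!length(cols)) stop_param("no feature columns found")
  center <- vapply(train[cols], mean, numeric(1))
  scl <- vapply(train[cols], function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  constant <- names(scl)[scl < .Machine$double.eps]
  scl[scl < .Machine$double.eps] <- 1
  apply_tf <- function(df) {
    for (cn in cols) df[[cn]] <- (df[[cn]] - center[[cn]]) / scl[[cn]]
    df
  }
  list(train = apply_tf(train),
       other = if (is.null(other)) NULL else apply_tf(other),
       center = center, scale = scl, constant = constant)
}

#' @noRd
patient_class_map <- function(table) {
  m <- unique(table[c("patient_id", "label")])
  if (anyDuplicated(m$patient_id)) stop_param("a patient appears with two labels")
  m
}

#' Build the two balanced binary sub-datasets
#'
#' Task (i) `lesion_vs_normal` pools malignant + benign against fat +
#' glandular; task (ii) `malignant_vs_benign` compares the two lesion
#' classes. The majority side is down-sampled by removing whole randomly
#' chosen patients (seeded) while a removal still brings the image counts
#' closer to balance, so classes balance as closely as whole patients allow.
#'
#' @param table feature table with `class` and `patient_id` columns.
#' @param seed integer seed for the down-sampling order.
#' @return named list of two `sub_dataset` objects (`data` with a binary
#'   `label` factor, positive level last; `task`; `balance` counts;
#'   `removed_patients`).
#' @export
make_subsets <- function(table, seed = 1L) {
  need <- c("malignant", "benign", "fat", "glandular")
  missing_cls <- setdiff(need, unique(table$class))
  if (length(missing_cls)) {
    stop_param(paste("class(es) absent from table:", paste(missing_cls, collapse = ", ")))
  }
  build <- function(task, pos_classes, neg_classes, pos_name, neg_name, sub_seed) {
    df <- table[table$class %in% c(pos_classes, neg_classes), , drop = FALSE]
    df$label <- factor(ifelse(df$class %in% pos_classes, pos_name, neg_name),
                       levels = c(neg_name, pos_name))
    removed <- character(0)
    with_seed(sub_seed, {
      repeat {
        n_by <- table(df$label)
        diff <- abs(n_by[1] - n_by[2])
        if (diff == 0) break
        maj <- names(n_by)[which.max(n_by)]
        cand <- unique(df$patient_id[df$label == maj])
        cand <- sample(cand)
        sizes <- vapply(cand, function(p) sum(df$patient_id == p), numeric(1))
        ok <- which(abs(diff - sizes) < diff)
        if (!length(ok)) break
        drop_p <- cand[ok[1]]
        removed <- c(removed, drop_p)
        df <- df[df$patient_id != drop_p, , drop = FALSE]
      }
    })
    structure(list(task = task, data = df, balance = table(df$label),
                   positive = pos_name, removed_patients = removed),
              class = "sub_dataset")
  }
  list(
    lesion_vs_normal = build("lesion_vs_normal", c("malignant", "benign"),
                             c("fat", "glandular"), "lesion", "normal", seed),
    malignant_vs_benign = build("malignant_vs_benign", "malignant", "benign",
                                "malignant", "benign", seed + 1L)
  )
}

#' Patient-disjoint stratified train/validation split
#'
#' Patients (not images) are shuffled and split per class, so no patient
#' contributes images to both partitions and each class is represented in
#' both.
#'
#' @param sub a `sub_dataset` from [make_subsets()] (or any data frame with
#'   `patient_id` and `label`).
#' @param ratio validation fraction in (0, 1), default 0.2.
#' @param seed integer seed.
#' @return a `split_plan`: `train` / `validation` data frames,
#'   `train_patients`, `validation_patients`, `ratio`, `seed`.
#' @export
split_train_validation <- function(sub, ratio = 0.2, seed = 1L) {
  df <- if (inherits(sub, "sub_dataset")) sub$data else sub
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop_param("'ratio' must be a validation fraction in (0, 1)")
  }
  pmap <- patient_class_map(df)
  val_patients <- character(0)
  with_seed(seed, {
    for (lab in levels(df$label)) {
      pats <- sample(pmap$patient_id[pmap$label == lab])
      if (length(pats) < 2L) stop_param("need at least 2 patients per class to stratify")
      n_val <- max(1L, min(length(pats) - 1L, round(length(pats) * ratio)))
      val_patients <- c(val_patients, pats[seq_len(n_val)])
    }
  })
  val <- df$patient_id %in% val_patients
  structure(list(train = df[!val, , drop = FALSE],
                 validation = df[val, , drop = FALSE],
                 train_patients = setdiff(pmap$patient_id, val_patients),
                 validation_patients = val_patients,
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

# Patient-grouped, class-stratified fold assignment (per row).
#' @noRd
make_group_folds <- function(table, folds, seed) {
  pmap <- patient_class_map(table)
  pf <- integer(nrow(pmap))
  names(pf) <- pmap$patient_id
  with_seed(seed, {
    for (lab in levels(table$label)) {
      pats <- sample(pmap$patient_id[pmap$label == lab])
      if (length(pats) < folds) {
        stop_param("too few patients per class for the requested number of folds")
      }
      pf[pats] <- rep_len(seq_len(folds), length(pats))
    }
  })
  fold <- pf[table$patient_id]
  for (k in seq_len(folds)) {
    if (length(unique(table$label[fold != k])) < 2L ||
        length(unique(table$label[fold == k])) < 2L) {
      stop_param("a cross-validation fold contains a single class")
    }
  }
  unname(fold)
}

#' @noRd
xy_of <- function(table, cols = feature_columns(table)) {
  list(x = as.matrix(table[cols]), y = table$label)
}

#' @noRd
fit_rbf_svm <- function(x, y, C, gamma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

#' Grid search for the RBF-SVM hyperparameters
#'
#' Mean accuracy over patient-grouped stratified k-fold cross-validation for
#' every (C, gamma) combination on a logarithmic grid (defaults: C in
#' 1..1000, gamma in 1e-5..1e-3). Ties on mean accuracy are broken towards
#' the smallest C, then the smallest gamma (the smoother model).
#'
#' @param train standardized training data frame (`label`, `patient_id`,
#'   feature columns).
#' @param c_grid,gamma_grid hyperparameter grids.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return a `grid_search_result`: `heatmap` (|C| x |gamma| mean CV
#'   accuracy), `per_fold` (array folds x |C| x |gamma|), `best`
#'   (list `C`, `gamma`, `cv_accuracy`).
#' @export
grid_search_svm <- function(train, c_grid = default_c_grid(),
                            gamma_grid = default_gamma_grid(),
                            folds = 5L, seed = 1L) {
  fold <- make_group_folds(train, folds, seed)
  d <- xy_of(train)
  per_fold <- array(NA_real_, c(folds, length(c_grid), length(gamma_grid)),
                    dimnames = list(NULL, paste0("C=", c_grid),
                                    paste0("gamma=", gamma_grid)))
  for (ci in seq_along(c_grid)) {
    for (gi in seq_along(gamma_grid)) {
      for (k in seq_len(folds)) {
        fit <- fit_rbf_svm(d$x[fold != k, , drop = FALSE], d$y[fold != k],
                           c_grid[ci], gamma_grid[gi])
        pred <- predict(fit, d$x[fold == k, , drop = FALSE])
        per_fold[k, ci, gi] <- mean(pred == d$y[fold == k])
      }
    }
  }
  heatmap <- apply(per_fold, c(2, 3), mean)
  best_idx <- which(heatmap == max(heatmap), arr.ind = TRUE)
  best_idx <- best_idx[order(best_idx[, 1], best_idx[, 2]), , drop = FALSE][1, ]
  structure(list(heatmap = heatmap, per_fold = per_fold,
                 best = list(C = c_grid[best_idx[1]],
                             gamma = gamma_grid[best_idx[2]],
                             cv_accuracy = heatmap[best_idx[1], best_idx[2]]),
                 c_grid = c_grid, gamma_grid = gamma_grid,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "grid_search_result")
}

#' Train the RBF-SVM and score a validation partition
#'
#' Fits the SVM on the training rows only, converts decision values to
#' probability scores with a logistic calibration fitted on the training
#' decision values, and thresholds scores at 0.5 for hard labels.
#'
#' @param train,validation standardized data frames.
#' @param C,gamma hyperparameters (e.g. from [grid_search_svm()]).
#' @return a `prediction_result`: `scores` (probability of the positive
#'   class), `predicted` (factor), `actual`, `train_scores`,
#'   `train_predicted`, `positive` (positive level name).
#' @export
train_and_predict <- function(train, validation, C, gamma) {
  cols <- feature_columns(train)
  miss <- setdiff(cols, colnames(validation))
  if (length(miss)) stop_param(paste("validation lacks feature column(s):",
                                     paste(miss, collapse = ", ")))
  d <- xy_of(train, cols)
  fit <- fit_rbf_svm(d$x, d$y, C, gamma)
  dv_train <- attr(predict(fit, d$x, decision.values = TRUE), "decision.values")[, 1]
  pos <- levels(d$y)[2]
  cal_df <- data.frame(y = as.integer(d$y == pos), dv = dv_train)
  cal <- suppressWarnings(glm(y ~ dv, family = binomial(), data = cal_df))
  score_of <- function(x) {
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1]
    as.numeric(predict(cal, newdata = data.frame(dv = dv), type = "response"))
  }
  vx <- as.matrix(validation[cols])
  scores <- score_of(vx)
  train_scores <- score_of(d$x)
  to_label <- function(s) factor(ifelse(s >= 0.5, pos, levels(d$y)[1]),
                                 levels = levels(d$y))
  structure(list(scores = scores, predicted = to_label(scores),
                 actual = validation$label,
                 train_scores = train_scores,
                 train_predicted = to_label(train_scores),
                 train_actual = d$y,
                 positive = pos, C = C, gamma = gamma),
            class = "prediction_result")
}

# |w| importance of a linear-kernel SVM (the RFE ranking estimator; the RBF
# kernel provides no per-feature weights).
#' @noRd
linear_svm_importance <- function(x, y, C = 1) {
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)[1, ]
  abs(w)
}

#' Recursive feature elimination with cross-validation
#'
#' Starting from all features, repeatedly drops the feature with the
#' smallest absolute weight in a linear-kernel SVM fitted on the training
#' rows, recording patient-grouped CV accuracy at every subset size. The
#' optimal size maximizes CV accuracy (ties towards the smaller set); the
#' features surviving to that size form the reduced feature set (RFS).
#'
#' @param train standardized training data frame.
#' @param folds CV folds (default 5).
#' @param seed integer seed (fold assignment).
#' @param cost linear-SVM cost used for ranking and scoring (default 1).
#' @return an `rfecv_result`: `ranking` (feature names, best first = kept
#'   longest), `rfs`, `optimal_size`, `cv_accuracy` (named by subset size,
#'   largest to 1).
#' @export
rfecv_select <- function(train, folds = 5L, seed = 1L, cost = 1) {
  cols <- feature_columns(train)
  if (length(cols) < 2L) stop_param("need at least 2 features")
  fold <- make_group_folds(train, folds, seed)
  d <- xy_of(train, cols)
  cv_acc_of <- function(active) {
    acc <- vapply(seq_len(folds), function(k) {
      fit <- e1071::svm(d$x[fold != k, active, drop = FALSE], d$y[fold != k],
                        type = "C-classification", kernel = "linear",
                        cost = cost, scale = FALSE)
      mean(predict(fit, d$x[fold == k, active, drop = FALSE]) == d$y[fold == k])
    }, numeric(1))
    mean(acc)
  }
  active <- cols
  elim_order <- character(0)
  sizes <- integer(0); accs <- numeric(0); sets <- list()
  while (length(active) >= 1L) {
    sizes <- c(sizes, length(active))
    accs <- c(accs, cv_acc_of(active))
    sets[[length(sets) + 1L]] <- active
    if (length(active) == 1L) break
    imp <- linear_svm_importance(d$x[, active, drop = FALSE], d$y, cost)
    drop_f <- active[which.min(imp)]
    elim_order <- c(elim_order, drop_f)
    active <- setdiff(active, drop_f)
  }
  names(accs) <- sizes
  best_i <- which(accs == max(accs))
  best_i <- best_i[length(best_i)]  # sizes are decreasing: last max = smallest set
  structure(list(ranking = c(rev(c(elim_order, active))),
                 rfs = sets[[best_i]],
                 optimal_size = sizes[best_i],
                 cv_accuracy = accs,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "rfecv_result")
}
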