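test_that("standardization fits on training rows only and hits exact moments", {
  tab <- synthetic_feature_table(seed = 1, n_pat = 5, n_img = 2)
  # two-point column check
  small <- tab[1:2, ]
  small$hist_entropy <- c(1, 3)
  std <- standardize(small)
  expect_equal(std$train$hist_entropy, c(-1, 1), tolerance = 1e-12)
  # validation row equal to the training mean maps to 0
  val <- small[1, ]
  val$hist_entropy <- 2
  std2 <- standardize(small, val)
  expect_equal(std2$other$hist_entropy, 0)
  # full random table: every training column mean ~ 0, variance ~ 1
  big <- synthetic_feature_table(seed = 2, n_pat = 9, n_img = 3)[1:50, ]
  stdb <- standardize(big)
  mo <- vapply(stdb$train[feature_names()], mean, numeric(1))
  vo <- vapply(stdb$train[feature_names()], function(x) mean((x - mean(x))^2), numeric(1))
  expect_true(all(abs(mo) < 1e-9))
  expect_true(all(abs(vo - 1) < 1e-9))
})

test_that("standardization ignores validation content (no information leak)", {
  tab <- synthetic_feature_table(seed = 3, n_pat = 6, n_img = 2)
  val <- synthetic_feature_table(seed = 4, n_pat = 2, n_img = 2)
  a <- standardize(tab, val)
  val_corrupt <- val
  val_corrupt[feature_names()] <- val_corrupt[feature_names()] * 100 + 7
  b <- standardize(tab, val_corrupt)
  expect_identical(a$center, b$center)
  expect_identical(a$scale, b$scale)
  expect_identical(a$train, b$train)
})

test_that("constant training columns are flagged with unit scale", {
  tab <- synthetic_feature_table(seed = 5, n_pat = 4, n_img = 2)
  tab$szm_zsv <- 3
  std <- standardize(tab)
  expect_identical(std$constant, "szm_zsv")
  expect_true(all(std$train$szm_zsv == 0))
})

mock_class_table <- function(seed, n_per_class, images_each = 2) {
  set.seed(seed)
  rows <- list()
  for (cls in c("malignant", "benign", "fat", "glandular")) {
    for (p in seq_len(n_per_class[[cls]])) {
      for (i in seq_len(images_each)) {
        row <- as.data.frame(as.list(stats::setNames(rnorm(47), feature_names())))
        row$class <- cls
        row$patient_id <- paste0(cls, "_p", p)
        row$image_id <- paste0(cls, "_p", p, "_i", i)
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

test_that("already balanced sub-datasets keep every patient", {
  tab <- mock_class_table(1, list(malignant = 5, benign = 5, fat = 5, glandular = 5))
  subs <- make_subsets(tab, seed = 1)
  expect_identical(as.integer(subs$lesion_vs_normal$balance), c(20L, 20L))
  expect_identical(as.integer(subs$malignant_vs_benign$balance), c(10L, 10L))
  expect_length(subs$lesion_vs_normal$removed_patients, 0)
  expect_identical(levels(subs$lesion_vs_normal$data$label), c("normal", "lesion"))
})

test_that("unbalanced cohorts are down-sampled by whole patients to near balance", {
  tab <- mock_class_table(2, list(malignant = 10, benign = 10, fat = 5, glandular = 5))
  subs <- make_subsets(tab, seed = 7)
  bal <- subs$lesion_vs_normal$balance
  expect_lte(abs(bal[[1]] - bal[[2]]), 2)  # images per patient = 2: within one patient
  # whole patients only: removed ids no longer present
  expect_false(any(subs$lesion_vs_normal$removed_patients %in%
                   subs$lesion_vs_normal$data$patient_id))
  # reproducible under the same seed
  subs2 <- make_subsets(tab, seed = 7)
  expect_identical(subs$lesion_vs_normal$data, subs2$lesion_vs_normal$data)
  expect_error(make_subsets(tab[tab$class != "fat", ]), class = "sonotex_parameter_error")
})

test_that("patient-wise stratified splitting is exact and leak-free", {
  tab <- mock_class_table(3, list(malignant = 10, benign = 10, fat = 10, glandular = 10))
  subs <- make_subsets(tab, seed = 1)
  sp <- split_train_validation(subs$malignant_vs_benign, ratio = 0.2, seed = 1)
  val_pat <- unique(sp$validation$patient_id)
  expect_identical(length(val_pat), 4L)  # 2 per class
  expect_identical(length(intersect(unique(sp$train$patient_id), val_pat)), 0L)
  expect_error(split_train_validation(subs$malignant_vs_benign, ratio = 0),
               class = "sonotex_parameter_error")
  for (s in 1:100) {
    spl <- split_train_validation(subs$lesion_vs_normal, 0.2, seed = s)
    expect_length(intersect(unique(spl$train$patient_id),
                            unique(spl$validation$patient_id)), 0)
    expect_setequal(unique(spl$validation$label), levels(spl$validation$label))
  }
})

test_that("grid search finds a perfect cell on separable data and covers the grid", {
  tab <- synthetic_feature_table(seed = 6, n_pat = 10, n_img = 2,
                                 n_informative = 5, shift = 8)
  std <- standardize(tab)
  gs <- grid_search_svm(std$train, folds = 5, seed = 1)
  expect_identical(dim(gs$heatmap), c(4L, 3L))
  expect_equal(max(gs$heatmap), 1.0)
  expect_equal(gs$best$cv_accuracy, 1.0)
  # tie-break: smallest C then smallest gamma among the maxima
  idx <- which(gs$heatmap == max(gs$heatmap), arr.ind = TRUE)
  expect_true(all(gs$best$C <= default_c_grid()[idx[, 1]]))
})

test_that("label-permuted data gives chance-level best CV accuracy", {
  accs <- vapply(1:20, function(s) {
    tab <- synthetic_feature_table(seed = 100 + s, n_pat = 8, n_img = 2,
                                   n_informative = 0, shift = 0,
                                   n_features = 10)
    std <- standardize(tab)
    grid_search_svm(std$train, folds = 5, seed = s)$best$cv_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("training-set predictions on separable data are perfect with [0,1] scores", {
  tab <- synthetic_feature_table(seed = 8, n_pat = 8, n_img = 2, shift = 8)
  std <- standardize(tab, tab)
  pred <- train_and_predict(std$train, std$other, C = 10, gamma = 1e-3)
  expect_equal(mean(pred$train_predicted == std$train$label), 1.0)
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
  expect_identical(as.character(pred$predicted),
                   ifelse(pred$scores >= 0.5, "pos", "neg"))
})

test_that("flipping the class encoding mirrors the probability scores", {
  tab <- synthetic_feature_table(seed = 9, n_pat = 8, n_img = 2, shift = 1.5)
  flip <- tab
  flip$label <- factor(as.character(tab$label), levels = c("pos", "neg"))
  std <- standardize(tab, tab)
  stdf <- standardize(flip, flip)
  a <- train_and_predict(std$train, std$other, C = 10, gamma = 1e-3)
  b <- train_and_predict(stdf$train, stdf$other, C = 10, gamma = 1e-3)
  expect_equal(a$scores, 1 - b$scores, tolerance = 1e-6)
  expect_error(train_and_predict(std$train, std$other[, 1:10], C = 1, gamma = 1e-3),
               class = "sonotex_parameter_error")
})

test_that("RFECV bookkeeping: full ranking and one accuracy per subset size", {
  tab <- synthetic_feature_table(seed = 10, n_pat = 8, n_img = 2,
                                 n_informative = 3, shift = 3, n_features = 12)
  std <- standardize(tab)
  rfe <- rfecv_select(std$train, folds = 5, seed = 2)
  expect_setequal(rfe$ranking, feature_names()[1:12])
  expect_length(rfe$cv_accuracy, 12)
  expect_identical(names(rfe$cv_accuracy), as.character(12:1))
  expect_true(all(rfe$rfs %in% feature_names()[1:12]))
  expect_identical(length(rfe$rfs), as.integer(rfe$optimal_size))
})

test_that("RFECV recovers informative features among noise", {
  hits <- vapply(1:3, function(s) {
    tab <- synthetic_feature_table(seed = 200 + s, n_pat = 12, n_img = 3,
                                   n_informative = 4, shift = 1, n_features = 20)
    std <- standardize(tab)
    rfe <- rfecv_select(std$train, folds = 5, seed = s)
    sum(feature_names()[1:4] %in% rfe$rfs)
  }, numeric(1))
  expect_true(all(hits >= 3))
})
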