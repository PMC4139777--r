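test_that("worked confusion-table cases evaluate exactly", {
  truth <- c(rep(1, 5), rep(0, 5))
  perfect <- compute_metrics(truth, truth)
  expect_equal(unlist(perfect[, c("SN", "SP", "ACC", "MCC")]), rep(1, 4),
               ignore_attr = TRUE)

  # TP = TN = FP = FN = 5: accuracy one half, no association
  y <- c(rep(1, 10), rep(0, 10))
  p <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5))
  m <- compute_metrics(y, p)
  expect_equal(m$ACC, 0.5)
  expect_equal(m$MCC, 0)

  # TP=3, FP=1, TN=4, FN=2 -> SN .6, SP .8, ACC .7, MCC 10/sqrt(600)
  y2 <- c(rep(1, 5), rep(0, 5))
  p2 <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m2 <- compute_metrics(y2, p2)
  expect_equal(unlist(m2[, c("TP", "FP", "TN", "FN")]), c(3L, 1L, 4L, 2L),
               ignore_attr = TRUE)
  expect_equal(m2$SN, 0.6)
  expect_equal(m2$SP, 0.8)
  expect_equal(m2$ACC, 0.7)
  expect_equal(m2$MCC, 10 / sqrt(600), tolerance = 1e-12)
  expect_false(m2$degenerate)
})

test_that("metrics match a brute-force pairwise count oracle", {
  withr::with_seed(18, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      y <- rbinom(n, 1, 0.5)
      p <- rbinom(n, 1, 0.5)
      m <- compute_metrics(y, p)
      tp <- 0; tn <- 0; fp <- 0; fn <- 0
      for (j in seq_len(n)) {
        if (y[j] == 1 && p[j] == 1) tp <- tp + 1
        if (y[j] == 0 && p[j] == 0) tn <- tn + 1
        if (y[j] == 0 && p[j] == 1) fp <- fp + 1
        if (y[j] == 1 && p[j] == 0) fn <- fn + 1
      }
      expect_equal(unlist(m[, c("TP", "TN", "FP", "FN")]),
                   c(tp, tn, fp, fn), ignore_attr = TRUE)
      expect_equal(m$TP + m$TN + m$FP + m$FN, n)
      # MCC is symmetric under a simultaneous class swap
      expect_equal(compute_metrics(1 - y, 1 - p)$MCC, m$MCC)
    }
  })
})

test_that("zero-denominator metrics flag instead of failing", {
  m <- compute_metrics(c(1, 1, 1), c(0, 0, 1))  # no true negatives possible
  expect_true(m$degenerate)
  expect_equal(m$SP, 0)
  expect_error(compute_metrics(integer(0), integer(0)),
               class = "snosite_validation_error")
  expect_error(compute_metrics(c(1, 0), c(1)),
               class = "snosite_validation_error")
})

test_that("stratified folds partition evenly and deterministically", {
  withr::with_seed(40, y <- rbinom(300, 1, 0.35))
  fold <- make_folds(y, n_folds = 10, seed = 99)
  expect_setequal(unique(fold), 1:10)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 2L)  # per-class rounding, two classes
  for (cl in 0:1) {
    cs <- table(fold[y == cl])
    expect_lte(max(cs) - min(cs), 1L)
  }
  expect_identical(make_folds(y, 10, seed = 99), fold)
  expect_false(identical(make_folds(y, 10, seed = 100), fold))
  expect_error(make_folds(rep(1, 20), 10), class = "snosite_validation_error")
  expect_error(make_folds(c(1, rep(0, 20)), 5), "training",
               class = "snosite_validation_error")
})

test_that("protein-level splitting keeps each protein's windows together", {
  withr::with_seed(55, {
    data <- random_feature_data(80, 4, seed = 56)
    data$protein_id <- sample(sprintf("prot%02d", 1:16), 80, replace = TRUE)
  })
  fold <- make_folds(data$label, n_folds = 4, seed = 3,
                     groups = data$protein_id)
  expect_equal(length(unique(fold)), 4L)
  per_prot <- tapply(fold, data$protein_id, function(x) length(unique(x)))
  expect_true(all(per_prot == 1L))

  cv <- cross_validate(data, k = 3, n_folds = 4, seed = 3, split = "protein")
  expect_equal(nrow(cv$fold_metrics), 4L)
  expect_error(cross_validate(data[, names(data) != "protein_id"],
                              split = "protein"),
               "protein_id", class = "snosite_validation_error")
})

test_that("trivially separable duplicated samples cross-validate to MCC 1", {
  base <- tibble::tibble(label = rep(c(1L, 0L), each = 2),
                         v1 = rep(c(10, -10), each = 2),
                         v2 = rep(c(5, -5), each = 2))
  data <- base[rep(1:4, 15), ]
  cv <- cross_validate(data, k = 3, n_folds = 10, seed = 1)
  expect_equal(cv$summary$MCC, 1)
  expect_equal(cv$summary$ACC, 1)
})

test_that("cross-validation is reproducible and aggregates both ways", {
  data <- generate_feature_dataset(
    synth_config(seed = 5, n_pos = 60, n_neg = 80, n_features = 12,
                 n_informative = 2))
  a <- cross_validate(data, k = 9, n_folds = 10, seed = 7)
  b <- cross_validate(data, k = 9, n_folds = 10, seed = 7)
  expect_identical(a$fold_metrics, b$fold_metrics)
  expect_identical(a$summary, b$summary)
  expect_equal(nrow(a$fold_metrics), 10L)
  expect_equal(sum(a$fold_metrics$TP + a$fold_metrics$TN +
                     a$fold_metrics$FP + a$fold_metrics$FN), nrow(data))

  pooled <- cross_validate(data, k = 9, n_folds = 10, seed = 7,
                           aggregate = "pooled")
  expect_identical(pooled$fold_metrics, a$fold_metrics)
  counts <- colSums(a$fold_metrics[, c("TP", "TN", "FP", "FN")])
  expect_equal(pooled$summary$ACC,
               (counts["TP"] + counts["TN"]) / sum(counts),
               ignore_attr = TRUE)

  expect_s3_class(tidy(a), "tbl_df")
  expect_equal(glance(a), a$summary)
})
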