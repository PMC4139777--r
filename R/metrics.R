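#' Confusion counts and classification metrics
#'
#' Computes the confusion counts and the four standard site-prediction
#' metrics: sensitivity `SN = TP / (TP + FN)`, specificity
#' `SP = TN / (TN + FP)`, accuracy `ACC = (TP + TN) / n` and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' MCC is the headline metric throughout the package because SNO datasets
#' are class-imbalanced. A metric with a zero denominator is reported as 0
#' and the row is flagged `degenerate`, so selection sweeps over poor
#' feature prefixes keep running.
#'
#' @param truth Binary true labels (0/1, logical, or 0/1 factor).
#' @param predicted Binary predicted labels, same length.
#' @return One-row tibble with columns `TP`, `TN`, `FP`, `FN`, `SN`, `SP`,
#'   `ACC`, `MCC`, `degenerate`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
compute_metrics <- function(truth, predicted) {
  if (length(truth) == 0) stop_invalid("cannot compute metrics on empty input")
  if (length(truth) != length(predicted)) {
    stop_invalid("truth and predicted differ in length (%d vs %d)",
                 length(truth), length(predicted))
  }
  y <- as_binary_label(truth, "truth")
  p <- as_binary_label(predicted, "predicted")
  counts <- c(TP = sum(y == 1 & p == 1), TN = sum(y == 0 & p == 0),
              FP = sum(y == 0 & p == 1), FN = sum(y == 1 & p == 0))
  metrics_from_counts(counts["TP"], counts["TN"], counts["FP"], counts["FN"])
}

# Vectorised metric computation from counts; used by compute_metrics and the
# IFS sweep (one element per prefix size).
metrics_from_counts <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  total <- tp + tn + fp + fn
  sn_den <- tp + fn
  sp_den <- tn + fp
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  degenerate <- sn_den == 0 | sp_den == 0 | mcc_den == 0
  tibble::tibble(
    TP = as.integer(tp), TN = as.integer(tn),
    FP = as.integer(fp), FN = as.integer(fn),
    SN = ifelse(sn_den > 0, tp / sn_den, 0),
    SP = ifelse(sp_den > 0, tn / sp_den, 0),
    ACC = (tp + tn) / total,
    MCC = ifelse(mcc_den > 0, (tp * tn - fp * fn) / mcc_den, 0),
    degenerate = degenerate)
}

#' Stratified cross-validation fold assignment
#'
#' Partitions samples into `n_folds` near-equal folds, stratified by class so
#' that imbalanced data cannot produce a training fold missing a class. The
#' assignment is fully determined by `seed`.
#'
#' @param labels Binary labels.
#' @param n_folds Number of folds, `>= 2`.
#' @param seed Integer seed.
#' @param groups Optional grouping vector (e.g. protein ids): all samples of
#'   a group are assigned to the same fold, guarding against information
#'   leaking between overlapping windows of one protein. Stratification is
#'   then by group rather than by class, so every training part is checked
#'   to still contain both classes.
#' @return Integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1, groups = NULL) {
  y <- as_binary_label(labels)
  n_folds <- as.integer(n_folds)
  if (is.na(n_folds) || n_folds < 2) stop_invalid("n_folds must be >= 2")
  if (length(unique(y)) < 2) {
    stop_invalid("both classes must be present; use stratified labelled data")
  }
  fold <- integer(length(y))
  if (is.null(groups)) {
    if (min(table(y)) < 2) {
      stop_invalid(
        "a class has fewer than 2 samples; every training fold needs both classes (stratification cannot help here)")
    }
    with_seed(seed, {
      for (cl in c(0L, 1L)) {
        ii <- sample(which(y == cl))
        fold[ii] <- rep_len(seq_len(n_folds), length(ii))
      }
    })
  } else {
    if (length(groups) != length(y)) {
      stop_invalid("groups must have one entry per sample")
    }
    with_seed(seed, {
      g <- sample(unique(as.character(groups)))
      gf <- stats::setNames(rep_len(seq_len(n_folds), length(g)), g)
      fold <- unname(gf[as.character(groups)])
    })
    for (f in seq_len(n_folds)) {
      if (length(unique(y[fold != f])) < 2) {
        stop_invalid(
          "training part of fold %d has a single class under the protein-level split; use more groups or the site-level split", f)
      }
    }
  }
  fold
}

#' Cross-validated KNN performance on a feature subset
#'
#' Runs seeded stratified k-fold cross-validation of the KNN classifier on
#' the given feature subset: each fold is held out in turn, the model is fit
#' on the remainder (feature standardisation statistics come from the
#' training part only) and the held-out fold is scored. The summary is the
#' mean of the per-fold metrics (`aggregate = "mean"`, the default), or
#' metrics of the pooled confusion counts (`aggregate = "pooled"`).
#'
#' @param data Feature tibble with a binary `label` column.
#' @param features Character vector of feature columns to use (default: all).
#' @param k Neighbour count. Default 9.
#' @param n_folds Number of folds. Default 10.
#' @param seed Integer seed for the fold assignment.
#' @param aggregate `"mean"` or `"pooled"`.
#' @param split `"site"` (default; stratified by class over individual
#'   windows) or `"protein"` (all windows of one protein share a fold; see
#'   [make_folds()] on the leakage trade-off). `"protein"` requires a
#'   `protein_id` column.
#' @return An object of class `cv_result`: list with `fold_metrics` (tibble,
#'   one row per fold), `summary` (one-row tibble), `folds` (assignment
#'   vector), and the call parameters. `tidy()` returns the fold metrics,
#'   `glance()` the summary.
#' @export
cross_validate <- function(data, features = NULL, k = 9, n_folds = 10,
                           seed = 1, aggregate = c("mean", "pooled"),
                           split = c("site", "protein")) {
  aggregate <- match.arg(aggregate)
  split <- match.arg(split)
  if (!"label" %in% names(data)) stop_invalid("data must have a 'label' column")
  y <- as_binary_label(data$label)
  if (is.null(features)) features <- feature_columns(data)
  if (inherits(features, "ranked_features")) features <- features$feature
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop_invalid("feature(s) not in data: %s", paste(missing, collapse = ", "))
  }
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  groups <- NULL
  if (split == "protein") {
    if (!"protein_id" %in% names(data)) {
      stop_invalid("split = \"protein\" needs a protein_id column")
    }
    groups <- data$protein_id
  }
  fold <- make_folds(y, n_folds = n_folds, seed = seed, groups = groups)
  per_fold <- purrr::map(seq_len(n_folds), function(f) {
    te <- fold == f
    Xtr <- standardize_fit(X[!te, , drop = FALSE])
    Xte <- standardize_apply(X[te, , drop = FALSE], Xtr)
    scores <- knn_scores(Xtr$x, Xte, y[!te], as.integer(k))
    pred <- as.integer(scores > 0.5)
    dplyr::mutate(compute_metrics(y[te], pred), fold = f, .before = 1)
  })
  fold_metrics <- dplyr::bind_rows(per_fold)
  summary <- if (aggregate == "mean") {
    dplyr::summarise(fold_metrics,
                     dplyr::across(c("SN", "SP", "ACC", "MCC"), mean),
                     degenerate = any(.data$degenerate))
  } else {
    with(fold_metrics,
         metrics_from_counts(sum(TP), sum(TN), sum(FP), sum(FN)))[
           , c("SN", "SP", "ACC", "MCC", "degenerate")]
  }
  structure(
    list(fold_metrics = fold_metrics, summary = summary, folds = fold,
         features = features, k = k, n_folds = n_folds, seed = seed,
         aggregate = aggregate, split = split),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV, k = %d, %d features (seed %s)\n",
              x$n_folds, x$k, length(x$features), format(x$seed)))
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' @rdname cross_validate
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) x$summary
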