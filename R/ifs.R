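#' Incremental feature selection over a ranked feature list
#'
#' Walks the ranked feature list from the top, adding one feature at a time;
#' for every prefix size the KNN classifier is evaluated by stratified
#' k-fold cross-validation and the fold-mean SN, SP, ACC and MCC are
#' recorded. One fold partition is drawn once (seeded) and reused across all
#' prefix sizes, so the curve reflects feature-set changes only. The optimal
#' subset is the prefix maximising mean MCC, the smallest size among ties.
#'
#' The sweep shares distance computations across nested prefixes (compiled
#' kernel), so evaluating all prefixes costs a single pass over the
#' features per fold.
#'
#' @param data Feature tibble with a binary `label` column.
#' @param ranked A `ranked_features` tibble from [rank_features()];
#'   `NULL` computes it from `data` with `bins`.
#' @param k Neighbour count for the classifier. Default 9.
#' @param n_folds Number of CV folds. Default 10.
#' @param seed Integer seed for the shared fold partition.
#' @param bins Histogram bins for [rank_features()] when `ranked` is `NULL`.
#' @param max_features Optional cap on the number of prefixes to evaluate
#'   (default: all ranked features).
#' @return An `ifs_result`: list with `table` (tibble of `n_features`, `SN`,
#'   `SP`, `ACC`, `MCC`), `optimal_size`, `optimal_features` (character),
#'   `ranked`, and the call parameters. `tidy()` returns the table,
#'   `glance()` a one-row summary, `autoplot()` the IFS curve.
#' @export
ifs_search <- function(data, ranked = NULL, k = 9, n_folds = 10, seed = 1,
                       bins = 20, max_features = NULL) {
  if (!"label" %in% names(data)) stop_invalid("data must have a 'label' column")
  y <- as_binary_label(data$label)
  if (is.null(ranked)) ranked <- rank_features(data, bins = bins)
  feats <- ranked$feature
  if (!is.null(max_features)) feats <- head(feats, max_features)
  p <- length(feats)
  X <- as.matrix(data[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  fold <- make_folds(y, n_folds = n_folds, seed = seed)
  acc <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- fold == f
    tr_fit <- standardize_fit(X[!te, , drop = FALSE])
    Xte <- standardize_apply(X[te, , drop = FALSE], tr_fit)
    scores <- knn_prefix_scores(tr_fit$x, Xte, y[!te], as.integer(k))
    pred <- scores > 0.5                       # n_te x p logical
    yte <- y[te]
    tp <- colSums(pred[yte == 1, , drop = FALSE])
    fn <- sum(yte == 1) - tp
    fp <- colSums(pred[yte == 0, , drop = FALSE])
    tn <- sum(yte == 0) - fp
    m <- metrics_from_counts(tp, tn, fp, fn)
    acc[[f]] <- as.matrix(m[, c("SN", "SP", "ACC", "MCC")])
  }
  mean_m <- Reduce(`+`, acc) / n_folds
  table <- tibble::tibble(
    n_features = seq_len(p),
    SN = mean_m[, "SN"], SP = mean_m[, "SP"],
    ACC = mean_m[, "ACC"], MCC = mean_m[, "MCC"])
  optimal_size <- which.max(table$MCC)          # first max = smallest tie
  structure(
    list(table = table,
         optimal_size = optimal_size,
         optimal_features = feats[seq_len(optimal_size)],
         ranked = ranked, k = k, n_folds = n_folds, seed = seed),
    class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf(
    "<ifs_result> %d prefixes evaluated (%d-fold CV, k = %d)\noptimal subset: %d features, mean MCC = %.4f\n",
    nrow(x$table), x$n_folds, x$k, x$optimal_size,
    x$table$MCC[x$optimal_size]))
  invisible(x)
}

#' @rdname ifs_search
#' @param x An `ifs_result`.
#' @param ... Unused.
#' @method tidy ifs_result
#' @export
tidy.ifs_result <- function(x, ...) x$table

#' @rdname ifs_search
#' @method glance ifs_result
#' @export
glance.ifs_result <- function(x, ...) {
  opt <- x$table[x$optimal_size, ]
  tibble::tibble(
    n_prefixes = nrow(x$table), optimal_size = x$optimal_size,
    SN = opt$SN, SP = opt$SP, ACC = opt$ACC, MCC = opt$MCC,
    k = x$k, n_folds = x$n_folds, seed = x$seed)
}

#' Plot the IFS curve
#'
#' Mean cross-validated MCC against the number of top-ranked features, with
#' the optimal prefix marked.
#'
#' @param object An `ifs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ifs_result
#' @export
autoplot.ifs_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$n_features, y = .data$MCC)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$optimal_size,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::annotate("point", x = object$optimal_size,
                      y = object$table$MCC[object$optimal_size],
                      colour = "firebrick") +
    ggplot2::labs(
      x = "number of top-ranked features",
      y = "mean cross-validated MCC",
      title = sprintf("IFS curve (optimum at %d features, MCC = %.3f)",
                      object$optimal_size,
                      object$table$MCC[object$optimal_size])) +
    ggplot2::theme_minimal()
}

#' @rdname ifs_search
#' @export
plot.ifs_result <- function(x, ...) print(autoplot.ifs_result(x, ...))
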