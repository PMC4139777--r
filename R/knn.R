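# Training-set standardisation: per-feature mean and sd, sd of a constant
# feature replaced by 1 so centering leaves it at exactly 0.
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  if (nrow(X) == 1) scale[] <- 1
  scale[!is.finite(scale) | scale == 0] <- 1
  list(x = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
}

#' Fit a k-nearest-neighbour site classifier
#'
#' Stores the standardised training matrix (per-feature z-scores; constant
#' features are centered and left at 0) together with the labels and `k`.
#' The default `k = 9` with Euclidean distance is the selected operating
#' configuration of the method.
#'
#' @param data Feature tibble with a binary `label` column.
#' @param features Character vector of feature columns to use (default: all
#'   feature columns), e.g. the optimal subset from [ifs_search()].
#' @param k Neighbour count, `1 <= k <= n`. Default 9.
#' @return A `knn_model` object.
#' @export
knn_fit <- function(data, features = NULL, k = 9) {
  if (!"label" %in% names(data)) stop_invalid("data must have a 'label' column")
  y <- as_binary_label(data$label)
  if (anyNA(y)) stop_invalid("training labels contain NA")
  if (is.null(features)) features <- feature_columns(data)
  if (inherits(features, "ranked_features")) features <- features$feature
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop_invalid("feature(s) not in data: %s", paste(missing, collapse = ", "))
  }
  if (length(features) < 1) stop_invalid("at least one feature is required")
  k <- as.integer(k)
  n <- nrow(data)
  if (is.na(k) || k < 1) stop_invalid("k must be a positive integer")
  if (k > n) stop_invalid("k = %d exceeds the number of training samples (%d)", k, n)
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  fit <- standardize_fit(X)
  structure(
    list(x = fit$x, y = y, k = k, features = features,
         center = fit$center, scale = fit$scale),
    class = "knn_model")
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("<knn_model> k = %d, %d training samples (%d positive), %d features\n",
              x$k, length(x$y), sum(x$y), length(x$features)))
  invisible(x)
}

#' Predict S-nitrosylation labels for new windows
#'
#' Applies the model's standardiser to the query features, finds the `k`
#' training samples with the smallest Euclidean distance (distance ties at
#' the k-th rank broken by lower training-row index, so predictions are
#' deterministic), and scores each query by the fraction of positive
#' neighbours. The label is positive when the score exceeds 0.5; an exact
#' 0.5 vote (only reachable with an even `k`) is resolved to negative — the
#' conservative call for a site predictor.
#'
#' @param object A `knn_model`.
#' @param newdata Tibble (or data frame) containing the model's feature
#'   columns; metadata columns are carried through to the output.
#' @param ... Unused.
#' @return `newdata`'s metadata columns plus `.pred_score` (fraction of
#'   positive neighbours, in `[0, 1]`) and `.pred_label` (integer 0/1).
#' @export
predict.knn_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    stop_invalid("newdata lacks model feature(s): %s (feature-name mismatch)",
                 paste(missing, collapse = ", "))
  }
  Q <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(Q) <- "double"
  Q <- standardize_apply(Q, object)
  scores <- knn_scores(object$x, Q, object$y, object$k)
  meta <- intersect(meta_cols(), names(newdata))
  dplyr::bind_cols(
    tibble::as_tibble(newdata[, meta, drop = FALSE]),
    tibble::tibble(.pred_score = as.vector(scores),
                   .pred_label = as.integer(scores > 0.5)))
}

#' @rdname knn_fit
#' @param x A `knn_model`.
#' @param ... Unused.
#' @return `tidy()`: one row per feature with its standardisation
#'   statistics; `glance()`: one row with `n`, `n_pos`, `n_features`, `k`.
#' @method tidy knn_model
#' @export
tidy.knn_model <- function(x, ...) {
  tibble::tibble(feature = x$features, center = unname(x$center),
                 scale = unname(x$scale))
}

#' @rdname knn_fit
#' @method glance knn_model
#' @export
glance.knn_model <- function(x, ...) {
  tibble::tibble(n = length(x$y), n_pos = sum(x$y),
                 n_features = length(x$features), k = x$k)
}

#' Persist a KNN model as a self-describing JSON archive
#'
#' The archive stores feature names, `k`, the standardiser and the raw
#' training data as plain JSON so a model can be reloaded later (or by other
#' tooling) and give byte-identical predictions.
#'
#' @param model A `knn_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_knn_model <- function(model, path) {
  payload <- list(
    format = "snosite_knn_model",
    version = 1L,
    k = model$k,
    features = model$features,
    center = unname(model$center),
    scale = unname(model$scale),
    labels = model$y,
    x = model$x)   # standardized training matrix, row-major list of rows
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_knn_model
#' @return `read_knn_model()`: the restored `knn_model`.
#' @export
read_knn_model <- function(path) {
  if (!file.exists(path)) stop_format("model file not found: %s", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "snosite_knn_model")) {
    stop_format("'%s' is not a snosite KNN model archive", path)
  }
  x <- matrix(as.numeric(payload$x), nrow = length(payload$labels),
              ncol = length(payload$features))
  colnames(x) <- payload$features
  structure(
    list(x = x, y = as.integer(payload$labels), k = as.integer(payload$k),
         features = payload$features,
         center = stats::setNames(as.numeric(payload$center), payload$features),
         scale = stats::setNames(as.numeric(payload$scale), payload$features)),
    class = "knn_model")
}
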