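#' Symmetric relative entropy between two class-conditional samples
#'
#' Scores how differently one feature is distributed in the positive and
#' negative class: the class-conditional densities P and Q are estimated by
#' histograms over shared equal-width bins spanning the pooled range, with an
#' additive pseudocount per bin, and the score is the symmetrised
#' Kullback-Leibler divergence `D(P||Q) + D(Q||P)` in nats. The pseudocount
#' keeps every bin probability positive, so the score is always finite; with
#' `pseudocount = 0`, empty-bin terms follow the usual conventions
#' (`0 log 0 = 0`; a bin with mass in one class only gives `Inf`).
#'
#' @param pos_values Numeric sample of the feature in the positive class.
#' @param neg_values Numeric sample in the negative class.
#' @param bins Number of histogram bins, `>= 2`. Default 20.
#' @param pseudocount Additive count per bin. Default 1.
#' @return Non-negative score in nats (0 for a feature constant across both
#'   classes or with identical histograms).
#' @export
#' @examples
#' symmetric_kl(rnorm(100, 1), rnorm(100, -1))
symmetric_kl <- function(pos_values, neg_values, bins = 20, pseudocount = 1) {
  if (length(pos_values) == 0 || length(neg_values) == 0) {
    stop_invalid("both class samples must be non-empty")
  }
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2) stop_invalid("bins must be an integer >= 2")
  pooled <- c(pos_values, neg_values)
  if (anyNA(pooled)) stop_invalid("feature values contain NA")
  lo <- min(pooled)
  hi <- max(pooled)
  if (lo == hi) return(0)
  edges <- seq(lo, hi, length.out = bins + 1L)
  cp <- bin_counts(pos_values, edges)
  cq <- bin_counts(neg_values, edges)
  p <- (cp + pseudocount) / sum(cp + pseudocount)
  q <- (cq + pseudocount) / sum(cq + pseudocount)
  kl_term(p, q) + kl_term(q, p)
}

# histogram counts over fixed edges; values == max fall in the last bin
bin_counts <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(b, nbins = length(edges) - 1L)
}

# sum p log(p/q) with 0 log 0 = 0
kl_term <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Rank features by symmetric relative entropy
#'
#' Computes the symmetric-KL score of every feature column against the
#' binary `label` column and returns the features sorted by decreasing score
#' (the ranked feature list fed to [ifs_search()]); ties are broken by
#' ascending original column index, making the ranking deterministic.
#'
#' @param data Feature tibble with a binary `label` column (see
#'   [encode_features()] or [generate_feature_dataset()]).
#' @param bins,pseudocount Passed to [symmetric_kl()].
#' @return A tibble of class `ranked_features` with columns `rank`,
#'   `feature`, `index` (original column position among the features) and
#'   `score`, sorted by `rank`.
#' @export
rank_features <- function(data, bins = 20, pseudocount = 1) {
  if (!"label" %in% names(data)) stop_invalid("data must have a 'label' column")
  y <- as_binary_label(data$label)
  if (length(unique(y)) < 2) {
    stop_invalid("both classes must be present to rank features")
  }
  feats <- feature_columns(data)
  if (length(feats) == 0) stop_invalid("data has no feature columns")
  scores <- vapply(feats, function(f) {
    v <- data[[f]]
    symmetric_kl(v[y == 1], v[y == 0], bins = bins, pseudocount = pseudocount)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  out <- tibble::tibble(
    rank = seq_along(feats),
    feature = feats[ord],
    index = ord,
    score = unname(scores[ord]))
  class(out) <- c("ranked_features", class(out))
  out
}
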