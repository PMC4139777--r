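# Shared fixture builders and independent oracles.

# A small, fully consistent synthetic protein set (sequences, profiles,
# structure, labels), optionally written to disk.
tiny_protein_set <- function(seed = 1, n = 6, dir = NULL) {
  generate_protein_set(
    synth_config(seed = seed, n_proteins = n,
                 protein_length_range = c(40, 90), cys_rate = 0.08),
    dir = dir)
}

# Hand-rolled window constructor for encoder edge cases; bypasses
# extract_windows on purpose.
make_window <- function(peptide, center_pos, xi, protein_id = "p1") {
  tibble::tibble(protein_id = protein_id, center_pos = as.integer(center_pos),
                 xi = as.integer(xi), peptide = peptide)
}

# Exhaustive KNN oracle: double-loop Euclidean distances on the model's
# standardised scale, sort, majority vote. Independent of the package's
# scoring kernel.
brute_knn_scores <- function(model, newdata) {
  st <- tidy(model)
  Q <- as.matrix(newdata[, st$feature, drop = FALSE])
  Q <- sweep(sweep(Q, 2, st$center), 2, st$scale, "/")
  X <- model$x
  y <- model$y
  k <- model$k
  vapply(seq_len(nrow(Q)), function(i) {
    d2 <- numeric(nrow(X))
    for (t in seq_len(nrow(X))) {
      d2[t] <- sum((Q[i, ] - X[t, ])^2)
    }
    ord <- order(d2, seq_along(d2))
    mean(y[ord[seq_len(k)]] == 1)
  }, numeric(1))
}

# Random labelled feature tibble (no structure), for KNN/metric fixtures.
random_feature_data <- function(n, d, seed) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, sprintf("v%02d", seq_len(d))))
    y <- rbinom(n, 1, 0.5)
    # guarantee both classes
    if (sum(y) == 0) y[1] <- 1L
    if (sum(y) == n) y[1] <- 0L
    dplyr::bind_cols(tibble::tibble(label = as.integer(y)),
                     tibble::as_tibble(X))
  })
}
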