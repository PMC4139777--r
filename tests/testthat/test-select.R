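test_that("symmetric KL matches direct summation on a closed-form case", {
  # two bins: P = (0.5, 0.5), Q = (0.9, 0.1), no pseudocount
  pos <- c(rep(0.5, 5), rep(1.5, 5))
  neg <- c(rep(0.5, 9), 1.5)
  expected <- 0.5 * log(25 / 9) + 0.9 * log(1.8) + 0.1 * log(0.2)
  expect_equal(symmetric_kl(pos, neg, bins = 2, pseudocount = 0), expected,
               tolerance = 1e-12)
  # symmetry under class swap
  expect_equal(symmetric_kl(neg, pos, bins = 2, pseudocount = 0), expected,
               tolerance = 1e-12)
})

test_that("symmetric KL is zero for identical histograms and constants", {
  x <- rnorm(50)
  expect_equal(symmetric_kl(x, x), 0)
  expect_equal(symmetric_kl(rep(2, 10), rep(2, 30)), 0)
  expect_gte(symmetric_kl(rnorm(100, 2), rnorm(100, -2)), 0)
})

test_that("non-negativity and class-swap invariance hold over random samples", {
  withr::with_seed(21, {
    for (i in 1:25) {
      a <- rnorm(40, sd = runif(1, 0.5, 2))
      b <- rnorm(60, mean = runif(1, -1, 1))
      s <- symmetric_kl(a, b)
      expect_gte(s, 0)
      expect_equal(symmetric_kl(b, a), s, tolerance = 1e-12)
    }
  })
})

test_that("a single separated feature ranks first; ties break by column index", {
  withr::with_seed(4, {
    n <- 120
    y <- rep(c(1L, 0L), each = n / 2)
    noise <- matrix(rnorm(n * 9), n, 9)
    signal <- rnorm(n) + ifelse(y == 1, 3, -3)
    data <- dplyr::bind_cols(
      tibble::tibble(label = y),
      tibble::as_tibble(matrix(c(noise[, 1:4], signal, noise[, 5:9]),
                               n, 10, dimnames = list(NULL, sprintf("g%02d", 1:10)))))
  })
  rk <- rank_features(data)
  expect_equal(rk$feature[1], "g05")
  expect_equal(rk$score, sort(rk$score, decreasing = TRUE))

  # duplicated columns score identically and keep original order
  dup <- dplyr::mutate(data, g11 = .data$g05, .after = "g10")
  rk2 <- rank_features(dup)
  pos5 <- which(rk2$feature == "g05")
  expect_equal(rk2$feature[pos5 + 1], "g11")
  expect_equal(rk2$score[pos5], rk2$score[pos5 + 1])

  # deterministic, and stable under row permutation
  expect_identical(rank_features(data), rk)
  withr::with_seed(9, perm <- sample(nrow(data)))
  expect_equal(rank_features(data[perm, ])$score, rk$score, tolerance = 1e-12)
  expect_equal(rank_features(data[perm, ])$feature, rk$feature)
})

test_that("label permutation drives scores toward the permutation null", {
  withr::with_seed(31, {
    data <- random_feature_data(150, 40, seed = 31)
    obs <- rank_features(data)$score
    null_max <- replicate(20, {
      shuffled <- data
      shuffled$label <- sample(shuffled$label)
      stats::quantile(rank_features(shuffled)$score, 0.95)
    })
  })
  # no feature stands far above the null 95th percentile band
  expect_lt(mean(obs > max(null_max)), 0.05)
})

test_that("ranking requires both classes", {
  data <- random_feature_data(30, 3, seed = 2)
  data$label <- 1L
  expect_error(rank_features(data), "both classes",
               class = "snosite_validation_error")
})

test_that("IFS prefers the informative prefix and ties pick the smaller subset", {
  withr::with_seed(14, {
    n <- 120
    y <- rep(c(1L, 0L), each = n / 2)
    informative <- sapply(1:3, function(i) rnorm(n) + ifelse(y == 1, 1.5, -1.5))
    noise <- matrix(rnorm(n * 27), n, 27)
    X <- cbind(informative, noise)
    colnames(X) <- sprintf("q%02d", 1:30)
    data <- dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
  })
  ifs <- ifs_search(data, seed = 5)
  expect_equal(nrow(ifs$table), 30L)
  expect_gte(ifs$table$MCC[3], ifs$table$MCC[30])

  # the full prefix equals a plain all-feature CV run on the same split
  cv <- cross_validate(data, features = ifs$ranked$feature, seed = 5)
  expect_equal(ifs$table$MCC[30], cv$summary$MCC, tolerance = 1e-12)
  expect_equal(ifs$table$ACC[30], cv$summary$ACC, tolerance = 1e-12)

  # a duplicated dominant feature yields identical metrics at prefixes 1 and
  # 2 (the duplicate only rescales distances); the smaller prefix wins
  sep <- ifelse(data$label == 1, 5, -5) + rnorm(nrow(data), sd = 0.1)
  dup <- dplyr::bind_cols(tibble::tibble(label = data$label, d1 = sep, d2 = sep))
  ifs2 <- ifs_search(dup, seed = 5)
  expect_equal(ifs2$table$MCC[1], ifs2$table$MCC[2])
  expect_equal(ifs2$optimal_size, 1L)
  expect_equal(ifs2$optimal_features, "d1")
})

test_that("IFS is reproducible and its optimum re-validates independently", {
  data <- generate_feature_dataset(
    synth_config(seed = 8, n_pos = 60, n_neg = 60, n_features = 25,
                 n_informative = 3))
  a <- ifs_search(data, seed = 3)
  b <- ifs_search(data, seed = 3)
  expect_identical(a$table, b$table)
  expect_identical(a$optimal_features, b$optimal_features)

  cv <- cross_validate(data, features = a$optimal_features, seed = 3)
  expect_equal(cv$summary$MCC, a$table$MCC[a$optimal_size], tolerance = 1e-12)
})
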