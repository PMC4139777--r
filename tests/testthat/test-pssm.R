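# A 3-position PSSM in the native PSI-BLAST column order with recognisable
# scores: position i has score (10 * i + j) for native column j.
write_native_pssm <- function(path, residues = "MCA", with_percentages = TRUE) {
  ord <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  res <- strsplit(residues, "")[[1]]
  header <- paste(" ", paste(ord, collapse = "  "))
  rows <- vapply(seq_along(res), function(i) {
    scores <- 10 * i + seq_len(20)
    line <- paste(i, res[i], paste(scores, collapse = " "))
    if (with_percentages) {
      line <- paste(line, paste(rep(0, 20), collapse = " "), "0.00 0.00")
    }
    line
  }, character(1))
  writeLines(c("", "Last position-specific scoring matrix computed", header,
               rows), path)
  ord
}

test_that("PSSM rows parse and columns re-map to the canonical order", {
  f <- withr::local_tempfile(fileext = ".pssm")
  ord <- write_native_pssm(f)
  prof <- parse_pssm(f, protein_id = "p1")
  expect_s3_class(prof, "pssm_profile")
  expect_equal(prof$residues, "MCA")
  expect_equal(dim(prof$scores), c(3L, 20L))
  expect_equal(colnames(prof$scores), amino_acids())
  # canonical column 'C' was native column 5, so row 1 holds 10 + 5
  expect_equal(prof$scores[1, "C"], 15L, ignore_attr = TRUE)
  expect_equal(prof$scores[3, "V"], 30L + 20L, ignore_attr = TRUE)
  expect_equal(unname(prof$scores[2, amino_acids()]),
               (20L + seq_len(20))[match(amino_acids(), ord)])
})

test_that("PSSM dialect tolerance and format errors", {
  f <- withr::local_tempfile(fileext = ".pssm")
  write_native_pssm(f, with_percentages = FALSE)
  expect_equal(nrow(parse_pssm(f)$scores), 3L)

  # truncated row: fewer than 22 fields, reported with its line number
  lines <- readLines(f)
  lines[length(lines)] <- "3 A 1 2 3"
  writeLines(lines, f)
  expect_error(parse_pssm(f), "line 6", class = "snosite_format_error")

  writeLines(c("no", "pssm", "here"), f)
  expect_error(parse_pssm(f), "header", class = "snosite_format_error")
})

test_that("generated PSSMs round-trip through the parser losslessly", {
  set <- tiny_protein_set(seed = 3, dir = withr::local_tempdir())
  for (id in names(set$profiles)) {
    back <- parse_pssm(file.path(set$dir, paste0(id, ".pssm")))
    expect_equal(back$protein_id, id)
    expect_equal(back$residues, set$profiles[[id]]$residues)
    expect_equal(unname(back$scores), unname(set$profiles[[id]]$scores))
  }
})

test_that("evolutionary encoding accumulates profile rows by source residue", {
  prof <- structure(
    list(protein_id = "p1", residues = "AAC",
         scores = matrix(seq_len(60), 3, 20,
                         dimnames = list(NULL, amino_acids()))),
    class = "pssm_profile")

  # fully padded window: empty sum
  w0 <- make_window("XXX", center_pos = 2, xi = 1)
  expect_equal(unlist(encode_evolutionary(w0, prof)), rep(0, 400),
               ignore_attr = TRUE)

  # exactly one covered residue: M row for that type equals the profile row
  w1 <- make_window("XAX", center_pos = 1, xi = 1)
  v1 <- encode_evolutionary(w1, prof)
  expect_equal(unlist(v1[, paste0("evo_A", amino_acids())]),
               prof$scores[1, ], ignore_attr = TRUE)
  expect_true(all(unlist(v1[, !grepl("^evo_A", names(v1))]) == 0))

  # 'A','A','C': row A = sum of the two A rows, row C = the C row,
  # checked against a position-by-position brute-force accumulation
  w2 <- make_window("AAC", center_pos = 2, xi = 1)
  v2 <- encode_evolutionary(w2, prof)
  brute <- matrix(0, 20, 20, dimnames = list(amino_acids(), amino_acids()))
  for (p in 1:3) {
    type <- substring(prof$residues, p, p)
    brute[type, ] <- brute[type, ] + prof$scores[p, ]
  }
  expect_equal(unlist(v2), as.vector(t(brute)), ignore_attr = TRUE)
  expect_equal(unlist(v2[, paste0("evo_A", amino_acids())]),
               prof$scores[1, ] + prof$scores[2, ], ignore_attr = TRUE)
})

test_that("encoding is linear over positions and invariant to same-type swaps", {
  set.seed(11)
  seq <- paste(sample(amino_acids(), 30, replace = TRUE), collapse = "")
  seq <- paste0(substr(seq, 1, 14), "C", substr(seq, 16, 30))
  prof <- structure(
    list(protein_id = "p1", residues = seq,
         scores = matrix(sample(-10:10, 30 * 20, TRUE), 30, 20,
                         dimnames = list(NULL, amino_acids()))),
    class = "pssm_profile")
  w <- extract_windows(tibble::tibble(protein_id = "p1", sequence = seq),
                       xi = 10)
  w <- w[w$center_pos == 15, ]
  full <- unlist(encode_evolutionary(w, prof))
  expect_length(full, 400)

  # sum of single-position encodings
  letters <- strsplit(w$peptide, "")[[1]]
  acc <- rep(0, 400)
  for (off in which(letters != "X")) {
    pep <- strrep("X", 21)
    substr(pep, off, off) <- letters[off]
    one <- make_window(pep, center_pos = w$center_pos, xi = 10)
    acc <- acc + unlist(encode_evolutionary(one, prof))
  }
  expect_equal(full, acc)
})

test_that("residue-column disagreement with the peptide is surfaced as a warning", {
  prof <- structure(
    list(protein_id = "p1", residues = "GGG",
         scores = matrix(0L, 3, 20, dimnames = list(NULL, amino_acids()))),
    class = "pssm_profile")
  w <- make_window("AAC", center_pos = 2, xi = 1)
  expect_warning(encode_evolutionary(w, prof), "disagrees")
})

test_that("windows beyond the profile length are a hard error", {
  prof <- structure(
    list(protein_id = "p1", residues = "AC",
         scores = matrix(0L, 2, 20, dimnames = list(NULL, amino_acids()))),
    class = "pssm_profile")
  w <- make_window("ACA", center_pos = 2, xi = 1)
  expect_error(encode_evolutionary(w, prof), "length mismatch",
               class = "snosite_validation_error")
})
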