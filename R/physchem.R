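#' Load a 49 x 20 physicochemical property table
#'
#' The encoder averages 49 per-residue physical, chemical, energetic and
#' conformational property values over each window. The bundled default
#' (`physchem_properties_synthetic.csv`) is a synthetic stand-in for the
#' published 49-property fold-rate collection: it contains seven standard
#' published scales (Kyte-Doolittle hydropathy, residue mass, Zamyatnin
#' volume, Grantham polarity, isoelectric point, Chou-Fasman helix and sheet
#' propensity) plus 42 deterministic synthetic scales. Any valid 49 x 20
#' table can be substituted; the encoder contract depends only on the shape.
#'
#' @param path Path to a CSV with a `property` name column and 20 amino-acid
#'   columns headed by one-letter codes (any order; re-mapped), 49 rows.
#'   `NULL` (default) loads the bundled table.
#' @return Tibble with column `property` plus the 20 amino-acid columns in
#'   canonical order.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physchem_properties_synthetic.csv",
                        package = "snosite")
  }
  if (!file.exists(path)) stop_format("property table not found: %s", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"property" %in% names(tab)) {
    names(tab)[1] <- "property"
  }
  aa_cols <- setdiff(names(tab), "property")
  if (!setequal(aa_cols, amino_acids()) || length(aa_cols) != 20) {
    stop_format(
      "property table must have exactly the 20 standard amino-acid columns; found: %s",
      paste(aa_cols, collapse = ", "))
  }
  if (nrow(tab) != 49) {
    stop_format("property table must have 49 rows (one per property); found %d",
                nrow(tab))
  }
  if (anyNA(tab)) stop_format("property table contains missing values")
  if (anyDuplicated(tab$property)) {
    stop_format("property table has duplicated property names")
  }
  dplyr::select(tab, "property", dplyr::all_of(amino_acids()))
}

#' Encode windows as 49 averaged physicochemical features
#'
#' For each property, the property value is summed over the window's non-X
#' residues and divided by the non-X residue count, i.e. a per-window mean of
#' per-residue values. X padding is excluded from numerator and denominator
#' so truncated windows are not biased toward zero; a fully padded window
#' encodes to zeros.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param table Property table from [load_property_table()]; `NULL` loads the
#'   bundled default.
#' @return Tibble with 49 numeric columns named `pc_<property>`, one row per
#'   window.
#' @export
encode_physchem <- function(windows, table = NULL) {
  if (is.null(table)) table <- load_property_table()
  vals <- as.matrix(table[, amino_acids()])      # 49 x 20
  rownames(vals) <- table$property
  counts <- t(vapply(windows$peptide, function(p) {
    tabulate(factor(strsplit(p, "")[[1]], levels = amino_acids()), nbins = 20)
  }, integer(20), USE.NAMES = FALSE))
  if (nrow(windows) == 0) counts <- matrix(0L, 0, 20)
  n_res <- rowSums(counts)
  feats <- counts %*% t(vals)                    # n x 49
  feats <- sweep(feats, 1, pmax(n_res, 1), "/")
  feats[n_res == 0, ] <- 0
  colnames(feats) <- paste0("pc_", table$property)
  tibble::as_tibble(feats)
}
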