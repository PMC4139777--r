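#' Pipeline: encode labelled sites into a feature matrix
#'
#' Orchestrates the encoding stage over on-disk inputs: reads the FASTA,
#' one PSSM and one secondary-structure file per protein (matched by FASTA
#' record id), and the site-label TSV; extracts labelled windows and encodes
#' them with all three feature sets. Proteins named in the label file but
#' missing a PSSM or ss2 file are a hard error in strict mode (the default
#' for evaluation workflows) or skipped with a warning otherwise.
#'
#' @param fasta Path to the protein FASTA.
#' @param pssm_dir Directory of `<protein_id>.pssm` files.
#' @param ss_dir Directory of `<protein_id>.ss2` files.
#' @param labels Path to the site-label TSV (see [read_site_labels()]).
#' @param properties Optional property-table CSV path.
#' @param xi Half-window size. Default 10.
#' @param strict Error (rather than skip with a warning) on proteins missing
#'   a profile or structure file. Default `TRUE`.
#' @param out Optional path: write the matrix as TSV.
#' @return The labelled feature tibble (invisible when `out` is given).
#' @export
pipeline_encode <- function(fasta, pssm_dir, ss_dir, labels,
                            properties = NULL, xi = 10, strict = TRUE,
                            out = NULL) {
  proteins <- read_fasta(fasta)
  sites <- read_site_labels(labels, proteins)
  if (nrow(sites) == 0) {
    warn("site-label file is empty; the feature matrix has no rows")
    proteins <- proteins[0, ]
  } else {
    proteins <- proteins[proteins$protein_id %in% sites$protein_id, ]
  }
  profiles <- read_pssm_dir(pssm_dir)
  ss <- read_ss_dir(ss_dir)
  have <- proteins$protein_id %in% names(profiles) &
    proteins$protein_id %in% ss$protein_id
  if (any(!have)) {
    msg <- sprintf("no PSSM and/or ss2 file for protein(s): %s (searched %s, %s)",
                   paste(proteins$protein_id[!have], collapse = ", "),
                   pssm_dir, ss_dir)
    if (strict) stop_invalid("%s", msg)
    warn(paste0(msg, "; skipping"))
    proteins <- proteins[have, ]
    sites <- sites[sites$protein_id %in% proteins$protein_id, ]
  }
  windows <- extract_windows(proteins, xi = xi, sites = sites)
  windows <- windows[!is.na(windows$label), , drop = FALSE]
  tab <- if (is.null(properties)) NULL else load_property_table(properties)
  mat <- encode_features(windows, profiles, ss, tab)
  if (!is.null(out)) {
    readr::write_tsv(mat, out, progress = FALSE)
    return(invisible(mat))
  }
  mat
}

#' Pipeline: rank features and search the optimal prefix subset
#'
#' Runs [rank_features()] and [ifs_search()] on an encoded feature matrix
#' and, when `out_dir` is given, writes `ranked_features.tsv` (the feature
#' list with its coefficient scores in descending order), `ifs_table.tsv`
#' and `optimal_features.txt`.
#'
#' @param data Feature tibble, or path to a TSV written by
#'   [pipeline_encode()].
#' @param bins Histogram bins for the symmetric-KL scores. Default 20.
#' @param k,n_folds,seed Classifier and CV settings (defaults 9, 10, 1).
#' @param max_features Optional cap on evaluated prefixes.
#' @param out_dir Optional output directory.
#' @return List with `ranked` and `ifs` (invisible when `out_dir` is given).
#' @export
pipeline_select <- function(data, bins = 20, k = 9, n_folds = 10, seed = 1,
                            max_features = NULL, out_dir = NULL) {
  if (is.character(data)) {
    data <- readr::read_tsv(data, show_col_types = FALSE, progress = FALSE)
  }
  ranked <- rank_features(data, bins = bins)
  ifs <- ifs_search(data, ranked = ranked, k = k, n_folds = n_folds,
                    seed = seed, max_features = max_features)
  res <- list(ranked = ranked, ifs = ifs)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(ranked, file.path(out_dir, "ranked_features.tsv"),
                     progress = FALSE)
    readr::write_tsv(ifs$table, file.path(out_dir, "ifs_table.tsv"),
                     progress = FALSE)
    writeLines(ifs$optimal_features,
               file.path(out_dir, "optimal_features.txt"))
    return(invisible(res))
  }
  res
}

#' Pipeline: train and persist a KNN model
#'
#' @param data Feature tibble or TSV path.
#' @param features Feature subset (character vector, path to a one-name-per-
#'   line file such as `optimal_features.txt`, or `NULL` for all).
#' @param k Neighbour count. Default 9.
#' @param out Path for the model JSON archive.
#' @return The fitted `knn_model` (invisibly when `out` is given).
#' @export
pipeline_train <- function(data, features = NULL, k = 9, out = NULL) {
  if (is.character(data)) {
    data <- readr::read_tsv(data, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(features) && length(features) == 1 &&
      file.exists(features)) {
    features <- readLines(features)
  }
  model <- knn_fit(data, features = features, k = k)
  if (!is.null(out)) {
    write_knn_model(model, out)
    return(invisible(model))
  }
  model
}

#' Pipeline: score every candidate cysteine of new proteins
#'
#' Extracts all cysteine windows from the FASTA (no labels needed), encodes
#' them, and scores them with a persisted model. Prediction is lenient about
#' proteins missing profile/structure files by default: they are skipped
#' with a warning.
#'
#' @param model A `knn_model` or path to a model JSON archive.
#' @param fasta,pssm_dir,ss_dir,properties,xi As in [pipeline_encode()].
#' @param strict Error on proteins missing inputs. Default `FALSE`.
#' @param out Optional TSV output path.
#' @return Tibble with `protein_id`, `center_pos`, `peptide`, `.pred_score`,
#'   `.pred_label` per candidate cysteine.
#' @export
pipeline_predict <- function(model, fasta, pssm_dir, ss_dir,
                             properties = NULL, xi = 10, strict = FALSE,
                             out = NULL) {
  if (is.character(model)) model <- read_knn_model(model)
  proteins <- read_fasta(fasta)
  profiles <- read_pssm_dir(pssm_dir)
  ss <- read_ss_dir(ss_dir)
  have <- proteins$protein_id %in% names(profiles) &
    proteins$protein_id %in% ss$protein_id
  if (any(!have)) {
    msg <- sprintf("no PSSM and/or ss2 file for protein(s): %s",
                   paste(proteins$protein_id[!have], collapse = ", "))
    if (strict) stop_invalid("%s", msg)
    warn(paste0(msg, "; skipping"))
    proteins <- proteins[have, ]
  }
  windows <- extract_windows(proteins, xi = xi)
  tab <- if (is.null(properties)) NULL else load_property_table(properties)
  mat <- encode_features(windows, profiles, ss, tab)
  preds <- predict(model, mat)
  preds <- dplyr::select(preds, "protein_id", "center_pos", "peptide",
                         ".pred_score", ".pred_label")
  if (!is.null(out)) {
    readr::write_tsv(preds, out, progress = FALSE)
    return(invisible(preds))
  }
  preds
}

#' Pipeline: evaluate a model or feature subset by cross-validation
#'
#' @param data Labelled feature tibble or TSV path.
#' @param features Feature subset (vector, file path, or `NULL` for all).
#' @param k,n_folds,seed CV settings.
#' @param out Optional path: write per-fold and mean metrics as JSON.
#' @return A `cv_result` (invisible when `out` is given).
#' @export
pipeline_evaluate <- function(data, features = NULL, k = 9, n_folds = 10,
                              seed = 1, out = NULL) {
  if (is.character(data)) {
    data <- readr::read_tsv(data, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(features) && length(features) == 1 &&
      file.exists(features)) {
    features <- readLines(features)
  }
  cv <- cross_validate(data, features = features, k = k, n_folds = n_folds,
                       seed = seed)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(folds = cv$fold_metrics, mean = cv$summary),
      out, digits = NA, auto_unbox = TRUE, dataframe = "rows")
    return(invisible(cv))
  }
  cv
}
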