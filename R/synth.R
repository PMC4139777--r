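#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs of the two generators ([generate_protein_set()] and
#' [generate_feature_dataset()]). Defaults mirror the operating conditions
#' of the method: class sizes 731 positive / 810 negative (the size of a
#' typical curated SNO training set), 458 features of which 5 are
#' informative, class separation 3, 21-residue windows upstream.
#'
#' @param seed Integer seed; generation is fully determined by it.
#' @param n_proteins Number of proteins for the sequence-level generator.
#' @param protein_length_range Integer `(min, max)` protein length.
#' @param cys_rate Per-residue probability of a cysteine (at least one is
#'   forced per protein).
#' @param pssm_score_range Integer `(lo, hi)` range of generated log-odds
#'   scores. Default `c(-10, 10)`.
#' @param ss_run_length_mean Mean length of secondary-structure runs.
#' @param n_features Total feature count for the feature-level generator.
#' @param n_informative Number of informative features.
#' @param effect_size Euclidean separation between the class mean vectors in
#'   within-class standard-deviation units; the separation is split evenly
#'   over the informative features (each gets
#'   `effect_size / sqrt(n_informative)`), so overall problem difficulty
#'   does not change with `n_informative`.
#' @param n_pos,n_neg Class sizes for the feature-level generator.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_proteins = 30,
                         protein_length_range = c(60, 200),
                         cys_rate = 0.05, pssm_score_range = c(-10, 10),
                         ss_run_length_mean = 5, n_features = 458,
                         n_informative = 5, effect_size = 3,
                         n_pos = 731, n_neg = 810) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              protein_length_range = as.integer(protein_length_range),
              cys_rate = cys_rate,
              pssm_score_range = as.integer(pssm_score_range),
              ss_run_length_mean = ss_run_length_mean,
              n_features = as.integer(n_features),
              n_informative = as.integer(n_informative),
              effect_size = effect_size,
              n_pos = as.integer(n_pos), n_neg = as.integer(n_neg))
  stopifnot(cfg$n_proteins > 0, length(cfg$protein_length_range) == 2,
            cfg$protein_length_range[1] >= 1,
            cfg$protein_length_range[2] >= cfg$protein_length_range[1],
            cfg$cys_rate > 0, cfg$cys_rate < 1,
            cfg$pssm_score_range[1] <= cfg$pssm_score_range[2],
            cfg$ss_run_length_mean > 0, cfg$n_features >= 1,
            cfg$n_informative >= 0, cfg$n_informative <= cfg$n_features,
            cfg$effect_size >= 0, cfg$n_pos > 0, cfg$n_neg > 0)
  structure(cfg, class = "synth_config")
}

#' Generate a mutually consistent synthetic protein fixture set
#'
#' Produces random proteins (with at least one cysteine each), a matching
#' integer PSSM-like profile and a secondary-structure string per protein,
#' and random 0/1 site labels over all cysteines. When `dir` is given, the
#' set is written as `proteins.fasta`, one `<id>.pssm` and `<id>.ss2` per
#' protein, and `sites.tsv`, all satisfying the package parsers' format
#' contracts. Generation is byte-deterministic under `cfg$seed`.
#'
#' These fixtures emulate the input *formats* only: residues, profile scores
#' and structure runs are independent draws, with none of the sequence
#' motifs, conservation structure or class signal of real SNO data.
#'
#' @param cfg A [synth_config()].
#' @param dir Optional output directory (created if missing).
#' @return List with `proteins` (tibble), `profiles` (named list of
#'   `pssm_profile`), `ss` (tibble `protein_id`, `ss`), `sites` (tibble),
#'   and `dir`.
#' @export
generate_protein_set <- function(cfg = synth_config(), dir = NULL) {
  aa <- amino_acids()
  aa_no_c <- setdiff(aa, "C")
  with_seed(cfg$seed, {
    ids <- sprintf("synthP%03d", seq_len(cfg$n_proteins))
    proteins <- purrr::map(seq_len(cfg$n_proteins), function(i) {
      L <- resample(seq(cfg$protein_length_range[1],
                        cfg$protein_length_range[2]), 1)
      res <- ifelse(runif(L) < cfg$cys_rate, "C",
                    sample(aa_no_c, L, replace = TRUE))
      if (!any(res == "C")) res[sample(L, 1)] <- "C"
      paste(res, collapse = "")
    })
    proteins <- tibble::tibble(protein_id = ids,
                               sequence = unlist(proteins),
                               length = nchar(unlist(proteins)))
    profiles <- purrr::map2(proteins$protein_id, proteins$sequence,
      function(id, seq) {
        L <- nchar(seq)
        m <- matrix(resample(seq(cfg$pssm_score_range[1],
                                 cfg$pssm_score_range[2]),
                             L * 20, replace = TRUE), L, 20)
        colnames(m) <- aa
        structure(list(protein_id = id, residues = seq, scores = m),
                  class = "pssm_profile")
      })
    names(profiles) <- proteins$protein_id
    ss <- tibble::tibble(
      protein_id = proteins$protein_id,
      ss = vapply(proteins$length, function(L) {
        states <- character(0)
        prev <- ""
        while (sum(nchar(states)) < L) {
          st <- sample(setdiff(c("H", "E", "C"), prev), 1)
          len <- 1 + rpois(1, max(cfg$ss_run_length_mean - 1, 0))
          states <- c(states, strrep(st, len))
          prev <- st
        }
        substr(paste(states, collapse = ""), 1, L)
      }, character(1)))
    windows <- extract_windows(proteins, xi = 10)
    sites <- tibble::tibble(
      protein_id = windows$protein_id,
      position = windows$center_pos,
      label = rbinom(nrow(windows), 1, 0.5))
  })
  out <- list(proteins = proteins, profiles = profiles, ss = ss,
              sites = sites, dir = dir)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(proteins, file.path(dir, "proteins.fasta"))
    purrr::walk(profiles, function(p) {
      write_pssm(p, file.path(dir, paste0(p$protein_id, ".pssm")))
    })
    for (i in seq_len(nrow(ss))) {
      write_ss2(ss$ss[i], proteins$sequence[i],
                file.path(dir, paste0(ss$protein_id[i], ".ss2")))
    }
    utils::write.table(sites, file.path(dir, "sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Generate a two-class synthetic feature dataset
#'
#' Draws `n_pos + n_neg` samples over `n_features` standard-normal features;
#' `n_informative` randomly chosen features carry a class-mean shift of
#' `±effect_size / (2 * sqrt(n_informative))`, so the Euclidean separation
#' between the class mean vectors is `effect_size` within-class standard
#' deviations regardless of how many features carry it. The remaining
#' features are identically distributed in both classes. With
#' `effect_size = 0` the construction is an exact label-permutation null.
#'
#' @param cfg A [synth_config()].
#' @return Feature tibble with a `label` column and features `f001`,
#'   `f002`, ...; the informative feature names are in
#'   `attr(, "informative")`.
#' @export
generate_feature_dataset <- function(cfg = synth_config()) {
  p <- cfg$n_features
  n <- cfg$n_pos + cfg$n_neg
  fnames <- sprintf("f%03d", seq_len(p))
  with_seed(cfg$seed, {
    y <- c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, fnames))
    info <- integer(0)
    if (cfg$n_informative > 0) {
      info <- sort(sample(p, cfg$n_informative))
      shift <- cfg$effect_size / (2 * sqrt(cfg$n_informative))
      X[y == 1L, info] <- X[y == 1L, info] + shift
      X[y == 0L, info] <- X[y == 0L, info] - shift
    }
  })
  out <- dplyr::bind_cols(tibble::tibble(label = y), tibble::as_tibble(X))
  attr(out, "informative") <- fnames[info]
  attr(out, "seed") <- cfg$seed
  out
}
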