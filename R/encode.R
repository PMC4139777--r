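#' Encode windows with all three feature sets
#'
#' Binds the window metadata to the 400 evolutionary-conservation features,
#' the 9 secondary-structure segment features and the 49 physicochemical
#' features, giving the full 458-dimensional representation used by the
#' ranking, selection and classification stages.
#'
#' @param windows Window tibble from [extract_windows()] (with a `label`
#'   column when sites were joined).
#' @param profiles Named list of `pssm_profile` objects (see
#'   [read_pssm_dir()]).
#' @param ss Secondary-structure tibble (`protein_id`, `ss`; see
#'   [read_ss_dir()]).
#' @param properties Property table, `NULL` for the bundled default.
#' @return A feature tibble: metadata columns (`protein_id`, `center_pos`,
#'   `xi`, `peptide`, optionally `label`) followed by 458 named feature
#'   columns.
#' @export
encode_features <- function(windows, profiles, ss, properties = NULL) {
  dplyr::bind_cols(
    windows,
    encode_evolutionary(windows, profiles),
    encode_secondary(windows, ss),
    encode_physchem(windows, properties))
}
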