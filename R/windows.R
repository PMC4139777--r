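#' Extract cysteine-centered peptide windows
#'
#' Each cysteine in each protein yields one window of `2 * xi + 1` residues
#' centered on the cysteine; positions falling outside the protein are padded
#' with the dummy residue `X`. Coordinates are 1-based on the protein, the
#' convention of experimental site databases.
#'
#' @param proteins A tibble as returned by [read_fasta()] (columns
#'   `protein_id`, `sequence`), or a single sequence string.
#' @param xi Half-window size in residues (window length `2 * xi + 1`).
#'   Default 10, giving 21-mer windows.
#' @param sites Optional site-label tibble as returned by
#'   [read_site_labels()]; when given, a `label` column (integer 0/1, `NA`
#'   for unlabelled cysteines) is joined onto the windows.
#' @return A tibble with columns `protein_id`, `center_pos`, `xi`, `peptide`
#'   (and `label` when `sites` is supplied), one row per cysteine, in
#'   increasing `center_pos` within each protein.
#' @export
#' @examples
#' extract_windows(tibble::tibble(protein_id = "p1", sequence = "MCA"), xi = 3)
extract_windows <- function(proteins, xi = 10, sites = NULL) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(protein_id = "query", sequence = proteins)
  }
  xi <- as.integer(xi)
  if (is.na(xi) || xi < 1) stop_invalid("xi must be a positive integer")
  rows <- purrr::pmap(list(proteins$protein_id, proteins$sequence),
    function(id, seq) {
      pos <- as.integer(gregexpr("C", seq, fixed = TRUE)[[1]])
      if (length(pos) == 1 && pos[1] == -1L) return(NULL)
      pad <- strrep("X", xi)
      padded <- paste0(pad, seq, pad)
      tibble::tibble(
        protein_id = id,
        center_pos = pos,
        xi = xi,
        peptide = substring(padded, pos, pos + 2L * xi)
      )
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(protein_id = character(), center_pos = integer(),
                          xi = integer(), peptide = character())
  }
  if (!is.null(sites)) {
    validate_sites(sites, proteins)
    out <- dplyr::left_join(
      out,
      dplyr::select(sites, "protein_id", center_pos = "position", "label"),
      by = c("protein_id", "center_pos"))
  }
  out
}

#' Read a site-label table
#'
#' Reads a headerless three-column TSV of labelled cysteine sites:
#' `protein_id<TAB>position<TAB>label`, position 1-based, label 1 for an
#' experimentally verified S-nitrosylation site (SNO) and 0 for a verified
#' non-site. When `proteins` is supplied every position is checked to point
#' at a cysteine; a mismatch is an error (silent skipping would hide
#' label/sequence version mismatches).
#'
#' @param path Path to the TSV file.
#' @param proteins Optional protein tibble from [read_fasta()] used to
#'   validate ids and residues.
#' @return A tibble with columns `protein_id`, `position` (integer), `label`
#'   (integer 0/1). An empty file yields an empty tibble.
#' @export
read_site_labels <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop_format("site-label file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0) {
    sites <- tibble::tibble(protein_id = character(), position = integer(),
                            label = integer())
    return(sites)
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    stop_format("site-label file '%s': line %d has %d fields, expected 3",
                path, which(nf != 3)[1], nf[nf != 3][1])
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  if (any(is.na(pos) | pos < 1)) {
    stop_format("site-label file '%s': line %d has a non-positive-integer position",
                path, which(is.na(pos) | pos < 1)[1])
  }
  sites <- tibble::tibble(
    protein_id = vapply(parts, `[`, character(1), 1),
    position = pos,
    label = as_binary_label(vapply(parts, `[`, character(1), 3),
                            "site label"))
  dup <- duplicated(sites[, c("protein_id", "position")])
  if (any(dup)) {
    stop_invalid("duplicate site rows: %s",
                 paste(sites$protein_id[dup], sites$position[dup],
                       sep = ":", collapse = ", "))
  }
  if (!is.null(proteins)) validate_sites(sites, proteins)
  sites
}

# Check that every labelled position points at a 'C' in a known protein.
validate_sites <- function(sites, proteins) {
  unknown <- setdiff(sites$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    stop_invalid("site labels name unknown protein(s): %s",
                 paste(unknown, collapse = ", "))
  }
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  res <- substring(seqs[sites$protein_id], sites$position, sites$position)
  bad <- which(res != "C")
  if (length(bad) > 0) {
    stop_invalid(
      "labelled position(s) do not fall on a cysteine: %s",
      paste(sprintf("%s:%d (residue '%s')", sites$protein_id[bad],
                    sites$position[bad], res[bad]), collapse = ", "))
  }
  invisible(sites)
}
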