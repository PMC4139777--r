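#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard amino-acid
#' letters. With `strict = TRUE` (default) any other letter is a format
#' error naming the offending record; with `strict = FALSE` unknown letters
#' are mapped to the dummy residue `X`.
#'
#' @param path Path to a FASTA file (`>` headers, possibly multi-line
#'   sequences). The record id is the first whitespace-delimited token of the
#'   header.
#' @param strict Reject non-standard residue letters? Default `TRUE`.
#' @return A tibble with columns `protein_id`, `sequence`, `length`, in file
#'   order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 example", "MKVC", ">p2", "CCAGG"), fa)
#' read_fasta(fa)
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_format("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_format("malformed FASTA '%s': %s", path,
                                    conditionMessage(e))
  )
  if (length(set) == 0) stop_format("FASTA '%s' contains no records", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(set))
  for (i in seq_along(ids)) {
    if (is.na(ids[i]) || !nzchar(ids[i])) {
      stop_format("record %d of '%s' has an empty header", i, path)
    }
    if (!nzchar(seqs[i])) {
      stop_format("record '%s' has an empty sequence", ids[i])
    }
  }
  seqs <- gsub("[[:space:]]", "", seqs)
  bad <- gsub(paste0("[", paste(amino_acids(), collapse = ""), "]"), "", seqs)
  if (any(nzchar(bad))) {
    if (strict) {
      off <- ids[nzchar(bad)][1]
      stop_format(
        "record '%s' contains non-standard residue letter(s): %s (use strict = FALSE to map them to X)",
        off, paste(unique(strsplit(bad[nzchar(bad)][1], "")[[1]]), collapse = ", "))
    }
    pattern <- paste0("[^", paste(amino_acids(), collapse = ""), "]")
    seqs <- gsub(pattern, "X", seqs)
  }
  tibble::tibble(protein_id = unname(ids),
                 sequence = unname(seqs),
                 length = unname(nchar(seqs)))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @param width Line width for wrapping sequences. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  lines <- unlist(purrr::map2(proteins$protein_id, proteins$sequence,
    function(id, seq) {
      starts <- seq(1, nchar(seq), by = width)
      c(paste0(">", id), substring(seq, starts, pmin(starts + width - 1, nchar(seq))))
    }))
  writeLines(lines, path)
  invisible(path)
}
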