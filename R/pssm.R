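#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the ASCII PSSM emitted by `blastpgp`/`psiblast -Q`: header lines, an
#' amino-acid column header, then one row per sequence position holding the
#' position index, the residue, 20 integer log-odds substitution scores and
#' (optionally) 20 weighted-percentage columns plus two trailing floats. Only
#' the log-odds columns are kept — they carry the signed
#' favoured/disfavoured-substitution information the evolutionary encoding
#' aggregates. Columns are re-mapped from the file's header letters to the
#' package-wide alphabetical order ([amino_acids()]).
#'
#' @param path Path to the PSSM file.
#' @param protein_id Identifier to attach; defaults to the file name without
#'   extension.
#' @return A `pssm_profile` object: list with `protein_id`, `residues`
#'   (length-L string) and `scores` (L x 20 integer matrix, columns in
#'   canonical order).
#' @export
parse_pssm <- function(path, protein_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop_format("PSSM file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  # the header line: >= 20 single uppercase letters
  is_header <- vapply(toks, function(tk) {
    length(tk) >= 20 && all(grepl("^[A-Z]$", tk))
  }, logical(1))
  if (!any(is_header)) {
    stop_format("'%s' has no amino-acid column header line", path)
  }
  h <- which(is_header)[1]
  letters20 <- toks[[h]][1:20]
  if (!setequal(letters20, amino_acids()) || anyDuplicated(letters20)) {
    stop_format("'%s' line %d: column header is not the 20 standard amino acids",
                path, h)
  }
  is_row <- vapply(toks, function(tk) {
    length(tk) >= 2 && grepl("^\\d+$", tk[1]) && grepl("^[A-Z]$", tk[2])
  }, logical(1))
  is_row[seq_len(h)] <- FALSE
  rows <- which(is_row)
  if (length(rows) == 0) stop_format("'%s' contains no PSSM rows", path)
  L <- length(rows)
  scores <- matrix(NA_integer_, L, 20)
  residues <- character(L)
  idx <- integer(L)
  for (r in seq_len(L)) {
    tk <- toks[[rows[r]]]
    if (length(tk) < 22) {
      stop_format("'%s' line %d: expected at least 22 fields, found %d",
                  path, rows[r], length(tk))
    }
    vals <- suppressWarnings(as.numeric(tk[3:22]))
    if (any(is.na(vals)) || any(vals != round(vals))) {
      stop_format("'%s' line %d: non-integer log-odds score", path, rows[r])
    }
    idx[r] <- as.integer(tk[1])
    residues[r] <- tk[2]
    scores[r, ] <- as.integer(vals)
  }
  if (!identical(idx, seq_len(L))) {
    stop_format("'%s': position indices are not contiguous from 1 (line %d)",
                path, rows[which(idx != seq_len(L))[1]])
  }
  colnames(scores) <- letters20
  scores <- scores[, amino_acids(), drop = FALSE]
  structure(
    list(protein_id = protein_id,
         residues = paste(residues, collapse = ""),
         scores = scores),
    class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 amino-acid columns\n",
              x$protein_id, nrow(x$scores)))
  invisible(x)
}

#' Turn a PSSM profile into a long tibble
#'
#' @param x A `pssm_profile`.
#' @param ... Unused.
#' @return Tibble with columns `position`, `residue`, `target`, `score`.
#' @method tidy pssm_profile
#' @export
tidy.pssm_profile <- function(x, ...) {
  L <- nrow(x$scores)
  tibble::tibble(
    position = rep(seq_len(L), each = 20),
    residue = rep(strsplit(x$residues, "")[[1]], each = 20),
    target = rep(amino_acids(), L),
    score = as.vector(t(x$scores)))
}

#' Read a directory of per-protein PSSM files
#'
#' @param dir Directory containing one `<protein_id>.pssm` file per protein.
#' @param pattern File pattern, default `"\\.pssm$"`.
#' @return Named list of `pssm_profile` objects keyed by protein id.
#' @export
read_pssm_dir <- function(dir, pattern = "\\.pssm$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  profiles <- purrr::map(files, parse_pssm)
  stats::setNames(profiles, vapply(profiles, `[[`, character(1), "protein_id"))
}

#' Write a PSSM profile in PSI-BLAST ASCII dialect
#'
#' Emits the `blastpgp -Q` layout (native `A R N D C ...` column order,
#' percentage columns zeroed) so generated fixtures round-trip through
#' [parse_pssm()], exercising the column re-mapping.
#'
#' @param profile A `pssm_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  ord <- pssm_native_order()
  m <- profile$scores[, ord, drop = FALSE]
  res <- strsplit(profile$residues, "")[[1]]
  header <- paste0("          ",
                   paste(sprintf(" %3s", ord), collapse = ""), " ",
                   paste(sprintf(" %3s", ord), collapse = ""))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste0(sprintf("%5d %s", i, res[i]),
           paste(sprintf(" %3d", m[i, ]), collapse = ""), " ",
           paste(sprintf(" %3d", rep(0L, 20)), collapse = ""),
           sprintf("  %4.2f %4.2f", 0, 0))
  }, character(1))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapped matches",
    header, body, "", ""), path)
  invisible(path)
}

#' Encode windows as 400 evolutionary-conservation features
#'
#' For each window, substitution-score rows of the protein's PSSM at the
#' window's non-X positions are accumulated by source residue type into a
#' 20 x 20 matrix `M`: row `i`, column `j` holds the sum of the scores of
#' residues of type `i` in the window being substituted by type `j`. `M` is
#' flattened row-major into 400 features named `evo_<from><to>`; X-padded
#' positions contribute nothing, so a fully padded window encodes to zeros.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param profiles A single `pssm_profile` or a named list of them keyed by
#'   protein id (see [read_pssm_dir()]).
#' @return Tibble with 400 numeric columns `evo_AA` ... `evo_YY`, one row per
#'   window.
#' @export
encode_evolutionary <- function(windows, profiles) {
  if (inherits(profiles, "pssm_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$protein_id)
  }
  aa <- amino_acids()
  fnames <- paste0("evo_", rep(aa, each = 20), rep(aa, 20))
  warned <- character(0)
  out <- matrix(0, nrow(windows), 400, dimnames = list(NULL, fnames))
  for (w in seq_len(nrow(windows))) {
    prof <- profiles[[windows$protein_id[w]]]
    if (is.null(prof)) {
      stop_invalid("no PSSM profile for protein '%s'", windows$protein_id[w])
    }
    L <- nrow(prof$scores)
    xi <- windows$xi[w]
    letters <- strsplit(windows$peptide[w], "")[[1]]
    offs <- which(letters != "X")
    if (length(offs) == 0) next
    pos <- windows$center_pos[w] - xi - 1L + offs
    if (any(pos < 1L | pos > L)) {
      stop_invalid(
        "window %s:%d extends beyond its PSSM profile (length %d): profile/protein length mismatch",
        windows$protein_id[w], windows$center_pos[w], L)
    }
    prof_res <- substring(prof$residues, pos, pos)
    if (any(prof_res != letters[offs]) &&
        !(windows$protein_id[w] %in% warned)) {
      warn(sprintf(
        "PSSM residue column for '%s' disagrees with the window peptide; check sequence versions",
        windows$protein_id[w]))
      warned <- c(warned, windows$protein_id[w])
    }
    M <- rowsum(prof$scores[pos, , drop = FALSE],
                group = factor(letters[offs], levels = aa))
    keep <- rownames(M)
    full <- matrix(0, 20, 20, dimnames = list(aa, aa))
    full[keep, ] <- M
    out[w, ] <- as.vector(t(full))
  }
  tibble::as_tibble(out)
}
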