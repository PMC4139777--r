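#' Parse a PSIPRED secondary-structure prediction
#'
#' Reads the PSIPRED vertical (`.ss2`) format — per-residue rows of position
#' index, residue, predicted state letter and three state probabilities — and
#' returns the per-residue state string over the three-letter alphabet H
#' (helix), E (strand), C (coil). A plain one-line file containing only
#' H/E/C letters is also accepted, which is convenient for fixtures.
#'
#' @param path Path to a `.ss2` (or plain state-string) file.
#' @return A single string over `{H, E, C}`, one letter per residue.
#' @export
parse_ss2 <- function(path) {
  if (!file.exists(path)) stop_format("secondary-structure file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_format("'%s' has no secondary-structure rows", path)
  if (length(lines) == 1 && grepl("^[HEChec]+$", lines[1])) {
    return(toupper(lines[1]))
  }
  toks <- strsplit(lines, "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3)) {
    stop_format("'%s': row %d has %d fields, expected at least 3 (index, residue, state)",
                path, which(nf < 3)[1], nf[nf < 3][1])
  }
  idx <- suppressWarnings(as.integer(vapply(toks, `[`, character(1), 1)))
  states <- toupper(vapply(toks, `[`, character(1), 3))
  if (any(is.na(idx)) || !identical(idx, seq_along(idx))) {
    stop_format("'%s': position indices are not contiguous from 1", path)
  }
  bad <- which(!states %in% c("H", "E", "C"))
  if (length(bad) > 0) {
    stop_format("'%s': unknown secondary-structure state '%s' at row %d",
                path, states[bad[1]], bad[1])
  }
  paste(states, collapse = "")
}

#' Read a directory of per-protein secondary-structure files
#'
#' @param dir Directory with one `<protein_id>.ss2` file per protein.
#' @param pattern File pattern, default `"\\.ss2$"`.
#' @return Tibble with columns `protein_id`, `ss`.
#' @export
read_ss_dir <- function(dir, pattern = "\\.ss2$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  tibble::tibble(
    protein_id = tools::file_path_sans_ext(basename(files)),
    ss = vapply(files, parse_ss2, character(1), USE.NAMES = FALSE))
}

#' Write a secondary-structure string in PSIPRED ss2 layout
#'
#' @param ss State string over `{H, E, C}`.
#' @param residues Residue string of the same length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ss2 <- function(ss, residues, path) {
  states <- strsplit(ss, "")[[1]]
  res <- strsplit(residues, "")[[1]]
  if (length(states) != length(res)) {
    stop_invalid("secondary-structure and residue strings differ in length")
  }
  probs <- matrix(0, length(states), 3,
                  dimnames = list(NULL, c("C", "H", "E")))
  probs[cbind(seq_along(states), match(states, colnames(probs)))] <- 1
  body <- sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                  seq_along(states), res, states,
                  probs[, "C"], probs[, "H"], probs[, "E"])
  writeLines(c("# PSIPRED VFORMAT (PSIPRED V3.3)", "", body), path)
  invisible(path)
}

#' Encode windows as 9 secondary-structure segment features
#'
#' The predicted states at the window's non-X positions are sliced out and,
#' for each state `a` in H, E, C, three statistics are computed: the total
#' residue count of `a` in the slice, the average length of the maximal runs
#' (segments) of `a` (0 when `a` is absent), and the composition — the count
#' divided by the slice length. A run broken only by window truncation counts
#' as one run of the slice.
#'
#' @param windows Window tibble from [extract_windows()].
#' @param ss A tibble with columns `protein_id`, `ss` (see [read_ss_dir()]),
#'   or a single state string when all windows come from one protein.
#' @return Tibble with 9 numeric columns `ss_total_H/E/C`, `ss_avglen_H/E/C`,
#'   `ss_comp_H/E/C`, one row per window.
#' @export
encode_secondary <- function(windows, ss) {
  if (is.character(ss) && length(ss) == 1) {
    ids <- unique(windows$protein_id)
    if (length(ids) > 1) {
      stop_invalid("a single ss string was given for windows from %d proteins",
                   length(ids))
    }
    ss <- tibble::tibble(protein_id = ids, ss = ss)
  }
  ss_map <- stats::setNames(ss$ss, ss$protein_id)
  states <- c("H", "E", "C")
  fnames <- c(paste0("ss_total_", states), paste0("ss_avglen_", states),
              paste0("ss_comp_", states))
  out <- matrix(0, nrow(windows), 9, dimnames = list(NULL, fnames))
  for (w in seq_len(nrow(windows))) {
    s <- ss_map[[windows$protein_id[w]]]
    if (is.null(s) || is.na(s)) {
      stop_invalid("no secondary structure for protein '%s'", windows$protein_id[w])
    }
    letters <- strsplit(windows$peptide[w], "")[[1]]
    offs <- which(letters != "X")
    if (length(offs) == 0) next
    pos <- windows$center_pos[w] - windows$xi[w] - 1L + offs
    if (any(pos < 1L | pos > nchar(s))) {
      stop_invalid(
        "window %s:%d extends beyond its secondary-structure string (length %d)",
        windows$protein_id[w], windows$center_pos[w], nchar(s))
    }
    slice <- substring(s, pos, pos)
    runs <- rle(slice)
    n <- length(slice)
    for (a in states) {
      total <- sum(slice == a)
      nseg <- sum(runs$values == a)
      out[w, paste0("ss_total_", a)] <- total
      out[w, paste0("ss_avglen_", a)] <- if (nseg > 0) total / nseg else 0
      out[w, paste0("ss_comp_", a)] <- total / n
    }
  }
  tibble::as_tibble(out)
}
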