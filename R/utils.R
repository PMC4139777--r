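#' The canonical amino-acid alphabet
#'
#' Every matrix-valued object in the package (PSSM columns, the
#' physicochemical property table, the 20x20 evolutionary aggregation) uses
#' one fixed column order: the 20 standard one-letter codes sorted
#' alphabetically. Input files using a different order (PSI-BLAST prints
#' `A R N D C ...`) are re-mapped by their header letters at parse time.
#'
#' @return Character vector of the 20 standard one-letter amino-acid codes,
#'   alphabetical.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# PSI-BLAST's native column order, used when writing fixture PSSMs.
pssm_native_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Columns of a window/feature tibble that are metadata, not features.
meta_cols <- function() c("protein_id", "center_pos", "xi", "peptide", "label")

#' Names of the feature columns of a feature tibble
#'
#' A feature tibble carries metadata columns (`protein_id`, `center_pos`,
#' `xi`, `peptide`, `label`) next to the numeric feature columns; this helper
#' returns the feature column names in their stored order.
#'
#' @param data A data frame with feature columns.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(data) {
  setdiff(names(data), meta_cols())
}

# sample() that never treats a length-1 x as 1:x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "snosite_format_error")
}

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "snosite_validation_error")
}

# Coerce labels to integer 0/1; accepts logical, numeric 0/1, factor or
# character with exactly the levels "0"/"1".
as_binary_label <- function(x, what = "label") {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    if (!all(x %in% c("0", "1"))) {
      stop_invalid("%s must be binary (0/1); got other values", what)
    }
    return(as.integer(x))
  }
  x <- as.numeric(x)
  if (any(is.na(x)) || !all(x %in% c(0, 1))) {
    stop_invalid("%s must be binary (0/1) with no missing values", what)
  }
  as.integer(x)
}
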