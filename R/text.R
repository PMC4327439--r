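#' Normalize query text
#'
#' Lower-cases, strips characters other than letters, digits and
#' apostrophes, and collapses runs of whitespace to single spaces. All
#' matching in the package operates on normalized text, so normalization is
#' idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)`.
#'
#' @param x character vector of raw query strings.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_text("  I was  Diagnosed with HIV! ")
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9' ]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Token-subsequence test: does `phrase` occur in `text` on word boundaries?
# Both are assumed normalized; implemented by padding with spaces so that
# "hives" does not match "hiv".
contains_phrase <- function(text, phrase) {
  grepl(paste0(" ", phrase, " "), paste0(" ", text, " "), fixed = TRUE)
}
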