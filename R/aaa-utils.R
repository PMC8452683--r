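#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS_TBL5 <- c("TAA", "TAG")
START_CODONS_TBL5 <- c("ATG", "ATA", "ATT", "ATC", "GTG", "TTG")

`%||%` <- function(x, y) if (is.null(x)) y else x

# split a DNA/alignment string into a character vector of single residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

# vectorized reverse complement on character vectors (ACGT only)
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring of a circular sequence, 1-based inclusive; `end` may exceed L
circular_substr <- function(seq, start, end) {
  L <- nchar(seq)
  start <- ((start - 1L) %% L) + 1L
  end <- ((end - 1L) %% L) + 1L
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, L), substr(seq, 1L, end))
  }
}

# length of the circular span from position a to position b (inclusive)
circular_span <- function(a, b, L) {
  ((b - a) %% L) + 1L
}

assert_dna <- function(x, what = "sequence", allow_gap = FALSE) {
  pat <- if (allow_gap) "^[ACGT-]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T%s}; ambiguity codes are not supported",
      what, if (allow_gap) ",-" else ""
    ))
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))
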