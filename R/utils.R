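#' Reverse-complement nucleotide strings
#'
#' Vectorised over a character vector; `N` stays `N`.
#'
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uppercase and fold anything outside {A,C,G,T} to N.
normalize_seq <- function(x) {
  gsub("[^ACGT]", "N", toupper(x))
}

# Round half away from zero, matching printed integer percentages.
round_half_up <- function(x) floor(x + 0.5)

#' Write a data frame as TSV
#'
#' @param x data.frame or data.table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a TSV into a data.table
#'
#' @param path input file.
#' @return data.table.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t")
}

# All substrings of length k of a single string, at starts 1..n-k+1.
# Returns character(0) if the string is shorter than k.
substr_windows <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(s, starts, starts + k - 1L)
}

# Per-position mismatch counts between two equal-width character vectors.
# N never matches (policy: unmappable base), including N vs N.
string_mismatches <- function(a, b, width, positions = seq_len(width)) {
  stopifnot(length(a) == length(b))
  mm <- integer(length(a))
  for (j in positions) {
    ca <- substr(a, j, j)
    cb <- substr(b, j, j)
    mm <- mm + as.integer(ca != cb | ca == "N" | cb == "N")
  }
  mm
}
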