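# Low-level sequence helpers. Sequences are plain uppercase character
# scalars internally; Biostrings objects appear only at I/O and alignment
# boundaries.

.BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x A character scalar (or vector) of DNA sequence.
#' @return Character of the same length with each element reverse-complemented.
#' @keywords internal
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    comp <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  out
}

#' Random DNA sequence
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

#' Split a CDS into codons
#' @keywords internal
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0L))
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Lexicographically minimal rotation of a string
#'
#' Used to report tandem repeat units in a canonical orientation-free form.
#' @keywords internal
min_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  doubled <- paste0(s, s)
  rots <- substring(doubled, seq_len(n), seq_len(n) + n - 1L)
  sort(rots)[1L]
}

#' Smallest primitive period of a string
#'
#' Returns the shortest unit u such that s is a prefix of repeated u.
#' @keywords internal
primitive_unit <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    unit <- substr(s, 1L, p)
    if (strrep(unit, n %/% p) == s) return(unit)
  }
  s
}

# Positions (1-based) of all occurrences of a fixed pattern in a string.
str_find_all <- function(pattern, x) {
  if (nchar(pattern) == 0L || nchar(x) < nchar(pattern)) return(integer(0L))
  res <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (res[1L] == -1L) integer(0L) else as.integer(res)
}

# Vectorised substring insert/delete/replace used by the simulator.
str_replace_at <- function(x, at, replacement) {
  paste0(substr(x, 1L, at - 1L), replacement,
         substr(x, at + nchar(replacement), nchar(x)))
}

str_insert_at <- function(x, at, insert) {
  # insert before position `at`
  paste0(substr(x, 1L, at - 1L), insert, substr(x, at, nchar(x)))
}

str_delete_at <- function(x, at, len = 1L) {
  paste0(substr(x, 1L, at - 1L), substr(x, at + len, nchar(x)))
}
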