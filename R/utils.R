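# Internal sequence helpers shared across modules. Sequences are plain upper-case
# character scalars over {A,C,G,T,N}; genome coordinates are 0-based half-open on
# the stored (J) strand, with wraps across the origin encoded as end > length.

.complement_from <- "ACGTNacgtn"
.complement_to   <- "TGCANtgcan"

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `{A,C,G,T,N}` (case preserved per base).
#' @return The reverse complement as a character scalar.
#' @examples
#' revcomp("ACGT")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return(seq)
  intToUtf8(rev(utf8ToInt(chartr(.complement_from, .complement_to, seq))))
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Map A,C,G,T,N -> 1..5 (anything else -> NA) for vectorized lookups.
seq_ints <- function(seq) {
  match(seq_chars(toupper(seq)), c("A", "C", "G", "T", "N"))
}

clean_dna <- function(seq) {
  s <- toupper(gsub("[^A-Za-z]", "", seq))
  s <- chartr("U", "T", s)
  if (grepl("[^ACGTN]", s)) {
    # IUPAC ambiguity codes are tolerated on input but collapsed to N
    s <- gsub("[^ACGT]", "N", s)
  }
  s
}

#' Extract a substring on a circular sequence
#'
#' Zero-based half-open coordinates; `end` may exceed the sequence length to
#' denote a span wrapping the origin (only meaningful on circular molecules).
#'
#' @param seq DNA string.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; may exceed `nchar(seq)`.
#' @return The spanned substring, read forward with modular indexing.
#' @export
circular_substr <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(end > start, end - start <= n)
  if (end <= n) return(substr(seq, start + 1L, end))
  paste0(substr(seq, start + 1L, n), substr(seq, 1L, end - n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic local RNG scope: evaluates expr with the given seed and restores
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, at = 0.5) {
  if (n <= 0L) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
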