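# Nucleotide composition and AT/GC statistics, whole-genome and per partition.

#' Base composition of a DNA string
#'
#' Counts A, C, G, T (N and other ambiguity codes are excluded from all counts
#' and denominators) and derives A+T and G+C percentages and strand skews.
#' `at_skew = (A - T)/(A + T)` and `gc_skew = (G - C)/(G + C)`; a skew whose
#' denominator is zero is reported as `NA`, as are the percentages of an all-N
#' sequence.
#'
#' @param seq DNA string.
#' @return An object of class `CompositionReport`: a list with `counts` (named
#'   integer vector A/C/G/T), `denominator`, `at_percent`, `gc_percent`,
#'   `at_skew`, `gc_skew`.
#' @examples
#' base_composition("ACGT")$at_percent  # 50
#' @export
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  x <- Biostrings::DNAString(clean_dna(seq))
  counts <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  counts <- stats::setNames(as.integer(counts), c("A", "C", "G", "T"))
  denom <- sum(counts)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  rep <- list(
    counts = counts,
    denominator = denom,
    at_percent = if (denom > 0) 100 * at / denom else NA_real_,
    gc_percent = if (denom > 0) 100 * gc / denom else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_
  )
  class(rep) <- "CompositionReport"
  rep
}

#' @export
print.CompositionReport <- function(x, ...) {
  cat(sprintf("CompositionReport: %d bases (A %d, C %d, G %d, T %d)\n",
              x$denominator, x$counts[["A"]], x$counts[["C"]],
              x$counts[["G"]], x$counts[["T"]]))
  cat(sprintf("  A+T %.2f%%  G+C %.2f%%  AT-skew %.4f  GC-skew %.4f\n",
              x$at_percent, x$gc_percent, x$at_skew, x$gc_skew))
  invisible(x)
}

.partition_names <- c("whole", "PCG", "rRNA", "tRNA", "rrnL", "rrnS", "control")

#' Composition by genome partition
#'
#' Computes a [base_composition()] report for the whole genome and for the
#' standard partitions: all protein-coding genes, all rRNAs, all tRNAs, `rrnL`
#' and `rrnS` individually, and the control (A+T-rich) region. Each partition
#' is the concatenation of the reading-direction sequences of its member
#' features, so a base shared by two overlapping features counts once per
#' feature.
#'
#' @param genome `AnnotatedMitogenome`.
#' @param partitions Which partitions to compute (default: all).
#' @return Named list of `CompositionReport`s; partitions with no member
#'   features are absent from the list and named in the `"absent"` attribute.
#' @export
partition_composition <- function(genome, partitions = .partition_names) {
  partitions <- match.arg(partitions, .partition_names, several.ok = TRUE)
  f <- genome$features
  members <- function(p) {
    switch(p,
      whole = NULL,
      PCG = f$name[f$kind == "PCG"],
      rRNA = f$name[f$kind == "rRNA"],
      tRNA = f$name[f$kind == "tRNA"],
      rrnL = f$name[f$name == "rrnL"],
      rrnS = f$name[f$name == "rrnS"],
      control = f$name[f$kind == "control"]
    )
  }
  out <- list()
  absent <- character(0)
  for (p in partitions) {
    if (p == "whole") {
      out[[p]] <- base_composition(genome$seq)
      next
    }
    nms <- members(p)
    if (!length(nms)) {
      absent <- c(absent, p)
      next
    }
    seqs <- vapply(nms, function(nm) extract_feature_sequence(genome, nm), "")
    out[[p]] <- base_composition(paste(seqs, collapse = ""))
  }
  attr(out, "absent") <- absent
  out
}

#' Flatten partition reports to a data frame
#'
#' @param reports Result of [partition_composition()].
#' @return `data.frame` with one row per partition.
#' @export
composition_table <- function(reports) {
  rows <- lapply(names(reports), function(p) {
    r <- reports[[p]]
    data.frame(partition = p, A = r$counts[["A"]], C = r$counts[["C"]],
               G = r$counts[["G"]], T = r$counts[["T"]],
               denominator = r$denominator,
               at_percent = r$at_percent, gc_percent = r$gc_percent,
               at_skew = r$at_skew, gc_skew = r$gc_skew,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
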