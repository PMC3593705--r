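# Translation under the invertebrate mitochondrial genetic code, start/stop
# classification, codon counting, RSCU and amino-acid frequencies.

.all_codons <- local({
  b <- c("T", "C", "A", "G")
  as.vector(vapply(b, function(x) vapply(b, function(y)
    paste0(x, y, b), character(4)), matrix("", 4, 4)))
})

#' Genetic code tables
#'
#' Returns a genetic code as a named list. `"invertebrate"` is the invertebrate
#' mitochondrial code (NCBI translation table 5: AGA/AGG -> Ser, ATA -> Met,
#' TGA -> Trp), the default throughout the package. `"arthropod_variant"` is
#' the variant arthropod code in which AGG is reassigned to Lys; it is provided
#' for genomes that use AGG, but is never the default because genomes that
#' avoid AGG entirely give no evidence for the reassignment.
#'
#' @param name `"invertebrate"` or `"arthropod_variant"`.
#' @return List with `name` and `codon_to_aa`, a named character vector over
#'   all 64 codons mapping to one-letter amino acids or `"*"` for stops.
#' @export
genetic_code <- function(name = c("invertebrate", "arthropod_variant")) {
  name <- match.arg(name)
  tab <- Biostrings::getGeneticCode("5")  # invertebrate mitochondrial
  if (name == "arthropod_variant") tab[["AGG"]] <- "K"
  stopifnot(length(tab) == 64L, all(.all_codons %in% names(tab)))
  list(name = name, codon_to_aa = tab[.all_codons])
}

split_codons <- function(cds) {
  n <- nchar(cds)
  k <- n %/% 3L
  if (!k) return(character(0))
  substring(cds, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}

#' Classify the start codon of a coding sequence
#'
#' Insect mitochondrial PCGs start with an ATN codon (ATT/ATC/ATA/ATG) or, for
#' cox1 in many species, with CGA. Anything else is classified `"other"`.
#'
#' @param cds Reading-direction coding sequence, length >= 3.
#' @return List with `class` (`"ATN"`, `"CGA"` or `"other"`) and `codon`.
#' @export
classify_start_codon <- function(cds) {
  cds <- clean_dna(cds)
  if (nchar(cds) < 3L) stop("cds shorter than one codon")
  codon <- substr(cds, 1L, 3L)
  cls <- if (codon %in% c("ATT", "ATC", "ATA", "ATG")) "ATN"
         else if (codon == "CGA") "CGA"
         else "other"
  list(class = cls, codon = codon)
}

#' Classify the stop of a coding sequence
#'
#' Mitochondrial CDSs may end in a complete TAA/TAG stop or in a truncated
#' stop completed by post-transcriptional polyadenylation: a single trailing T
#' (length = 1 mod 3) or trailing TA (length = 2 mod 3).
#'
#' @param cds Reading-direction coding sequence, length >= 4.
#' @return One of `"complete_TAA"`, `"complete_TAG"`, `"incomplete_T"`,
#'   `"incomplete_TA"`, `"other"`.
#' @export
classify_stop_codon <- function(cds) {
  cds <- clean_dna(cds)
  n <- nchar(cds)
  if (n < 4L) stop("cds shorter than 4 bases")
  r <- n %% 3L
  if (r == 0L) {
    last <- substr(cds, n - 2L, n)
    if (last == "TAA") return("complete_TAA")
    if (last == "TAG") return("complete_TAG")
    return("other")
  }
  if (r == 1L) {
    if (substr(cds, n, n) == "T") return("incomplete_T")
    return("other")
  }
  if (substr(cds, n - 1L, n) == "TA") return("incomplete_TA")
  "other"
}

#' Translate a coding sequence
#'
#' Straight in-frame table lookup. Trailing incomplete codons (1-2 bases) are
#' dropped and flagged; a terminal stop codon is excluded from the returned
#' peptide; internal stops are flagged by codon index but are not fatal.
#'
#' @param cds Reading-direction coding sequence, length >= 3.
#' @param code A [genetic_code()].
#' @return List with `peptide`, `internal_stops` (codon indices), and
#'   `incomplete_tail` (0-2 trailing bases dropped).
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  cds <- clean_dna(cds)
  if (nchar(cds) < 3L) stop("cds shorter than one codon")
  tail_len <- nchar(cds) %% 3L
  codons <- split_codons(cds)
  aa <- unname(code$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"  # ambiguous codon
  k <- length(aa)
  terminal_stop <- aa[k] == "*"
  pept <- aa
  if (terminal_stop) pept <- pept[-k]
  internal <- which(pept == "*")
  pept[pept == "*"] <- "*"
  list(peptide = paste(pept, collapse = ""),
       internal_stops = internal,
       incomplete_tail = tail_len)
}

#' Per-gene start/stop classification
#'
#' @param genome `AnnotatedMitogenome`.
#' @return `data.frame` with one row per PCG: `gene`, `start_codon`,
#'   `start_class`, `stop_class`.
#' @export
start_stop_report <- function(genome) {
  f <- genome$features
  pcg <- f[f$kind == "PCG", , drop = FALSE]
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    cds <- extract_feature_sequence(genome, pcg$name[i])
    st <- classify_start_codon(cds)
    data.frame(gene = pcg$name[i], start_codon = st$codon,
               start_class = st$class, stop_class = classify_stop_codon(cds),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------

#' Codon counts over a set of coding sequences
#'
#' Each CDS is read in frame 0. A terminal complete stop codon is excluded, as
#' are 1-2 trailing bases of an incomplete stop (the genomic sequence is
#' counted as annotated; completion by polyadenylation is a transcript-level
#' event). Codons containing an ambiguous base are skipped and tallied
#' separately.
#'
#' @param cds_set Character vector (or list) of reading-direction CDSs.
#' @param code A [genetic_code()] (used only to recognize stop codons).
#' @return A `CodonUsageTable`: list with `counts` (named integer vector over
#'   the 64 codons), `n_codons`, `n_ambiguous`; `rscu` and `aa_percent` are
#'   `NULL` until filled by [rscu()] / [aa_frequencies()].
#' @export
codon_counts <- function(cds_set, code = genetic_code()) {
  cds_set <- vapply(cds_set, clean_dna, "")
  counts <- stats::setNames(integer(64), .all_codons)
  ambiguous <- 0L
  stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
  for (cds in cds_set) {
    codons <- split_codons(cds)
    k <- length(codons)
    if (k && nchar(cds) %% 3L == 0L && codons[k] %in% stops) {
      codons <- codons[-k]
    }
    ok <- codons %in% .all_codons
    ambiguous <- ambiguous + sum(!ok)
    tab <- table(codons[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(counts = counts, n_codons = sum(counts),
                 n_ambiguous = ambiguous, rscu = NULL, aa_percent = NULL,
                 code = code$name),
            class = "CodonUsageTable")
}

codon_families <- function(code) {
  aa <- code$codon_to_aa
  split(names(aa)[aa != "*"], aa[aa != "*"])
}

#' Relative synonymous codon usage
#'
#' For codon `c` in a synonymous family of size `k` with family total `N`,
#' `RSCU(c) = count(c) * k / N` (0 when `N = 0`). Stop codons are excluded from
#' families. Under the invertebrate mitochondrial code, Leu is one family of
#' six codons (TTA/TTG + CTN) and Ser one family of eight (TCN + AGN).
#'
#' @param table A `CodonUsageTable` from [codon_counts()].
#' @param code A [genetic_code()].
#' @return The table with `rscu` filled (named numeric over non-stop codons).
#' @export
rscu <- function(table, code = genetic_code()) {
  fams <- codon_families(code)
  vals <- numeric(0)
  for (fam in fams) {
    tot <- sum(table$counts[fam])
    k <- length(fam)
    v <- if (tot > 0) table$counts[fam] * k / tot else
      stats::setNames(numeric(k), fam)
    vals <- c(vals, stats::setNames(as.numeric(v), fam))
  }
  table$rscu <- vals[order(match(names(vals), .all_codons))]
  table
}

#' Amino-acid frequencies of a CDS set
#'
#' Percent of each amino acid among all translated non-stop codons across the
#' set, under the same exclusions as [codon_counts()] (terminal stops and
#' incomplete tails are not counted; internal stop codons are excluded from
#' the denominator).
#'
#' @param cds_set Character vector of reading-direction CDSs.
#' @param code A [genetic_code()].
#' @return Named numeric vector of percentages, summing to 100.
#' @export
aa_frequencies <- function(cds_set, code = genetic_code()) {
  tab <- codon_counts(cds_set, code)
  aa <- code$codon_to_aa[names(tab$counts)]
  keep <- aa != "*"
  agg <- tapply(tab$counts[keep], aa[keep], sum)
  total <- sum(agg)
  if (total == 0) return(stats::setNames(numeric(0), character(0)))
  out <- 100 * agg / total
  out[order(-out)]
}

#' Full codon-usage analysis of a genome
#'
#' Convenience wrapper: extracts all PCG sequences, counts codons, fills RSCU
#' and amino-acid frequencies.
#'
#' @param genome `AnnotatedMitogenome`.
#' @param code A [genetic_code()].
#' @return A completed `CodonUsageTable`.
#' @export
codon_usage <- function(genome, code = genetic_code()) {
  f <- genome$features
  pcg <- f$name[f$kind == "PCG"]
  cds_set <- vapply(pcg, function(nm) extract_feature_sequence(genome, nm), "")
  tab <- codon_counts(cds_set, code)
  tab <- rscu(tab, code)
  tab$aa_percent <- aa_frequencies(cds_set, code)
  tab
}

#' @export
print.CodonUsageTable <- function(x, ...) {
  cat(sprintf("CodonUsageTable (%s code): %d codons counted, %d ambiguous\n",
              x$code, x$n_codons, x$n_ambiguous))
  if (!is.null(x$aa_percent)) {
    top <- utils::head(x$aa_percent, 4)
    cat("  top amino acids:",
        paste(sprintf("%s %.2f%%", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Codon usage as a data frame
#'
#' @param x A `CodonUsageTable`.
#' @param code A [genetic_code()] used for the amino-acid column.
#' @param ... Unused.
#' @return `data.frame` with columns `codon`, `aa`, `count`, `rscu`.
#' @export
as.data.frame.CodonUsageTable <- function(x, ..., code = genetic_code(x$code)) {
  df <- data.frame(codon = names(x$counts),
                   aa = unname(code$codon_to_aa[names(x$counts)]),
                   count = as.integer(x$counts),
                   stringsAsFactors = FALSE)
  df$rscu <- if (is.null(x$rscu)) NA_real_ else
    unname(x$rscu[match(df$codon, names(x$rscu))])
  df
}
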