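# Non-coding analysis: intergenic spacers and gene overlaps on the circle,
# tandem repeats, homopolymer tracts, conserved motifs, and spacer-vs-gene
# identity. String-level finders use 1-based inclusive positions within the
# given sequence; genome feature coordinates remain 0-based half-open.

#' Catalogue intergenic spacers and gene overlaps on the circle
#'
#' Features are sorted by start; for each adjacent pair (including the
#' origin-spanning junction of a circular molecule) the signed gap between the
#' upstream end and the downstream start yields a spacer (gap > 0), an overlap
#' (gap < 0) or neither (gap = 0). A feature wholly contained in another is
#' recorded separately, excluded from both catalogs, and warned about.
#'
#' @param genome `AnnotatedMitogenome` with at least two features.
#' @return List of class `SpacerOverlapCatalog` with `spacers` (`data.frame`:
#'   `left`, `right`, `start`, `end`, `length`, `at_percent`, `seq`),
#'   `overlaps` (`data.frame`: `gene_a`, `gene_b`, `length`, `seq`),
#'   `containments`, `total_spacer_bp`, `total_overlap_bp`.
#' @export
catalog_spacers_overlaps <- function(genome) {
  f <- genome$features
  stopifnot(nrow(f) >= 2L)
  n <- genome$length
  f <- f[order(f$start, f$end), , drop = FALSE]

  # containment on the circle: span of i inside span of j
  contained <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(f))) {
      if (i == j || contained[j]) next
      si <- f$start[i]; ei <- f$end[i]
      sj <- f$start[j]; ej <- f$end[j]
      # compare on an unrolled axis anchored at j
      off <- (si - sj) %% n
      if (off + (ei - si) <= ej - sj && (ei - si) < (ej - sj)) {
        contained[i] <- TRUE
      }
    }
  }
  containments <- f[contained, , drop = FALSE]
  if (nrow(containments)) {
    warning("features wholly contained in another are excluded from the ",
            "spacer/overlap catalogs: ",
            paste(containments$name, collapse = ", "))
  }
  f <- f[!contained, , drop = FALSE]

  spacers <- list(); overlaps <- list()
  m <- nrow(f)
  idx_next <- c(seq_len(m)[-1], 1L)
  for (k in seq_len(m)) {
    a <- f[k, ]; b <- f[idx_next[k], ]
    b_start <- if (idx_next[k] == 1L) b$start + n else b$start
    if (genome$topology == "linear" && idx_next[k] == 1L) break
    gap <- b_start - a$end
    if (gap > 0L) {
      s0 <- a$end %% n
      e0 <- s0 + gap
      sq <- circular_substr(genome$seq, s0, e0)
      spacers[[length(spacers) + 1L]] <- data.frame(
        left = a$name, right = b$name, start = s0, end = e0, length = gap,
        at_percent = base_composition(sq)$at_percent, seq = sq,
        stringsAsFactors = FALSE)
    } else if (gap < 0L) {
      s0 <- b_start %% n
      sq <- circular_substr(genome$seq, b$start, b$start - gap)
      overlaps[[length(overlaps) + 1L]] <- data.frame(
        gene_a = a$name, gene_b = b$name, start = s0, length = -gap, seq = sq,
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, cols) if (length(x)) do.call(rbind, x) else
    stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  spacers <- bind(spacers, c("left", "right", "start", "end", "length",
                             "at_percent", "seq"))
  overlaps <- bind(overlaps, c("gene_a", "gene_b", "start", "length", "seq"))
  structure(list(
    spacers = spacers, overlaps = overlaps, containments = containments,
    total_spacer_bp = sum(spacers$length), total_overlap_bp = sum(overlaps$length)
  ), class = "SpacerOverlapCatalog")
}

#' @export
print.SpacerOverlapCatalog <- function(x, ...) {
  cat(sprintf("SpacerOverlapCatalog: %d spacers (%d bp), %d overlaps (%d bp)\n",
              nrow(x$spacers), x$total_spacer_bp,
              nrow(x$overlaps), x$total_overlap_bp))
  invisible(x)
}

#' Circle accounting identity
#'
#' On a circular genome whose features overlap only pairwise between circular
#' neighbours, feature lengths minus overlap bases plus spacer bases tile the
#' circle exactly: sum(feature lengths) - total overlap + total spacers =
#' genome length.
#'
#' @param genome `AnnotatedMitogenome`.
#' @param catalog Optional precomputed [catalog_spacers_overlaps()] result.
#' @return List with `lhs`, `rhs` (= genome length) and `holds`.
#' @export
circle_accounting <- function(genome, catalog = NULL) {
  if (is.null(catalog)) catalog <- catalog_spacers_overlaps(genome)
  lhs <- sum(genome$features$end - genome$features$start) -
    catalog$total_overlap_bp + catalog$total_spacer_bp
  list(lhs = lhs, rhs = genome$length, holds = lhs == genome$length)
}

# ---------------------------------------------------------------------------
# Tandem repeats

smallest_period <- function(unit) {
  u <- nchar(unit)
  for (p in seq_len(u - 1L)) {
    if (u %% p == 0L &&
        unit == strrep(substr(unit, 1L, p), u %/% p)) return(p)
  }
  u
}

least_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(k)
    paste0(substr(unit, k, u), substr(unit, 1L, k - 1L)), "")
  sort(rots)[1]
}

#' Find maximal exact tandem repeats
#'
#' Locates every maximal exact tandem array with unit length 1-6 whose copy
#' number (fractional trailing copy allowed) meets the per-unit-class minimum
#' (defaults: mononucleotide 8, dinucleotide 5, units of 3-6 nt 3 copies).
#' Arrays whose unit is itself periodic (a repetition of a shorter unit) are
#' reported once under the shorter unit, and `canonical_unit` is the
#' lexicographically least rotation, so (AT)n and (TA)n name the same repeat.
#'
#' @param seq DNA string.
#' @param max_unit Largest unit length considered (default 6).
#' @param min_copies Named numeric vector of copy thresholds per unit length.
#' @return `data.frame` with `start`, `end` (1-based inclusive), `unit`
#'   (leading phase), `canonical_unit`, `unit_len`, `copies`.
#' @export
find_tandem_repeats <- function(seq, max_unit = 6L,
                                min_copies = c(8, 5, 3, 3, 3, 3)) {
  seq <- clean_dna(seq)
  n <- nchar(seq)
  if (length(min_copies) < max_unit) {
    min_copies <- c(min_copies, rep(min_copies[length(min_copies)],
                                    max_unit - length(min_copies)))
  }
  chars <- seq_chars(seq)
  hits <- list()
  for (u in seq_len(min(max_unit, n - 1L))) {
    m <- chars[(u + 1L):n] == chars[seq_len(n - u)]
    r <- rle(m)
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (!r$values[k]) next
      q <- r$lengths[k]
      start <- pos[k]               # first matched offset corresponds to s[start+u]
      total <- q + u                # span length of the array
      if (total / u < min_copies[u]) next
      unit <- substr(seq, start, start + u - 1L)
      if (smallest_period(unit) < u) next  # reported under the primitive unit
      hits[[length(hits) + 1L]] <- data.frame(
        start = start, end = start + total - 1L, unit = unit,
        canonical_unit = least_rotation(unit), unit_len = u,
        copies = total / u, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0), unit = character(0),
                      canonical_unit = character(0), unit_len = integer(0),
                      copies = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$unit_len), , drop = FALSE]
}

#' Find homopolymer tracts
#'
#' Maximal runs of a single base with length at or above `min_len`.
#'
#' @param seq DNA string.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param min_len Minimum run length (>= 5).
#' @return `data.frame` with `start`, `end` (1-based inclusive), `length`.
#' @export
find_poly_tracts <- function(seq, base, min_len = 8L) {
  stopifnot(min_len >= 5L, base %in% c("A", "C", "G", "T"))
  seq <- clean_dna(seq)
  r <- rle(seq_chars(seq) == base)
  pos <- cumsum(c(1L, r$lengths))
  keep <- which(r$values & r$lengths >= min_len)
  data.frame(start = pos[keep], end = pos[keep] + r$lengths[keep] - 1L,
             length = r$lengths[keep])
}

#' Find a motif allowing mismatches
#'
#' All positions where the motif matches with Hamming distance at most
#' `max_mismatches`; optionally also scans for the reverse complement.
#'
#' @param seq DNA string.
#' @param motif DNA string, length >= 3.
#' @param max_mismatches Maximum Hamming distance (default 0).
#' @param both_strands Also report reverse-complement matches.
#' @return `data.frame` with `start` (1-based), `match` (the matched words),
#'   `mismatches`, `strand` (`+`/`-`).
#' @export
find_motif <- function(seq, motif, max_mismatches = 0L, both_strands = FALSE) {
  seq <- clean_dna(seq); motif <- clean_dna(motif)
  stopifnot(nchar(motif) >= 3L)
  scan_one <- function(pat, strand) {
    m <- nchar(pat); n <- nchar(seq)
    if (n < m) return(NULL)
    chars <- seq_chars(seq); pc <- seq_chars(pat)
    mm <- integer(n - m + 1L)
    for (k in seq_len(m)) {
      mm <- mm + (chars[k:(n - m + k)] != pc[k])
    }
    pos <- which(mm <= max_mismatches)
    if (!length(pos)) return(NULL)
    data.frame(start = pos, match = substring(seq, pos, pos + m - 1L),
               mismatches = mm[pos], strand = strand, stringsAsFactors = FALSE)
  }
  out <- scan_one(motif, "+")
  if (both_strands && revcomp(motif) != motif) {
    out <- rbind(out, scan_one(revcomp(motif), "-"))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), match = character(0),
                      mismatches = integer(0), strand = character(0)))
  }
  out[order(out$start), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Global alignment (Needleman-Wunsch, linear gaps) with deterministic
# traceback. Hand-implemented so that the tie-break order (diagonal, then up =
# gap in b, then left = gap in a) is fixed; Biostrings::pairwiseAlignment
# serves as an independent score oracle in the tests.

#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and linear
#' gap -2. Identity is matches divided by alignment columns, in percent.
#' Traceback ties prefer the diagonal, then the gap in `b`, then the gap in
#' `a`, so the alignment is a deterministic function of its inputs.
#'
#' @param a,b Non-empty DNA strings.
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `identity` (percent), `matches`, `columns`, `score`,
#'   `aligned_a`, `aligned_b`.
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- clean_dna(a); b <- clean_dna(b)
  na <- nchar(a); nb <- nchar(b)
  stopifnot(na > 0L, nb > 0L)
  ac <- seq_chars(a); bc <- seq_chars(b)
  M <- matrix(0, na + 1L, nb + 1L)
  M[1, ] <- gap * (0:nb)
  M[, 1] <- gap * (0:na)
  jj <- seq_len(nb)
  for (i in seq_len(na)) {
    sub <- ifelse(ac[i] == bc, match, mismatch)
    cand <- pmax(M[i, jj] + sub, M[i, jj + 1L] + gap)
    # resolve the left-gap recurrence in closed form:
    # row[j] = max_{k<=j} cand[k] + gap*(j-k)
    M[i + 1L, jj + 1L] <- cummax(cand - gap * jj) + gap * jj
  }
  # traceback
  i <- na; j <- nb
  out_a <- character(0); out_b <- character(0)
  while (i > 0L || j > 0L) {
    here <- M[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == M[i, j] + (if (ac[i] == bc[j]) match else mismatch)) {
      out_a <- c(ac[i], out_a); out_b <- c(bc[j], out_b)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == M[i, j + 1L] + gap) {
      out_a <- c(ac[i], out_a); out_b <- c("-", out_b)
      i <- i - 1L
    } else {
      out_a <- c("-", out_a); out_b <- c(bc[j], out_b)
      j <- j - 1L
    }
  }
  matches <- sum(out_a == out_b & out_a != "-")
  columns <- length(out_a)
  list(identity = 100 * matches / columns, matches = matches,
       columns = columns, score = M[na + 1L, nb + 1L],
       aligned_a = paste(out_a, collapse = ""),
       aligned_b = paste(out_b, collapse = ""))
}

#' Best local placement of a spacer within a gene
#'
#' Slides the spacer across every gene window of the spacer's length and
#' reports the window maximizing [global_identity()], ties broken by the
#' leftmost window. Used to ask whether an intergenic spacer originated as a
#' partial duplication of a neighbouring gene.
#'
#' @param spacer DNA string.
#' @param gene DNA string longer than `spacer`.
#' @return List with `offset` (1-based window start in `gene`), `identity`,
#'   and the full `alignment` at the best window.
#' @export
spacer_origin_scan <- function(spacer, gene) {
  spacer <- clean_dna(spacer); gene <- clean_dna(gene)
  m <- nchar(spacer)
  stopifnot(nchar(gene) > m)
  best <- NULL; best_off <- NA_integer_
  for (off in seq_len(nchar(gene) - m + 1L)) {
    al <- global_identity(spacer, substr(gene, off, off + m - 1L))
    if (is.null(best) || al$identity > best$identity) {
      best <- al; best_off <- off
    }
  }
  list(offset = best_off, identity = best$identity, alignment = best)
}
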