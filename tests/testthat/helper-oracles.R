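# Independent brute-force oracles. These deliberately share no code with the
# package implementation: pair positions, scores and counts are re-derived
# from first principles with plain loops and substring arithmetic.

# Best cloverleaf score by naive enumeration over all legal boundary
# assignments (length-filtered first, then scored pair by pair with substr).
oracle_fold_best <- function(seq, anticodon = NULL) {
  n <- nchar(seq)
  pair_score <- function(x, y) {
    p <- paste0(x, y)
    if (p %in% c("AT", "TA", "GC", "CG")) 2L
    else if (p %in% c("GT", "TG")) 1L
    else 0L
  }
  ch <- function(i) substr(seq, i, i)
  best <- c(score = -1L, wc = -1L)
  for (s1 in 0:3) for (d in 3:4) for (dl in 4:12) for (s2 in 0:3)
    for (v in 3:9) for (t in 4:5) for (tl in 3:9) for (disc in 0:3) {
      if (31L + s1 + 2L * d + dl + s2 + v + 2L * t + tl + disc != n) next
      base <- 7L + s1 + 2L * d + dl + s2
      if (!is.null(anticodon) &&
          substr(seq, base + 8L, base + 10L) != anticodon) next
      wc <- 0L; gu <- 0L
      bump <- function(cl) {
        if (cl == 2L) wc <<- wc + 1L else if (cl == 1L) gu <<- gu + 1L
      }
      for (k in 1:7) bump(pair_score(ch(k), ch(n - disc - k + 1L)))
      for (k in seq_len(d)) {
        bump(pair_score(ch(7L + s1 + k), ch(7L + s1 + 2L * d + dl + 1L - k)))
      }
      for (k in 1:5) bump(pair_score(ch(base + k), ch(base + 18L - k)))
      tb <- base + 17L + v
      for (k in seq_len(t)) {
        bump(pair_score(ch(tb + k), ch(tb + 2L * t + tl + 1L - k)))
      }
      if (wc + gu > best[["score"]] ||
          (wc + gu == best[["score"]] && wc > best[["wc"]])) {
        best <- c(score = wc + gu, wc = wc)
      }
    }
  best
}

# O(n^2) tandem-repeat scan: for every start and unit size, extend while the
# periodicity holds; keep maximal arrays meeting the copy threshold, with
# non-primitive units dropped.
oracle_tandem_repeats <- function(seq, max_unit = 6L,
                                  min_copies = c(8, 5, 3, 3, 3, 3)) {
  n <- nchar(seq)
  hits <- list()
  for (u in seq_len(min(max_unit, n - 1L))) {
    i <- 1L
    while (i + u <= n) {
      # extend the array starting at i
      j <- i + u
      while (j <= n && substr(seq, j, j) == substr(seq, j - u, j - u)) {
        j <- j + 1L
      }
      span <- j - i
      if (span > u) {
        maximal_left <- i == 1L ||
          substr(seq, i - 1L, i - 1L) != substr(seq, i + u - 1L, i + u - 1L)
        unit <- substr(seq, i, i + u - 1L)
        primitive <- TRUE
        for (p in seq_len(u - 1L)) {
          if (u %% p == 0L &&
              unit == strrep(substr(unit, 1L, p), u %/% p)) {
            primitive <- FALSE
            break
          }
        }
        if (maximal_left && primitive && span / u >= min_copies[u]) {
          hits[[length(hits) + 1L]] <- data.frame(
            start = i, end = i + span - 1L, unit = unit, unit_len = u,
            copies = span / u, stringsAsFactors = FALSE)
        }
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), unit_len = integer(0),
                      copies = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[c("start", "end", "unit_len")]), , drop = FALSE]
  out[order(out$start, out$unit_len), , drop = FALSE]
}

# Exhaustive global-alignment score by recursion (tiny strings only).
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Position-wise translation via Biostrings' code table (independent of the
# package's lookup path).
oracle_translate <- function(cds) {
  tab <- Biostrings::getGeneticCode("5")
  k <- nchar(cds) %/% 3L
  paste(vapply(seq_len(k), function(i) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    unname(tab[codon])
  }, ""), collapse = "")
}

# Independent RSCU pass: counts by table(), families re-derived from the
# Biostrings code table.
oracle_rscu <- function(codons) {
  tab <- Biostrings::getGeneticCode("5")
  aa <- tab[codons]
  keep <- aa != "*"
  counts <- table(factor(codons[keep], levels = names(tab)[tab != "*"]))
  fam_of <- tab[names(counts)]
  out <- numeric(length(counts))
  names(out) <- names(counts)
  for (f in unique(fam_of)) {
    idx <- fam_of == f
    tot <- sum(counts[idx])
    out[idx] <- if (tot > 0) counts[idx] * sum(idx) / tot else 0
  }
  out
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

random_seq <- function(n, seed = NULL, at = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
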