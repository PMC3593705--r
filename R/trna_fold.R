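# Anticodon-anchored constrained cloverleaf folding of tRNA gene sequences.
#
# The fold model scores base pairs only (no thermodynamic energies): every
# candidate assignment of arm boundaries satisfying the canonical geometry is
# enumerated exhaustively, and the assignment maximizing the number of paired
# positions (Watson-Crick A:T/G:C plus G-U wobble) wins. Ties are resolved by
# more Watson-Crick pairs, then by the smaller DHU-loop start index, then by
# lexicographic order of the free geometry parameters, making the fold a total
# function of the sequence. T stands in for U throughout (gene-level DNA).

#' Canonical cloverleaf geometry constraints
#'
#' Fixed arms: acceptor stem 7 bp, anticodon stem 5 bp with a 7-nt loop.
#' Flexible: DHU stem 3-4 bp with a 4-12 nt loop, T-psi-C stem 4-5 bp with a
#' 3-9 nt loop, variable region 3-9 nt, two inter-arm spacers and the
#' discriminator region 0-3 nt each. A DHU-less topology replaces the whole
#' DHU arm and its spacers with a single unpaired 4-15 nt connector.
#'
#' @return Named list of ranges used by [fold_cloverleaf()].
#' @export
cloverleaf_constraints <- function() {
  list(acc = 7L, s1 = 0:3, d = 3:4, dloop = 4:12, s2 = 0:3,
       ac = 5L, acloop = 7L, var = 3:9, t = 4:5, tloop = 3:9, disc = 0:3,
       conn = 4:15)
}

# pair classes: 2 = Watson-Crick, 1 = G-U wobble, 0 = mismatch (N never pairs)
.pair_class_matrix <- local({
  m <- matrix(0L, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
})

.arm_of_segment <- c(acc5 = "acceptor", d5 = "DHU", ac5 = "anticodon",
                     t5 = "TpsiC")

cloverleaf_segments <- function(p, topology) {
  if (topology == "cloverleaf") {
    c(acc5 = 7L, s1 = p$s1, d5 = p$d, dloop = p$dloop, d3 = p$d, s2 = p$s2,
      ac5 = 5L, acloop = 7L, ac3 = 5L, var = p$v, t5 = p$t, tloop = p$tloop,
      t3 = p$t, acc3 = 7L, disc = p$disc)
  } else {
    c(acc5 = 7L, conn = p$conn, ac5 = 5L, acloop = 7L, ac3 = 5L, var = p$v,
      t5 = p$t, tloop = p$tloop, t3 = p$t, acc3 = 7L, disc = p$disc)
  }
}

# All (i, j, arm) stem pairs implied by a segment-length vector.
segment_pairs <- function(segs) {
  ends <- cumsum(segs)
  starts <- ends - segs + 1L
  pair_arm <- function(a5, a3, arm) {
    k <- seq_len(segs[[a5]])
    data.frame(i = starts[[a5]] + k - 1L, j = ends[[a3]] - k + 1L,
               arm = arm, stringsAsFactors = FALSE)
  }
  out <- pair_arm("acc5", "acc3", "acceptor")
  if ("d5" %in% names(segs)) out <- rbind(out, pair_arm("d5", "d3", "DHU"))
  rbind(out, pair_arm("ac5", "ac3", "anticodon"), pair_arm("t5", "t3", "TpsiC"))
}

build_fold <- function(seq, si, p, topology) {
  segs <- cloverleaf_segments(p, topology)
  pr <- segment_pairs(segs)
  chars <- seq_chars(seq)
  cls_code <- .pair_class_matrix[cbind(si[pr$i], si[pr$j])]
  pr$base5 <- chars[pr$i]
  pr$base3 <- chars[pr$j]
  pr$class <- c("mismatch", "GU", "WC")[cls_code + 1L]
  ends <- cumsum(segs)
  loop_start <- ends[["acloop"]] - segs[["acloop"]] + 1L
  anticodon <- substr(seq, loop_start + 2L, loop_start + 4L)
  structure(list(
    seq = seq, length = nchar(seq), topology = topology, segments = segs,
    pairs = pr, anticodon = anticodon,
    score = sum(cls_code > 0L), n_wc = sum(cls_code == 2L),
    n_gu = sum(cls_code == 1L), n_mismatch = sum(cls_code == 0L)
  ), class = "TrnaFold")
}

#' @export
print.TrnaFold <- function(x, ...) {
  if (x$topology == "unfoldable") {
    cat("TrnaFold: unfoldable under cloverleaf constraints\n")
    return(invisible(x))
  }
  cat(sprintf(
    "TrnaFold (%s): %d nt, anticodon %s, %d/%d paired (%d WC, %d GU, %d mismatch)\n",
    x$topology, x$length, x$anticodon, x$score, nrow(x$pairs), x$n_wc, x$n_gu,
    x$n_mismatch))
  cat(" ", to_dot_bracket(x), "\n")
  invisible(x)
}

# Vectorized exhaustive enumeration over one topology's constraint grid.
# Returns the best parameter row (plus score columns) or NULL when no
# assignment fits the sequence length / anticodon anchor.
enumerate_best <- function(si, n, topology, expected_anticodon, cons) {
  PM <- .pair_class_matrix
  if (topology == "cloverleaf") {
    g <- expand.grid(s1 = cons$s1, d = cons$d, dloop = cons$dloop,
                     s2 = cons$s2, v = cons$var, t = cons$t,
                     tloop = cons$tloop, disc = cons$disc,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[31L + g$s1 + 2L * g$d + g$dloop + g$s2 + g$v + 2L * g$t +
             g$tloop + g$disc == n, , drop = FALSE]
  } else {
    g <- expand.grid(conn = cons$conn, v = cons$var, t = cons$t,
                     tloop = cons$tloop, disc = cons$disc,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[31L + g$conn + g$v + 2L * g$t + g$tloop + g$disc == n, ,
           drop = FALSE]
  }
  if (!nrow(g)) return(NULL)
  base <- if (topology == "cloverleaf") {
    7L + g$s1 + 2L * g$d + g$dloop + g$s2
  } else 7L + g$conn
  if (!is.null(expected_anticodon)) {
    ac <- seq_ints(expected_anticodon)
    keep <- si[base + 8L] == ac[1] & si[base + 9L] == ac[2] &
      si[base + 10L] == ac[3]
    g <- g[keep, , drop = FALSE]
    base <- base[keep]
    if (!nrow(g)) return(NULL)
  }
  m <- nrow(g)
  wc <- integer(m); gu <- integer(m)
  add_pairs <- function(i, j, active = NULL) {
    cls <- PM[cbind(si[i], si[j])]
    if (!is.null(active)) cls <- cls * active
    wc <<- wc + (cls == 2L)
    gu <<- gu + (cls == 1L)
  }
  for (k in 1:7) add_pairs(rep.int(k, m), n - g$disc - k + 1L)
  if (topology == "cloverleaf") {
    for (k in 1:4) {
      add_pairs(7L + g$s1 + k, 7L + g$s1 + 2L * g$d + g$dloop + 1L - k,
                active = g$d >= k)
    }
  }
  for (k in 1:5) add_pairs(base + k, base + 18L - k)
  tbase <- base + 17L + g$v
  for (k in 1:5) {
    add_pairs(tbase + k, tbase + 2L * g$t + g$tloop + 1L - k,
              active = g$t >= k)
  }
  if (topology == "cloverleaf") {
    ord <- order(-(wc + gu), -wc, g$s1 + g$d, g$s1, g$d, g$dloop, g$s2, g$v,
                 g$t, g$tloop, g$disc)
  } else {
    ord <- order(-(wc + gu), -wc, g$conn, g$v, g$t, g$tloop, g$disc)
  }
  best <- as.list(g[ord[1], , drop = FALSE])
  best$score <- (wc + gu)[ord[1]]
  best$wc <- wc[ord[1]]
  best
}

arm_paired_fraction <- function(fold, arm) {
  p <- fold$pairs[fold$pairs$arm == arm, , drop = FALSE]
  if (!nrow(p)) return(NA_real_)
  mean(p$class != "mismatch")
}

#' Fold a tRNA gene sequence into a constrained cloverleaf
#'
#' Exhaustive search over all arm-boundary assignments satisfying
#' [cloverleaf_constraints()], maximizing the number of paired stem positions
#' (Watson-Crick plus G-U wobble), with deterministic tie-breaking (more WC
#' pairs, then smaller DHU-loop start, then lexicographic geometry). If
#' `expected_anticodon` is given, only folds placing that triplet at the
#' center of the anticodon loop are considered. With `allow_dhu_less`, when
#' the best cloverleaf leaves any of the acceptor, anticodon or T-psi-C stems
#' under 60% paired, a DHU-less topology (DHU arm replaced by an unpaired
#' connector) is also searched and the higher-scoring of the two returned
#' (cloverleaf preferred on ties).
#'
#' @param seq tRNA gene sequence, reading direction, 55-90 nt.
#' @param expected_anticodon Optional anticodon triplet (DNA alphabet).
#' @param allow_dhu_less Consider the DHU-less topology as a fallback.
#' @param constraints Geometry ranges, see [cloverleaf_constraints()].
#' @return A `TrnaFold`; when no boundary assignment satisfies the constraints
#'   the result has `topology = "unfoldable"`.
#' @export
fold_cloverleaf <- function(seq, expected_anticodon = NULL,
                            allow_dhu_less = FALSE,
                            constraints = cloverleaf_constraints()) {
  seq <- clean_dna(seq)
  n <- nchar(seq)
  if (n < 55L || n > 90L) stop("tRNA sequence length must be in [55, 90]")
  si <- seq_ints(seq)
  if (!is.null(expected_anticodon)) {
    expected_anticodon <- clean_dna(expected_anticodon)
    stopifnot(nchar(expected_anticodon) == 3L)
  }
  best_cl <- enumerate_best(si, n, "cloverleaf", expected_anticodon, constraints)
  fold_cl <- if (!is.null(best_cl)) build_fold(seq, si, best_cl, "cloverleaf")
  core_ok <- !is.null(fold_cl) && {
    fr <- vapply(c("acceptor", "anticodon", "TpsiC"),
                 function(a) arm_paired_fraction(fold_cl, a), numeric(1))
    all(fr >= 0.6)
  }
  dhu_weak <- !is.null(fold_cl) && arm_paired_fraction(fold_cl, "DHU") < 0.6
  if (allow_dhu_less && (!core_ok || dhu_weak)) {
    best_dl <- enumerate_best(si, n, "dhu_less", expected_anticodon, constraints)
    fold_dl <- if (!is.null(best_dl)) build_fold(seq, si, best_dl, "DHU_less")
    if (is.null(fold_cl)) {
      fold_cl <- fold_dl
    } else if (!is.null(fold_dl)) {
      if (dhu_weak && core_ok) {
        # the DHU arm pairs too poorly to be credible; prefer the DHU-less
        # topology whenever it explains the remaining arms at least as well
        dhu_paired <- sum(fold_cl$pairs$arm == "DHU" &
                            fold_cl$pairs$class != "mismatch")
        if (fold_dl$score >= fold_cl$score - dhu_paired) fold_cl <- fold_dl
      } else if (fold_dl$score > fold_cl$score ||
                 (fold_dl$score == fold_cl$score &&
                  fold_dl$n_wc > fold_cl$n_wc)) {
        fold_cl <- fold_dl
      }
    }
  }
  if (is.null(fold_cl)) {
    return(structure(list(seq = seq, length = n, topology = "unfoldable",
                          segments = NULL, pairs = NULL, anticodon = NA_character_,
                          score = 0L, n_wc = 0L, n_gu = 0L, n_mismatch = NA_integer_),
                     class = "TrnaFold"))
  }
  fold_cl
}

#' Census of non-Watson-Crick pairs across a set of folds
#'
#' Aggregates every non-WC stem pair by arm and by class. G-U wobble pairs are
#' counted separately from true mismatches, which are reported as unordered
#' base pairs (A-A, C-A, C-T, G-A, G-G, T-T, ...).
#'
#' @param folds List of `TrnaFold` objects (unfoldable entries are skipped).
#' @return A `MismatchCensus`: list with `total`, `by_arm` (named integer for
#'   DHU, acceptor, TpsiC, anticodon), `n_gu`, `by_class` (named integer,
#'   `"G-U"` plus mismatch types), `n_genes_with_mismatch`.
#' @export
census_mismatches <- function(folds) {
  stopifnot(length(folds) > 0L)
  arms <- c(DHU = 0L, acceptor = 0L, TpsiC = 0L, anticodon = 0L)
  classes <- integer(0)
  n_gu <- 0L
  genes_hit <- 0L
  for (f in folds) {
    if (f$topology == "unfoldable" || is.null(f$pairs)) next
    bad <- f$pairs[f$pairs$class != "WC", , drop = FALSE]
    if (nrow(bad)) genes_hit <- genes_hit + 1L
    for (r in seq_len(nrow(bad))) {
      arms[[bad$arm[r]]] <- arms[[bad$arm[r]]] + 1L
      key <- if (bad$class[r] == "GU") "G-U" else
        paste(sort(c(bad$base5[r], bad$base3[r])), collapse = "-")
      classes[key] <- (if (key %in% names(classes)) classes[[key]] else 0L) + 1L
      if (bad$class[r] == "GU") n_gu <- n_gu + 1L
    }
  }
  structure(list(total = sum(arms), by_arm = arms, n_gu = n_gu,
                 by_class = classes[order(names(classes))],
                 n_genes_with_mismatch = genes_hit),
            class = "MismatchCensus")
}

#' @export
print.MismatchCensus <- function(x, ...) {
  cat(sprintf("MismatchCensus: %d non-WC pairs (%d G-U) in %d genes\n",
              x$total, x$n_gu, x$n_genes_with_mismatch))
  cat("  by arm:",
      paste(sprintf("%s %d", names(x$by_arm), x$by_arm), collapse = ", "), "\n")
  invisible(x)
}

#' Dot-bracket notation of a fold
#'
#' @param fold A `TrnaFold`.
#' @return Balanced dot-bracket string of the same length as the sequence,
#'   with one helix block per stem.
#' @export
to_dot_bracket <- function(fold) {
  stopifnot(inherits(fold, "TrnaFold"), fold$topology != "unfoldable")
  db <- rep(".", fold$length)
  db[fold$pairs$i] <- "("
  db[fold$pairs$j] <- ")"
  paste(db, collapse = "")
}

#' Recover the pair set from a dot-bracket string
#'
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @return `data.frame` with columns `i`, `j` (1-based, i < j).
#' @export
parse_dot_bracket <- function(db) {
  chars <- seq_chars(db)
  stack <- integer(0)
  ii <- integer(0); jj <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") stack <- c(stack, k)
    else if (chars[k] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      ii <- c(ii, stack[length(stack)]); jj <- c(jj, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  o <- order(ii)
  data.frame(i = ii[o], j = jj[o])
}
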