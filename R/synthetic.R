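# Synthetic annotated mitogenomes with exhaustive ground truth.
#
# The generator emulates a lepidopteran mitogenome: the 37-gene complement in
# the derived lepidopteran order (control region - trnM - trnI - trnQ - nad2
# ...), AT-biased background drawn per site, protein-coding genes built
# in frame with chosen start codons and complete or truncated stops, tRNA
# genes emitted from cloverleaf templates with a controlled set of planted
# non-Watson-Crick pairs, planted intergenic spacers carrying microsatellites
# and motifs, planted gene overlaps (including the 7-nt atp8/atp6 ATGATAA
# overlap), and a control region carrying the ATAGA + poly-T signature.
# Every planted element is recorded in a truth table so downstream finders can
# be tested for exact recovery.

#' Lepidopteran mitochondrial gene order
#'
#' The derived gene order shared by sequenced Lepidoptera, in which trnM lies
#' between the A+T-rich region and trnI (control-trnM-trnI-trnQ-nad2-...).
#'
#' @return Character vector of 38 names (37 genes plus `AT_rich`).
#' @export
lepidopteran_gene_order <- function() {
  c("AT_rich", "trnM", "trnI", "trnQ", "nad2", "trnW", "trnC", "trnY",
    "cox1", "trnL2(UUR)", "cox2", "trnK", "trnD", "atp8", "atp6", "cox3",
    "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1(AGN)", "trnE", "trnF",
    "nad5", "trnH", "nad4", "nad4l", "trnT", "trnP", "nad6", "cob",
    "trnS2(UCN)", "nad1", "trnL1(CUN)", "rrnL", "trnV", "rrnS")
}

#' Ancestral insect mitochondrial gene order
#'
#' The ancestral arrangement (control-trnI-trnQ-trnM-nad2-...), from which the
#' lepidopteran order differs by the displacement of trnM.
#'
#' @return Character vector of 38 names.
#' @export
ancestral_insect_order <- function() {
  ord <- lepidopteran_gene_order()
  c("AT_rich", "trnI", "trnQ", "trnM", ord[-(1:4)])
}

.n_strand_genes <- c("trnQ", "trnC", "trnY", "trnF", "nad5", "trnH", "nad4",
                     "nad4l", "trnP", "nad1", "trnL1(CUN)", "rrnL", "trnV",
                     "rrnS")

.pcg_len <- c(nad2 = 1024L, cox1 = 1531L, cox2 = 682L, atp8 = 162L,
              atp6 = 678L, cox3 = 789L, nad3 = 354L, nad5 = 1734L,
              nad4 = 1339L, nad4l = 291L, nad6 = 531L, cob = 1149L,
              nad1 = 942L)

.pcg_start <- c(nad2 = "ATT", cox2 = "ATT", atp8 = "ATT", nad3 = "ATT",
                nad6 = "ATT", nad5 = "ATA", cob = "ATA", nad1 = "ATA",
                atp6 = "ATG", cox3 = "ATG", nad4 = "ATG", nad4l = "ATG",
                cox1 = "CGA")

.pcg_stop <- c(nad2 = "T", cox1 = "T", cox2 = "T", nad4 = "T",
               atp8 = "TAA", atp6 = "TAA", cox3 = "TAA", nad3 = "TAA",
               nad5 = "TAA", nad4l = "TAA", nad6 = "TAA", cob = "TAA",
               nad1 = "TAA")

.trna_len <- c(`trnM` = 72L, `trnI` = 69L, `trnQ` = 68L, `trnW` = 71L,
               `trnC` = 67L, `trnY` = 70L, `trnL2(UUR)` = 66L, `trnK` = 72L,
               `trnD` = 68L, `trnG` = 65L, `trnA` = 69L, `trnR` = 66L,
               `trnN` = 70L, `trnS1(AGN)` = 66L, `trnE` = 71L, `trnF` = 64L,
               `trnH` = 68L, `trnT` = 67L, `trnP` = 70L, `trnS2(UCN)` = 72L,
               `trnL1(CUN)` = 65L, `trnV` = 73L)

.trna_anticodon <- c(`trnM` = "CAT", `trnI` = "GAT", `trnQ` = "TTG",
                     `trnW` = "TCA", `trnC` = "GCA", `trnY` = "GTA",
                     `trnL2(UUR)` = "TAA", `trnK` = "CTT", `trnD` = "GTC",
                     `trnG` = "TCC", `trnA` = "TGC", `trnR` = "TCG",
                     `trnN` = "GTT", `trnS1(AGN)` = "GCT", `trnE` = "TTC",
                     `trnF` = "GAA", `trnH` = "GTG", `trnT` = "TGT",
                     `trnP` = "TGG", `trnS2(UCN)` = "TGA",
                     `trnL1(CUN)` = "TAG", `trnV` = "TAC")

# Default planted non-WC pair census: 43 pairs over 20 genes (trnM and trnV
# are perfect), 24 of them G-U wobbles; per arm 20 DHU, 8 acceptor, 9 TpsiC,
# 6 anticodon; mismatch types drawn from A-A, C-A, C-T, G-A, G-G, T-T.
.default_mismatch_plan <- list(
  `trnL2(UUR)` = "DHU:GU", `trnR` = "DHU:GU", `trnG` = "DHU:GU",
  `trnD` = "DHU:GU", `trnT` = "DHU:GU", `trnL1(CUN)` = "DHU:GU",
  `trnQ` = c("DHU:GU", "TpsiC:GU"),
  `trnC` = c("DHU:GU", "anticodon:GU"),
  `trnN` = c("DHU:CT", "acceptor:AA"),
  `trnF` = c("DHU:GA", "acceptor:GU"),
  `trnS2(UCN)` = c("DHU:TT", "anticodon:GU"),
  `trnS1(AGN)` = c("acceptor:GU", "TpsiC:AA", "anticodon:GU"),
  `trnI` = c("DHU:GU", "acceptor:GU", "TpsiC:TT"),
  `trnW` = c("DHU:GU", "TpsiC:GU", "TpsiC:GG"),
  `trnY` = c("DHU:GU", "TpsiC:AA", "anticodon:GG"),
  `trnK` = c("DHU:GG", "acceptor:GU", "TpsiC:CT"),
  `trnA` = c("DHU:AA", "DHU:GU", "TpsiC:AA"),
  `trnE` = c("DHU:CA", "acceptor:GU", "anticodon:CA"),
  `trnH` = c("DHU:GU", "TpsiC:GA", "anticodon:TT"),
  `trnP` = c("DHU:CT", "acceptor:GU", "acceptor:CA")
)

# Planted spacers by junction "left|right": the named lepidopteran spacers
# plus ten minor (1-5 bp) spacers; with the control region this yields 15
# non-coding regions.
.default_spacers <- list(
  `trnQ|nad2` = list(type = "at_exact", len = 61L, gc = 2L),
  `trnE|trnF` = list(type = "spacer_trnE_trnF", len = 49L),
  `trnS2(UCN)|nad1` = list(type = "spacer_motif", len = 16L),
  `nad1|trnL1(CUN)` = list(type = "random", len = 10L),
  `trnM|trnI` = list(type = "random", len = 1L),
  `trnY|cox1` = list(type = "random", len = 2L),
  `cox1|trnL2(UUR)` = list(type = "random", len = 1L),
  `trnK|trnD` = list(type = "random", len = 2L),
  `cox3|trnG` = list(type = "random", len = 1L),
  `nad3|trnA` = list(type = "random", len = 2L),
  `trnR|trnN` = list(type = "random", len = 1L),
  `nad4l|trnT` = list(type = "random", len = 2L),
  `trnP|nad6` = list(type = "random", len = 1L),
  `cob|trnS2(UCN)` = list(type = "random", len = 2L)
)

# Planted overlaps by junction: 35 bp over eight regions, led by the 7-nt
# atp8/atp6 ATGATAA overlap and an 8-nt trnW/trnC overlap.
.default_overlaps <- c(
  `atp8|atp6` = 7L, `trnW|trnC` = 8L, `trnI|trnQ` = 2L, `trnC|trnY` = 5L,
  `trnA|trnR` = 4L, `trnN|trnS1(AGN)` = 3L, `trnS1(AGN)|trnE` = 3L,
  `trnT|trnP` = 3L
)

#' Specification of a synthetic mitogenome
#'
#' Returns the generator's configuration: gene order and strands, per-gene
#' lengths, start/stop codon choices, tRNA templates with the planted non-WC
#' pair plan, planted spacers and overlaps, and the background A+T fraction.
#' The defaults describe a ~15.3 kb lepidopteran-style genome; pass a
#' different `at` to move the background composition.
#'
#' @param at Background A+T fraction in (0, 1) applied to every random draw
#'   (per site: P(A) = P(T) = at/2).
#' @param control_len Length of the A+T-rich control region (bp).
#' @param mismatch_plan Named list of planted tRNA pair plans
#'   (`"arm:class"` strings; arms `DHU`, `acceptor`, `TpsiC`, `anticodon`;
#'   classes `GU`, `AA`, `CA`, `CT`, `GA`, `GG`, `TT`).
#' @param spacers Named list of planted spacers by `"left|right"` junction.
#' @param overlaps Named integer vector of planted overlap lengths by junction.
#' @return A `GenomeSpec` list.
#' @export
genome_spec <- function(at = 0.80, control_len = 351L,
                        mismatch_plan = .default_mismatch_plan,
                        spacers = .default_spacers,
                        overlaps = .default_overlaps) {
  stopifnot(at > 0, at < 1, control_len >= 100L)
  structure(list(
    order = lepidopteran_gene_order(),
    n_strand = .n_strand_genes,
    pcg_len = .pcg_len, pcg_start = .pcg_start, pcg_stop = .pcg_stop,
    trna_len = .trna_len, trna_anticodon = .trna_anticodon,
    rrna_len = c(rrnL = 1312L, rrnS = 779L),
    control_len = as.integer(control_len),
    at = at, mismatch_plan = mismatch_plan,
    spacers = spacers, overlaps = overlaps
  ), class = "GenomeSpec")
}

# ---------------------------------------------------------------------------
# tRNA construction from cloverleaf templates

.class_bases <- list(GU = c("G", "T"), AA = c("A", "A"), CA = c("C", "A"),
                     CT = c("C", "T"), GA = c("G", "A"), GG = c("G", "G"),
                     TT = c("T", "T"))

normalize_class <- function(x) gsub("-", "", toupper(x))

geometry_for_length <- function(len, dhu_less = FALSE) {
  if (!dhu_less) {
    p <- list(s1 = 2L, d = 4L, dloop = 8L, s2 = 1L, v = 4L, t = 5L,
              tloop = 7L, disc = 1L)
    delta <- 72L - len
    shrink <- function(field, floor_at, by) {
      take <- min(by, p[[field]] - floor_at, delta)
      if (take > 0L) { p[[field]] <<- p[[field]] - take; delta <<- delta - take }
    }
    grow <- function(field, ceil_at) {
      add <- min(ceil_at - p[[field]], -delta)
      if (add > 0L) { p[[field]] <<- p[[field]] + add; delta <<- delta + add }
    }
    if (delta > 0L) {
      shrink("dloop", 4L, 4L); shrink("tloop", 3L, 4L); shrink("v", 3L, 1L)
      shrink("s2", 0L, 1L); shrink("disc", 0L, 1L); shrink("s1", 0L, 2L)
    } else if (delta < 0L) {
      grow("v", 9L); grow("dloop", 12L); grow("tloop", 9L)
    }
    if (delta != 0L) stop("no cloverleaf geometry of length ", len)
  } else {
    p <- list(conn = 8L, v = 4L, t = 5L, tloop = 7L, disc = 1L)
    delta <- 61L - len
    shrink <- function(field, floor_at, by) {
      take <- min(by, p[[field]] - floor_at, delta)
      if (take > 0L) { p[[field]] <<- p[[field]] - take; delta <<- delta - take }
    }
    grow <- function(field, ceil_at) {
      add <- min(ceil_at - p[[field]], -delta)
      if (add > 0L) { p[[field]] <<- p[[field]] + add; delta <<- delta + add }
    }
    if (delta > 0L) {
      shrink("conn", 4L, 4L); shrink("tloop", 3L, 4L); shrink("v", 3L, 1L)
      shrink("disc", 0L, 1L)
    } else if (delta < 0L) {
      grow("conn", 15L); grow("v", 9L); grow("tloop", 9L)
    }
    if (delta != 0L) stop("no DHU-less geometry of length ", len)
  }
  p
}

.comp <- c(A = "T", C = "G", G = "C", T = "A")

# bases that form neither a Watson-Crick nor a G-U pair with the given base
.non_pairing <- list(A = c("A", "C", "G"), C = c("A", "C", "T"),
                     G = c("A", "G"), T = c("C", "T"))

sample_non_pairing <- function(v, at = 0.8) {
  # stay within the loop alphabet {A, C} so the change cannot enable a pairing
  # elsewhere; the intersection with the non-pairing set is never empty
  allowed <- intersect(.non_pairing[[v]], c("A", "C"))
  w <- c(A = at, C = 1 - at)[allowed]
  sample(allowed, 1L, prob = w / sum(w))
}

# Unpaired template regions are drawn from {A, C} only: no two bases of that
# alphabet can form a Watson-Crick or G-U pair, so loops and spacers cannot
# host an alternative helix that would tie the planted structure. P(A) = at
# keeps the A+T expectation of the background.
sample_loop_chars <- function(n, at = 0.8) {
  sample(c("A", "C"), n, replace = TRUE, prob = c(at, 1 - at))
}

# Make the planted fold identifiable: the unpaired bases flanking each stem
# are reassigned, where needed, so that no helix can be extended or shifted by
# one position without losing pairs. Without this, a flanking base that
# happens to complement its would-be partner lets an alternative boundary
# assignment tie the planted score, and the deterministic tie-break may then
# prefer the alternative.
harden_template <- function(chars, segs, forced = logical(length(chars))) {
  ends <- cumsum(segs)
  starts <- ends - segs + 1L
  dhu <- "d5" %in% names(segs)
  cons <- list()
  add <- function(u, v) cons[[length(cons) + 1L]] <<- c(u, v)
  if (dhu) add(ends[["dloop"]], starts[["dloop"]])     # DHU inner extension
  add(ends[["acloop"]], starts[["acloop"]])            # anticodon inner
  add(ends[["tloop"]], starts[["tloop"]])              # TpsiC inner
  conn5 <- if (dhu) starts[["s1"]] else starts[["conn"]]
  if ((if (dhu) segs[["s1"]] else segs[["conn"]]) > 0L) {
    add(conn5, ends[["t3"]])                           # acceptor inner
  }
  if (dhu && segs[["s2"]] > 0L && segs[["s1"]] > 0L) {
    add(starts[["s2"]], ends[["s1"]])                  # DHU outer
  }
  add(starts[["var"]], if (dhu) ends[["s2"]] else ends[["conn"]])  # AC outer
  add(ends[["var"]], starts[["acc3"]])                 # TpsiC outer
  for (cn in cons) {
    u <- cn[1]; v <- cn[2]
    if (forced[u]) next
    if (.pair_class_matrix[chars[u], chars[v]] > 0L) {
      chars[u] <- sample_non_pairing(chars[v])
    }
  }
  chars
}

# Build one tRNA gene from its template under the current RNG state.
# force_head/force_tail fix the gene's first/last bases (used to realize
# planted overlaps); the paired stem partners of forced positions are reset to
# Watson-Crick complements and excluded from mismatch planting.
gen_trna_core <- function(name, len, anticodon, plan = character(0),
                          dhu_less = FALSE, force_head = NULL,
                          force_tail = NULL, at = 0.80) {
  p <- geometry_for_length(len, dhu_less)
  topology <- if (dhu_less) "dhu_less" else "cloverleaf"
  segs <- cloverleaf_segments(p, if (dhu_less) "dhu_less" else "cloverleaf")
  n <- sum(segs)
  stopifnot(n == len)
  pr <- segment_pairs(segs)
  chars <- sample_loop_chars(n, at)
  # perfect stems: 5' side random over the full alphabet, 3' complementary
  chars[pr$i] <- seq_chars(random_dna(nrow(pr), at))
  chars[pr$j] <- .comp[chars[pr$i]]
  # anticodon at the center of the 7-nt anticodon loop
  ends <- cumsum(segs)
  acl <- ends[["acloop"]] - 7L + 1L
  chars[(acl + 2L):(acl + 4L)] <- seq_chars(anticodon)

  constrained <- integer(0)
  forced <- logical(n)
  acc_rows <- which(pr$arm == "acceptor")  # ordered k = 1..7 (i ascending)
  if (!is.null(force_tail)) {
    k <- nchar(force_tail)
    stopifnot(k <= segs[["disc"]] + 7L)
    chars[(n - k + 1L):n] <- seq_chars(force_tail)
    forced[(n - k + 1L):n] <- TRUE
    kk <- k - segs[["disc"]]
    if (kk > 0L) {
      constrained <- acc_rows[seq_len(kk)]
      chars[pr$i[constrained]] <- .comp[chars[pr$j[constrained]]]
    }
  }
  if (!is.null(force_head)) {
    k <- nchar(force_head)
    stopifnot(k <= 7L + (if (dhu_less) segs[["conn"]] else segs[["s1"]]))
    chars[seq_len(k)] <- seq_chars(force_head)
    forced[seq_len(k)] <- TRUE
    kk <- min(k, 7L)
    constrained <- c(constrained, acc_rows[seq_len(kk)])
    chars[pr$j[acc_rows[seq_len(kk)]]] <- .comp[chars[pr$i[acc_rows[seq_len(kk)]]]]
  }

  used <- constrained
  planted <- list()
  for (item in plan) {
    bits <- strsplit(item, ":", fixed = TRUE)[[1]]
    arm <- bits[1]; cls <- normalize_class(bits[2])
    stopifnot(arm %in% c("DHU", "acceptor", "TpsiC", "anticodon"),
              cls %in% names(.class_bases))
    arm_rows <- which(pr$arm == arm)
    # in the length-flexible stems (DHU 3-4 bp, TpsiC 4-5 bp) only interior
    # pairs are used: an edge mismatch could be shed by an equally scoring
    # shorter stem, making the planted boundaries unidentifiable
    if (arm %in% c("DHU", "TpsiC") && length(arm_rows) > 2L) {
      arm_rows <- arm_rows[-c(1L, length(arm_rows))]
    }
    elig <- setdiff(arm_rows, used)
    if (!length(elig)) stop("no free stem pair in arm ", arm, " of ", name)
    r <- if (length(elig) > 1L) sample(elig, 1L) else elig
    b <- .class_bases[[cls]]
    if (stats::runif(1) < 0.5) b <- rev(b)
    chars[pr$i[r]] <- b[1]; chars[pr$j[r]] <- b[2]
    used <- c(used, r)
    planted[[length(planted) + 1L]] <- data.frame(
      arm = arm, class = cls, i = pr$i[r], j = pr$j[r],
      stringsAsFactors = FALSE)
  }
  chars <- harden_template(chars, segs, forced)
  seq <- paste(chars, collapse = "")
  fold <- build_fold(seq, seq_ints(seq),
                     p, if (dhu_less) "dhu_less" else "cloverleaf")
  fold$topology <- if (dhu_less) "DHU_less" else "cloverleaf"
  stopifnot(fold$n_gu + fold$n_mismatch == length(plan))
  list(name = name, seq = seq, fold = fold,
       planted = if (length(planted)) do.call(rbind, planted) else
         data.frame(arm = character(0), class = character(0),
                    i = integer(0), j = integer(0)))
}

# Rejection-sampled template generation: a draw is kept only if the
# constrained folder recovers exactly the planted boundaries and topology, so
# planted structures are by construction the unique optimum of the fold
# search. Draw rejection is rare (the non-pairing loop alphabet eliminates
# almost all competing boundary assignments) and deterministic under the
# session RNG.
gen_trna_checked <- function(name, len, anticodon, plan = character(0),
                             dhu_less = FALSE, force_head = NULL,
                             force_tail = NULL, at = 0.80, max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    tr <- gen_trna_core(name, len, anticodon, plan, dhu_less,
                        force_head, force_tail, at)
    fd <- fold_cloverleaf(tr$seq, expected_anticodon = anticodon,
                          allow_dhu_less = TRUE)
    if (identical(unname(fd$segments), unname(tr$fold$segments)) &&
        fd$topology == tr$fold$topology) {
      return(tr)
    }
  }
  stop("could not generate an identifiable template for ", name,
       " in ", max_tries, " draws")
}

#' Generate a single tRNA gene with planted non-WC pairs
#'
#' Builds a tRNA gene sequence from the named template (fixed geometry and
#' anticodon, fully Watson-Crick stems) and substitutes stem positions to
#' plant the requested pair classes. The planted fold is returned as ground
#' truth; [fold_cloverleaf()] is expected to recover it.
#'
#' @param template Canonical tRNA name (e.g. `"trnM"`, `"trnS1(AGN)"`).
#' @param mismatches Character vector of `"arm:class"` items (arms `DHU`,
#'   `acceptor`, `TpsiC`, `anticodon`; classes `GU`, `AA`, `CA`, `CT`, `GA`,
#'   `GG`, `TT`). At most 5.
#' @param seed Integer seed (the generator is deterministic given
#'   template + mismatches + seed).
#' @param at Background A+T fraction.
#' @return List with `seq`, `fold` (the planted `TrnaFold`) and `planted`
#'   (data frame of planted pairs).
#' @export
generate_trna <- function(template, mismatches = character(0), seed = 1L,
                          at = 0.80) {
  stopifnot(template %in% names(.trna_anticodon), length(mismatches) <= 5L)
  with_seed(seed, {
    gen_trna_checked(template, .trna_len[[template]],
                  .trna_anticodon[[template]], mismatches,
                  dhu_less = template == "trnS1(AGN)", at = at)
  })
}

# ---------------------------------------------------------------------------
# PCG and non-coding construction

sample_codon <- function(at) {
  repeat {
    c3 <- random_dna(3L, at)
    if (!c3 %in% c("TAA", "TAG")) return(c3)
  }
}

gen_pcg <- function(len, start_codon, stop_class, at,
                    force_head = NULL, force_tail = NULL) {
  r <- len %% 3L
  tail_seq <- switch(stop_class, TAA = "TAA", T = "T", TA = "TA")
  stopifnot((stop_class == "TAA" && r == 0L) ||
            (stop_class == "T" && r == 1L) ||
            (stop_class == "TA" && r == 2L))
  n_body <- (len - nchar(start_codon) - nchar(tail_seq)) %/% 3L
  body <- vapply(seq_len(n_body), function(i) sample_codon(at), "")
  chars <- seq_chars(paste0(start_codon, paste(body, collapse = ""), tail_seq))
  forced <- logical(len)
  forced[seq_len(3L)] <- TRUE
  if (!is.null(force_head)) {
    k <- nchar(force_head)
    stopifnot(substr(force_head, 1L, 3L) == start_codon)
    chars[seq_len(k)] <- seq_chars(force_head)
    forced[seq_len(k)] <- TRUE
  }
  if (!is.null(force_tail)) {
    k <- nchar(force_tail)
    chars[(len - k + 1L):len] <- seq_chars(force_tail)
    forced[(len - k + 1L):len] <- TRUE
  }
  # repair any internal stop codon introduced by forcing (resample free bases)
  n_cod <- (len - r) %/% 3L
  last_coding <- if (stop_class == "TAA") n_cod - 1L else n_cod
  for (ci in 2:last_coding) {
    idx <- (3L * ci - 2L):(3L * ci)
    repeat {
      codon <- paste(chars[idx], collapse = "")
      if (!codon %in% c("TAA", "TAG")) break
      free <- idx[!forced[idx]]
      if (!length(free)) stop("forced region creates an internal stop codon")
      chars[free] <- seq_chars(random_dna(length(free), at))
    }
  }
  paste(chars, collapse = "")
}

# AT-rich sequence with an exact number of G/C bases at random positions.
spacer_at_exact <- function(len, n_gc) {
  chars <- sample(c("A", "T"), len, replace = TRUE)
  if (n_gc > 0L) {
    pos <- sample.int(len, n_gc)
    chars[pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
  }
  paste(chars, collapse = "")
}

# ---------------------------------------------------------------------------

#' Generate an annotated synthetic mitogenome with ground truth
#'
#' Deterministic given `spec` and `seed`. The genome is assembled on the
#' circle starting at the control region; planted spacers, overlaps, repeats,
#' motifs, poly tracts, tRNA folds and PCG start/stop choices are all recorded
#' in the returned truth table.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#' @return List with `genome` (an `AnnotatedMitogenome`) and `truth` (list
#'   with `features`, `trna`, `pcg`, `spacers`, `overlaps`, `repeats`,
#'   `tracts`, `motifs`, `at`).
#' @export
generate_mitogenome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "GenomeSpec"))
  with_seed(seed, generate_mitogenome_impl(spec))
}

generate_mitogenome_impl <- function(spec) {
  at <- spec$at
  order <- spec$order
  strand_of <- function(nm) if (nm %in% spec$n_strand) "N" else "J"
  kind_of <- function(nm) {
    if (nm == "AT_rich") "control"
    else if (grepl("^trn", nm)) "tRNA"
    else if (grepl("^rrn", nm)) "rRNA"
    else "PCG"
  }

  # overlap bookkeeping: left gene -> (right gene, length)
  ov_left <- list()
  for (j in names(spec$overlaps)) {
    lr <- strsplit(j, "|", fixed = TRUE)[[1]]
    if (!all(lr %in% order)) stop("overlap junction not in gene order: ", j)
    if (match(lr[2], order) != match(lr[1], order) + 1L) {
      stop("overlap junction genes are not adjacent: ", j)
    }
    ov_left[[lr[1]]] <- list(right = lr[2], k = spec$overlaps[[j]])
  }

  stored <- list()   # stored-strand sequences per feature
  gene_seqs <- list()
  trna_truth <- list()
  control_truth <- NULL

  stored_of <- function(nm) {
    if (strand_of(nm) == "J") gene_seqs[[nm]] else revcomp(gene_seqs[[nm]])
  }

  # generation order honours overlap dependencies (right before left)
  gen_order <- unique(c("trnY", "trnC", "trnW", "trnQ", "trnI", "trnE",
                        "trnS1(AGN)", "trnN", "trnR", "trnA", "trnP", "trnT",
                        "atp6", "atp8", order))

  build_control <- function(len) {
    e <- list(motif = "ATAGA", polyT = strrep("T", 20L),
              ta9 = strrep("TA", 9L), ta8 = strrep("TA", 8L),
              polyA = strrep("A", 10L))
    planted_len <- sum(nchar(unlist(e)))
    n_guard <- 6L
    pad_total <- len - planted_len - n_guard
    stopifnot(pad_total >= 40L)
    p4 <- pad_total - 3L * (pad_total %/% 4L)
    pads <- c(rep(pad_total %/% 4L, 3L), p4)
    pad <- function(k) random_dna(k, 0.98)
    parts <- c(pad(pads[1]), e$motif, e$polyT, "C",
               pad(pads[2]), "C", e$ta9, "C",
               pad(pads[3]), "C", e$ta8, "C",
               pad(pads[4]), e$polyA, "C")
    seqs <- unlist(parts)
    offs <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]  # 0-based offsets
    list(seq = paste(seqs, collapse = ""),
         motif_off = offs[2], polyT_off = offs[3],
         ta9_off = offs[7], ta8_off = offs[11], polyA_off = offs[14])
  }

  for (nm in gen_order) {
    kd <- kind_of(nm)
    force_head <- NULL; force_tail <- NULL
    if (nm == "atp6") force_head <- "ATGATAA"
    if (!is.null(ov_left[[nm]])) {
      right <- ov_left[[nm]]$right; k <- ov_left[[nm]]$k
      req <- substr(stored_of(right), 1L, k)
      if (strand_of(nm) == "J") force_tail <- req else force_head <- revcomp(req)
    }
    if (kd == "tRNA") {
      tr <- gen_trna_checked(nm, spec$trna_len[[nm]], spec$trna_anticodon[[nm]],
                          spec$mismatch_plan[[nm]] %||% character(0),
                          dhu_less = nm == "trnS1(AGN)",
                          force_head = force_head, force_tail = force_tail,
                          at = at)
      gene_seqs[[nm]] <- tr$seq
      trna_truth[[nm]] <- tr
    } else if (kd == "PCG") {
      gene_seqs[[nm]] <- gen_pcg(spec$pcg_len[[nm]], spec$pcg_start[[nm]],
                                 spec$pcg_stop[[nm]], at,
                                 force_head = force_head,
                                 force_tail = force_tail)
    } else if (kd == "rRNA") {
      gene_seqs[[nm]] <- random_dna(spec$rrna_len[[nm]], at)
    } else {  # control
      control_truth <- build_control(spec$control_len)
      gene_seqs[[nm]] <- control_truth$seq
    }
  }

  # assemble the circle
  genome_str <- ""
  cursor <- 0L
  feat_rows <- list()
  spacer_truth <- list(); overlap_truth <- list()
  repeat_truth <- list(); tract_truth <- list(); motif_truth <- list()

  add_repeat <- function(region, unit, copies, gstart) {
    repeat_truth[[length(repeat_truth) + 1L]] <<- data.frame(
      region = region, unit = unit, canonical_unit = least_rotation(unit),
      copies = copies, genome_start = gstart,
      length = as.integer(round(copies * nchar(unit))),
      stringsAsFactors = FALSE)
  }

  build_spacer <- function(sp, left, right, gstart) {
    if (sp$type == "at_exact") return(spacer_at_exact(sp$len, sp$gc))
    if (sp$type == "spacer_trnE_trnF") {
      s <- paste0(strrep("TA", 18L), "C", strrep("TTAT", 3L))
      stopifnot(nchar(s) == sp$len)
      add_repeat("spacer", "TA", 18, gstart)
      add_repeat("spacer", "TTAT", 3, gstart + 37L)
      return(s)
    }
    if (sp$type == "spacer_motif") {
      s <- paste0("TAAT", "ATACTAT", "TATTA")
      stopifnot(nchar(s) == sp$len)
      motif_truth[[length(motif_truth) + 1L]] <<- data.frame(
        region = "spacer", motif = "ATACTAT", genome_start = gstart + 4L,
        stringsAsFactors = FALSE)
      return(s)
    }
    random_dna(sp$len, 0.95)
  }

  for (i in seq_along(order)) {
    nm <- order[i]
    sseq <- stored_of(nm)
    k_ov <- 0L
    if (i > 1L) {
      prev <- order[i - 1L]
      jname <- paste0(prev, "|", nm)
      if (!is.null(spec$spacers[[jname]])) {
        sp <- spec$spacers[[jname]]
        spseq <- build_spacer(sp, prev, nm, cursor)
        spacer_truth[[length(spacer_truth) + 1L]] <- data.frame(
          left = prev, right = nm, start = cursor,
          end = cursor + nchar(spseq), length = nchar(spseq), seq = spseq,
          stringsAsFactors = FALSE)
        genome_str <- paste0(genome_str, spseq)
        cursor <- cursor + nchar(spseq)
      }
      if (jname %in% names(spec$overlaps)) {
        k_ov <- spec$overlaps[[jname]]
        stopifnot(substr(genome_str, cursor - k_ov + 1L, cursor) ==
                    substr(sseq, 1L, k_ov))
        overlap_truth[[length(overlap_truth) + 1L]] <- data.frame(
          gene_a = prev, gene_b = nm, length = k_ov,
          start = cursor - k_ov, seq = substr(sseq, 1L, k_ov),
          stringsAsFactors = FALSE)
      }
    }
    start <- cursor - k_ov
    genome_str <- paste0(genome_str, substr(sseq, k_ov + 1L, nchar(sseq)))
    cursor <- start + nchar(sseq)
    feat_rows[[length(feat_rows) + 1L]] <- data.frame(
      name = nm, kind = kind_of(nm), start = start,
      end = start + nchar(sseq), strand = strand_of(nm),
      stringsAsFactors = FALSE)
    if (nm == "AT_rich") {
      ct <- control_truth
      add_repeat("control", "TA", 9, start + ct$ta9_off)
      add_repeat("control", "TA", 8, start + ct$ta8_off)
      tract_truth[[length(tract_truth) + 1L]] <- data.frame(
        region = "control", base = "T", length = 20L,
        genome_start = start + ct$polyT_off, stringsAsFactors = FALSE)
      tract_truth[[length(tract_truth) + 1L]] <- data.frame(
        region = "control", base = "A", length = 10L,
        genome_start = start + ct$polyA_off, stringsAsFactors = FALSE)
      motif_truth[[length(motif_truth) + 1L]] <- data.frame(
        region = "control", motif = "ATAGA", genome_start = start + ct$motif_off,
        stringsAsFactors = FALSE)
    }
  }

  features <- do.call(rbind, feat_rows)
  genome <- mitogenome("synthetic_lepidopteran", genome_str, features,
                       topology = "circular")
  bind0 <- function(x) if (length(x)) do.call(rbind, x) else NULL
  pcg_names <- features$name[features$kind == "PCG"]
  truth <- list(
    features = features,
    trna = trna_truth,
    pcg = data.frame(name = pcg_names,
                     start_codon = unname(spec$pcg_start[pcg_names]),
                     stop_class = unname(spec$pcg_stop[pcg_names]),
                     stringsAsFactors = FALSE),
    spacers = bind0(spacer_truth),
    overlaps = bind0(overlap_truth),
    repeats = bind0(repeat_truth),
    tracts = bind0(tract_truth),
    motifs = bind0(motif_truth),
    at = at
  )
  list(genome = genome, truth = truth)
}
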