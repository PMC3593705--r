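two_gene_genome <- function(seq, s1, e1, s2, e2, n = nchar(seq)) {
  mitogenome("t", seq, data.frame(
    name = c("a", "b"), kind = "PCG", start = c(s1, s2), end = c(e1, e2),
    strand = "J"))
}

test_that("abutting, spaced and overlapping neighbours are catalogued correctly", {
  # two genes tiling a 20 bp circle: no spacer, no overlap at either junction
  g0 <- two_gene_genome(random_seq(20, seed = 1), 0L, 10L, 10L, 20L)
  c0 <- catalog_spacers_overlaps(g0)
  expect_equal(nrow(c0$spacers), 0L)
  expect_equal(nrow(c0$overlaps), 0L)

  # overlap of 7 bp between (0,12) and (5,20)
  g1 <- two_gene_genome(random_seq(20, seed = 2), 0L, 12L, 5L, 20L)
  c1 <- catalog_spacers_overlaps(g1)
  expect_equal(nrow(c1$overlaps), 1L)
  expect_equal(c1$overlaps$length[1], 7L)
  expect_equal(c1$total_overlap_bp, 7L)

  # spacer across the origin junction
  g2 <- two_gene_genome(random_seq(20, seed = 3), 2L, 8L, 10L, 18L)
  c2 <- catalog_spacers_overlaps(g2)
  expect_equal(nrow(c2$spacers), 2L)
  wrap <- c2$spacers[c2$spacers$left == "b", ]
  expect_equal(wrap$length, 4L)  # 18..20 plus 0..2

  # containment is excluded and warned about
  g3 <- mitogenome("t", random_seq(30, seed = 4), data.frame(
    name = c("big", "small", "other"), kind = "PCG",
    start = c(0L, 5L, 20L), end = c(15L, 10L, 28L), strand = "J"))
  expect_warning(c3 <- catalog_spacers_overlaps(g3), "contained")
  expect_equal(c3$containments$name, "small")
  expect_false("small" %in% c(c3$spacers$left, c3$spacers$right))
})

test_that("the circle accounting identity holds on synthetic genomes", {
  for (seed in c(101, 102, 103)) {
    sim <- generate_mitogenome(genome_spec(), seed = seed)
    acc <- circle_accounting(sim$genome)
    expect_true(acc$holds)
  }
})

test_that("tandem repeat finding matches definitions and the brute-force scan", {
  h1 <- find_tandem_repeats("TATATATATA")
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$unit, "TA")
  expect_equal(h1$copies, 5)
  expect_equal(h1$canonical_unit, "AT")

  h2 <- find_tandem_repeats("TTATTTATTTAT")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$unit, "TTAT")
  expect_equal(h2$copies, 3)

  # maximality invariant: end - start + 1 = round(copies * unit length)
  set.seed(51)
  s <- random_seq(2000, at = 0.7)
  mine <- find_tandem_repeats(s)
  for (i in seq_len(nrow(mine))) {
    expect_equal(mine$end[i] - mine$start[i] + 1L,
                 as.integer(round(mine$copies[i] * mine$unit_len[i])))
  }
  # equality with the O(n^2) brute-force scan on 2 kb of random sequence
  ref <- oracle_tandem_repeats(s)
  rownames(mine) <- rownames(ref) <- NULL
  expect_equal(mine[c("start", "end", "unit", "unit_len", "copies")],
               ref[c("start", "end", "unit", "unit_len", "copies")])
})

test_that("poly tracts are maximal runs at or above the threshold", {
  h <- find_poly_tracts("TTTTTTTTTT", "T", min_len = 8)
  expect_equal(nrow(h), 1L)
  expect_equal(h$length, 10L)
  expect_equal(find_poly_tracts("TTTTATTTT", "T", min_len = 5)$length,
               integer(0))
  expect_error(find_poly_tracts("TTTTT", "T", min_len = 3))
})

test_that("motif scanning respects the mismatch budget and strand option", {
  s <- paste0("GGGG", "ATACTAT", "GGGG")
  hit <- find_motif(s, "ATACTAA", max_mismatches = 1)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 5L)
  expect_equal(hit$mismatches, 1L)
  expect_equal(nrow(find_motif(s, "ATACTAA", max_mismatches = 0)), 0L)
  expect_equal(find_motif(s, "ATACTAT", max_mismatches = 0)$mismatches, 0L)
  # reverse-complement scanning
  s2 <- paste0("GGGG", revcomp("ATAGA"), "GGGG")
  expect_equal(nrow(find_motif(s2, "ATAGA", both_strands = FALSE,
                               max_mismatches = 0)), 0L)
  both <- find_motif(s2, "ATAGA", both_strands = TRUE, max_mismatches = 0)
  expect_equal(both$strand, "-")
})

test_that("global identity matches its analytic cases and the exhaustive oracle", {
  s <- random_seq(50, seed = 61)
  expect_equal(global_identity(s, s)$identity, 100)
  r <- global_identity("ACGT", "ACGA")
  expect_equal(r$identity, 75)
  expect_equal(r$matches, 3L)
  expect_equal(r$columns, 4L)
  # symmetry, and 100 iff identical
  set.seed(62)
  for (i in 1:5) {
    a <- random_seq(30); b <- random_seq(30)
    ra <- global_identity(a, b); rb <- global_identity(b, a)
    expect_equal(ra$identity, rb$identity)
    expect_equal(ra$score, rb$score)
    if (a != b) expect_lt(ra$identity, 100)
  }
  # exhaustive enumeration oracle on tiny strings
  set.seed(63)
  for (i in 1:8) {
    a <- random_seq(sample(4:9, 1)); b <- random_seq(sample(4:9, 1))
    expect_equal(global_identity(a, b)$score, oracle_align_score(a, b))
  }
  # independent dynamic-programming oracle on longer strings
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:3) {
    a <- random_seq(60); b <- random_seq(60)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(global_identity(a, b)$score, Biostrings::score(ref))
  }
})

test_that("spacer origin scanning locates the source window", {
  set.seed(64)
  gene <- random_seq(200)
  spacer <- substr(gene, 81, 120)
  hit <- spacer_origin_scan(spacer, gene)
  expect_equal(hit$identity, 100)
  expect_equal(hit$offset, 81L)

  # ~10% substitutions: identity stays high at the planted offset
  ch <- seq_chars(spacer)
  pos <- sample(40, 4)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  mut <- paste(ch, collapse = "")
  hit2 <- spacer_origin_scan(mut, gene)
  expect_equal(hit2$offset, 81L)
  expect_gt(hit2$identity, 85)

  # the planted spacer clears the 95th percentile of a shuffled-spacer null;
  # an unrelated (shuffled) spacer by construction does not
  obs <- hit2$identity
  null <- replicate(20, {
    shuf <- paste(sample(seq_chars(mut)), collapse = "")
    spacer_origin_scan(shuf, gene)$identity
  })
  expect_gt(obs, stats::quantile(null, 0.95))
})
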