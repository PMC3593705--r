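make_tiny_genome <- function() {
  mitogenome("tiny", "AAACGTTTGCAGGTACGATCGATT",
             data.frame(name = c("g1", "g2"), kind = c("PCG", "tRNA"),
                        start = c(0L, 12L), end = c(9L, 20L),
                        strand = c("J", "N")))
}

test_that("genome construction enforces the container invariants", {
  g <- make_tiny_genome()
  expect_equal(g$length, nchar(g$seq))
  expect_error(mitogenome("x", "ACGT", data.frame(
    name = "a", kind = "PCG", start = 0, end = 10, strand = "J")),
    "longer than genome")
  expect_error(mitogenome("x", "ACGTACGT", data.frame(
    name = c("a", "a"), kind = "PCG", start = c(0, 4), end = c(3, 7),
    strand = "J")), "unique")
  expect_error(mitogenome("x", "ACGTACGT", data.frame(
    name = "a", kind = "PCG", start = 2, end = 2, strand = "J")),
    "end must exceed")
})

test_that("feature extraction honours strand, direction and origin wrap", {
  g <- mitogenome("s", "AAACGT",
                  data.frame(name = c("f", "r", "w"), kind = "PCG",
                             start = c(0L, 3L, 4L), end = c(3L, 6L, 8L),
                             strand = c("J", "N", "J")))
  expect_equal(extract_feature_sequence(g, "f"), "AAA")
  expect_equal(extract_feature_sequence(g, "r"), "ACG")  # revcomp of CGT
  expect_equal(extract_feature_sequence(g, "w"), "GTAA") # wraps the origin
  # extracted length always equals end - start
  for (i in seq_len(nrow(g$features))) {
    f <- g$features[i, ]
    expect_equal(nchar(extract_feature_sequence(g, f)), f$end - f$start)
  }
})

test_that("GenBank coordinates convert to 0-based half-open with wrap encoding", {
  gb <- c(
    "LOCUS       test                 24 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "     CDS             1..6",
    "                     /gene=\"nad2\"",
    "     tRNA            complement(join(22..24,1..3))",
    "                     /product=\"tRNA-Met\"",
    "ORIGIN",
    "        1 aaacgtttgc aggtacgatc gatt",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- read_genbank(path)
  expect_equal(g$length, 24L)
  expect_equal(g$topology, "circular")
  f <- g$features
  expect_equal(f$start[f$name == "nad2"], 0L)
  expect_equal(f$end[f$name == "nad2"], 6L)
  expect_equal(f$strand[f$name == "nad2"], "J")
  expect_equal(f$start[f$name == "trnM"], 21L)
  expect_equal(f$end[f$name == "trnM"], 27L)  # wrapped: end > length
  expect_equal(f$strand[f$name == "trnM"], "N")
})

test_that("reader rejects multi-record files and normalizes common aliases", {
  gb <- c("LOCUS       a   4 bp DNA circular", "ORIGIN", "        1 acgt", "//",
          "LOCUS       b   4 bp DNA circular", "ORIGIN", "        1 acgt", "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  expect_error(read_genbank(path), "exactly one LOCUS")

  expect_equal(normalize_gene_name("COI"), "cox1")
  expect_equal(normalize_gene_name("ND2"), "nad2")
  expect_equal(normalize_gene_name("16S rRNA"), "rrnL")
  expect_equal(normalize_gene_name(NA, "tRNA-Met"), "trnM")
  expect_equal(normalize_gene_name(NA, "tRNA-Leu(CUN)"), "trnL1(CUN)")
  expect_equal(normalize_gene_name(NA, "tRNA-Ser", anticodon = "GCT"),
               "trnS1(AGN)")
  expect_equal(normalize_gene_name("D-loop"), "AT_rich")
})

test_that("GenBank and FASTA+TSV round trips preserve sequence and coordinates", {
  sim <- generate_mitogenome(genome_spec(), seed = 11)
  g <- sim$genome
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, gb)
  g2 <- read_genbank(gb)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$features, g$features)
  expect_identical(g2$topology, g$topology)

  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_genome(g, fa)
  write_feature_tsv(g, tsv)
  g3 <- read_fasta_genome(fa, tsv)
  expect_identical(g3$seq, g$seq)
  expect_identical(g3$features[c("name", "start", "end", "strand")],
                   g$features[c("name", "start", "end", "strand")])
})

test_that("gene-order comparison is rotation-invariant and symmetric", {
  ord <- lepidopteran_gene_order()
  rot <- c(ord[-(1:3)], ord[1:3])
  r <- compare_gene_order(ord, rot)
  expect_true(r$identical)
  expect_length(r$displaced, 0)

  # the lepidopteran order differs from the ancestral insect order by trnM
  r2 <- compare_gene_order(lepidopteran_gene_order(), ancestral_insect_order())
  expect_false(r2$identical)
  expect_equal(r2$displaced, "trnM")
  # symmetry
  r3 <- compare_gene_order(ancestral_insect_order(), lepidopteran_gene_order())
  expect_equal(r3$displaced, r2$displaced)

  # single-swap case: removal of one gene restores rotational identity; the
  # alphabetically first valid set wins the tie
  r4 <- compare_gene_order(c("A", "B", "C", "D"), c("A", "C", "B", "D"))
  expect_equal(r4$displaced, "B")

  # names in only one order are reported, not fatal
  r5 <- compare_gene_order(c("A", "B", "C"), c("A", "C", "B", "X"))
  expect_equal(r5$only_in_b, "X")

  # rotation invariance under random rotations of either argument
  set.seed(7)
  for (i in 1:5) {
    k1 <- sample(length(ord), 1)
    k2 <- sample(length(ord), 1)
    rot_a <- c(ord[-seq_len(k1)], ord[seq_len(k1)])
    anc <- ancestral_insect_order()
    rot_b <- c(anc[-seq_len(k2)], anc[seq_len(k2)])
    expect_equal(compare_gene_order(rot_a, rot_b)$displaced, "trnM")
  }
})
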