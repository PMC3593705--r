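test_that("generation is byte-identical for a fixed spec and seed", {
  a <- generate_mitogenome(genome_spec(), seed = 71)
  b <- generate_mitogenome(genome_spec(), seed = 71)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$genome$features, b$genome$features)
  expect_identical(a$truth$spacers, b$truth$spacers)
  c <- generate_mitogenome(genome_spec(), seed = 72)
  expect_false(identical(a$genome$seq, c$genome$seq))
})

test_that("the default genome realizes the lepidopteran study conditions", {
  sim <- generate_mitogenome(genome_spec(), seed = 73)
  g <- sim$genome
  f <- g$features
  expect_equal(g$length, 15273L)
  expect_equal(nrow(f), 38L)
  expect_equal(sum(f$kind == "PCG"), 13L)
  expect_equal(sum(f$kind == "tRNA"), 22L)
  expect_equal(sum(f$kind == "rRNA"), 2L)
  expect_equal(sum(f$kind == "tRNA" & f$strand == "J"), 14L)
  expect_equal(sum(f$kind == "tRNA" & f$strand == "N"), 8L)
  expect_equal(f$name[order(f$start)], lepidopteran_gene_order())
  # tRNA lengths within the documented 64-73 nt range
  tl <- (f$end - f$start)[f$kind == "tRNA"]
  expect_true(all(tl >= 64 & tl <= 73))
})

test_that("planted spacers and overlaps are recovered exactly by the catalog", {
  sim <- generate_mitogenome(genome_spec(), seed = 74)
  cat_so <- catalog_spacers_overlaps(sim$genome)
  truth_sp <- sim$truth$spacers
  got_sp <- cat_so$spacers
  key <- function(d) paste(d$left, d$right, d$length)
  expect_setequal(paste(got_sp$left, got_sp$right, got_sp$start, got_sp$length),
                  paste(truth_sp$left, truth_sp$right, truth_sp$start,
                        truth_sp$length))
  truth_ov <- sim$truth$overlaps
  got_ov <- cat_so$overlaps
  expect_setequal(paste(got_ov$gene_a, got_ov$gene_b, got_ov$length),
                  paste(truth_ov$gene_a, truth_ov$gene_b, truth_ov$length))
  expect_equal(cat_so$total_overlap_bp, sum(truth_ov$length))
  # the atp8/atp6 overlap carries its canonical sequence
  expect_equal(got_ov$seq[got_ov$gene_a == "atp8"], "ATGATAA")
})

test_that("planted repeats, tracts and motifs are found with no false negatives", {
  sim <- generate_mitogenome(genome_spec(), seed = 75)
  g <- sim$genome
  # scan the whole genome once; every planted element must be contained in a
  # reported hit of the same canonical unit / base / word
  hits <- find_tandem_repeats(g$seq)
  for (i in seq_len(nrow(sim$truth$repeats))) {
    tr <- sim$truth$repeats[i, ]
    s1 <- tr$genome_start + 1L
    e1 <- tr$genome_start + tr$length
    cover <- hits[hits$canonical_unit == tr$canonical_unit &
                    hits$start <= s1 & hits$end >= e1, ]
    expect_gte(nrow(cover), 1L)
  }
  for (i in seq_len(nrow(sim$truth$tracts))) {
    tt <- sim$truth$tracts[i, ]
    ph <- find_poly_tracts(g$seq, tt$base, min_len = 8L)
    cover <- ph[ph$start <= tt$genome_start + 1L &
                  ph$end >= tt$genome_start + tt$length, ]
    expect_gte(nrow(cover), 1L)
  }
  for (i in seq_len(nrow(sim$truth$motifs))) {
    tm <- sim$truth$motifs[i, ]
    mh <- find_motif(g$seq, tm$motif, max_mismatches = 0)
    expect_true((tm$genome_start + 1L) %in% mh$start)
  }
})

test_that("background composition tracks the requested A+T fraction", {
  for (at in c(0.70, 0.80)) {
    sim <- generate_mitogenome(genome_spec(at = at), seed = 76)
    got <- base_composition(sim$genome$seq)$at_percent
    expect_lt(abs(got - 100 * at), 2)
  }
})

test_that("single-tRNA generation plants exactly the requested pair classes", {
  # n = 0: the fold recovers the template exactly
  t0 <- generate_trna("trnM", character(0), seed = 81)
  f0 <- fold_cloverleaf(t0$seq, expected_anticodon = "CAT",
                        allow_dhu_less = TRUE)
  expect_identical(unname(f0$segments), unname(t0$fold$segments))
  expect_equal(f0$n_mismatch + f0$n_gu, 0L)

  # one G-U and one A-A
  t2 <- generate_trna("trnG", c("DHU:GU", "acceptor:AA"), seed = 82)
  f2 <- fold_cloverleaf(t2$seq, expected_anticodon = "TCC",
                        allow_dhu_less = TRUE)
  cen <- census_mismatches(list(f2))
  expect_equal(cen$total, 2L)
  expect_equal(cen$n_gu, 1L)
  expect_equal(unname(cen$by_class[["A-A"]]), 1L)

  # the DHU-less template folds DHU-less by construction
  ts <- generate_trna("trnS1(AGN)", c("acceptor:GU"), seed = 83)
  fs <- fold_cloverleaf(ts$seq, expected_anticodon = "GCT",
                        allow_dhu_less = TRUE)
  expect_equal(fs$topology, "DHU_less")
  expect_equal(fs$n_gu, 1L)
})

test_that("every PCG carries its configured start codon and stop class", {
  sim <- generate_mitogenome(genome_spec(), seed = 77)
  rep <- start_stop_report(sim$genome)
  expect_equal(sum(rep$start_class == "ATN"), 12L)
  expect_equal(rep$start_class[rep$gene == "cox1"], "CGA")
  expect_equal(sum(rep$stop_class == "complete_TAA"), 9L)
  expect_setequal(rep$gene[rep$stop_class == "incomplete_T"],
                  c("nad2", "cox1", "cox2", "nad4"))
})
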