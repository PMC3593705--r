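test_that("the invertebrate mitochondrial code and its arthropod variant are correct", {
  code <- genetic_code()
  expect_length(code$codon_to_aa, 64)
  expect_equal(unname(code$codon_to_aa[c("AGA", "AGG")]), c("S", "S"))
  expect_equal(unname(code$codon_to_aa[["ATA"]]), "M")
  expect_equal(unname(code$codon_to_aa[["TGA"]]), "W")
  expect_equal(sum(code$codon_to_aa == "*"), 2)  # TAA, TAG only
  var <- genetic_code("arthropod_variant")
  expect_equal(unname(var$codon_to_aa[["AGG"]]), "K")
  expect_equal(unname(var$codon_to_aa[["AGA"]]), "S")
})

test_that("start codons classify as ATN, CGA or other", {
  expect_equal(classify_start_codon("ATGAAA")$class, "ATN")
  expect_equal(classify_start_codon("ATTAAA")$class, "ATN")
  expect_equal(classify_start_codon("ATAAAA")$class, "ATN")
  expect_equal(classify_start_codon("ATCAAA")$class, "ATN")
  expect_equal(classify_start_codon("CGAGCA")$class, "CGA")
  expect_equal(classify_start_codon("CGAGCA")$codon, "CGA")
  expect_equal(classify_start_codon("TTGAAA")$class, "other")
  expect_error(classify_start_codon("AT"), "shorter")
})

test_that("stop classification matches the rule table over every 1-3 nt suffix", {
  bases <- c("A", "C", "G", "T")
  body <- "ATGAAA"
  # the rule, restated independently: complete TAA/TAG when in frame,
  # trailing T when length = 1 mod 3, trailing TA when length = 2 mod 3
  expected_class <- function(cds) {
    n <- nchar(cds)
    last3 <- substr(cds, n - 2, n)
    last2 <- substr(cds, n - 1, n)
    last1 <- substr(cds, n, n)
    switch(as.character(n %% 3),
           "0" = if (last3 == "TAA") "complete_TAA"
                 else if (last3 == "TAG") "complete_TAG" else "other",
           "1" = if (last1 == "T") "incomplete_T" else "other",
           "2" = if (last2 == "TA") "incomplete_TA" else "other")
  }
  suffixes <- c(bases,
                as.vector(outer(bases, bases, paste0)),
                as.vector(outer(as.vector(outer(bases, bases, paste0)),
                                bases, paste0)))
  for (suf in suffixes) {
    cds <- paste0(body, suf)
    expect_equal(classify_stop_codon(cds), expected_class(cds), info = cds)
  }
})

test_that("translation follows the code table, flags internal stops, drops tails", {
  expect_equal(translate_cds("ATGTGATAA")$peptide, "MW")  # TGA = Trp
  expect_length(translate_cds("ATGTGATAA")$internal_stops, 0)
  expect_equal(translate_cds("AGAAGG")$peptide, "SS")
  tr <- translate_cds("ATGTAAATG")
  expect_equal(tr$internal_stops, 2L)
  expect_equal(translate_cds("ATGAAAT")$incomplete_tail, 1L)
  expect_equal(translate_cds("ATGAAAT")$peptide, "MK")
  # random 300-codon sequences equal a position-wise independent scan
  set.seed(31)
  for (i in 1:3) {
    cds <- random_seq(900)
    ref <- oracle_translate(cds)
    if (substr(ref, 300, 300) == "*") ref <- substr(ref, 1, 299)
    expect_equal(translate_cds(cds)$peptide, ref)
  }
})

test_that("codon counting excludes terminal stops and incomplete tails", {
  t1 <- codon_counts(list("ATGTAA"))
  expect_equal(unname(t1$counts[["ATG"]]), 1L)
  expect_equal(t1$n_codons, 1L)
  t2 <- codon_counts(list("ATGATGTAA", "ATGTAA"))
  expect_equal(unname(t2$counts[["ATG"]]), 3L)
  # incomplete tail dropped; ambiguous codons tallied separately
  t3 <- codon_counts(list("ATGAANAAAT"))
  expect_equal(t3$n_codons, 2L)
  expect_equal(t3$n_ambiguous, 1L)
  # order invariance
  set.seed(32)
  cds_set <- replicate(5, random_seq(90 + 3 * sample(5, 1)))
  a <- codon_counts(as.list(cds_set))$counts
  b <- codon_counts(as.list(rev(cds_set)))$counts
  expect_identical(a, b)
})

test_that("RSCU satisfies its defining identities and matches an independent pass", {
  code <- genetic_code()
  # equal counts in a family give RSCU 1 everywhere
  t_eq <- codon_counts(list(paste0(c("TTT", "TTC"), collapse = "")))
  r_eq <- rscu(t_eq, code)
  expect_equal(unname(r_eq$rscu[c("TTT", "TTC")]), c(1, 1))
  # Phe family k = 2 with counts 2:0
  t2 <- codon_counts(list("TTTTTT"))
  r2 <- rscu(t2, code)
  expect_equal(unname(r2$rscu[["TTT"]]), 2)
  expect_equal(unname(r2$rscu[["TTC"]]), 0)
  # Leu is one family of six, Ser one family of eight
  fams <- split(names(code$codon_to_aa)[code$codon_to_aa != "*"],
                code$codon_to_aa[code$codon_to_aa != "*"])
  expect_length(fams$L, 6)
  expect_length(fams$S, 8)

  # random codon sets: family sums equal family sizes; values match the
  # independent counting pass
  set.seed(33)
  for (i in 1:5) {
    codons <- sample(names(code$codon_to_aa), 500, replace = TRUE)
    tab <- rscu(codon_counts(list(paste(codons, collapse = ""))), code)
    counted <- codons
    if (codons[500] %in% c("TAA", "TAG")) counted <- codons[-500]
    ref <- oracle_rscu(counted)
    expect_equal(tab$rscu[names(ref)], ref, tolerance = 1e-12)
    for (f in fams) {
      if (sum(tab$counts[f]) > 0) {
        expect_equal(sum(tab$rscu[f]), length(f))
      }
    }
  }
})

test_that("amino-acid frequencies sum to 100 and behave under uniform sampling", {
  expect_equal(unname(aa_frequencies(list("ATGTAA"))["M"]), 100)
  set.seed(34)
  code <- genetic_code()
  non_stop <- names(code$codon_to_aa)[code$codon_to_aa != "*"]
  codons <- sample(non_stop, 20000, replace = TRUE)
  freq <- aa_frequencies(list(paste(codons, collapse = "")), code)
  expect_equal(sum(freq), 100)
  # uniform codon draws: each amino acid's percent ~ family_size/62 * 100
  fams <- table(code$codon_to_aa[non_stop])
  for (aa in names(fams)) {
    expect_lt(abs(freq[[aa]] - 100 * fams[[aa]] / 62), 1.5)
  }
})

test_that("start/stop report covers every PCG exactly once", {
  sim <- generate_mitogenome(genome_spec(), seed = 41)
  rep <- start_stop_report(sim$genome)
  pcg <- sim$genome$features$name[sim$genome$features$kind == "PCG"]
  expect_setequal(rep$gene, pcg)
  expect_equal(anyDuplicated(rep$gene), 0L)
  truth <- sim$truth$pcg
  m <- match(rep$gene, truth$name)
  expect_equal(rep$start_codon, truth$start_codon[m])
  expect_equal(rep$stop_class == "incomplete_T", truth$stop_class[m] == "T")
})
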