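# One-command characterization: runs every stage in fixed order and returns a
# single report object; JSON is the canonical serialized form, TSVs are
# projections of it. The report contains no timestamps, so identical inputs
# and options yield byte-identical output.

#' Characterize an annotated mitogenome
#'
#' Runs the full pipeline: genome summary, composition by partition,
#' start/stop classification, codon usage and RSCU, tRNA cloverleaf folding
#' with a mismatch census, the spacer/overlap catalog, and repeat, poly-tract
#' and motif scans over the non-coding sequence. Sections whose inputs are
#' missing (e.g. an annotation-free FASTA) are marked absent with a reason
#' rather than failing.
#'
#' @param input An `AnnotatedMitogenome`, or a path to a GenBank flat file or
#'   FASTA (detected from content).
#' @param outdir Optional directory; when given, writes `report.json` plus TSV
#'   projections and a dot-bracket structure file.
#' @param code Genetic code name for [genetic_code()].
#' @param min_spacer Minimum spacer length to report (bp).
#' @param motifs Motifs to scan for in non-coding sequence.
#' @param max_mismatch Maximum Hamming distance for motif hits.
#' @return A `CharacterizationReport` (list of sections).
#' @export
characterize <- function(input, outdir = NULL, code = "invertebrate",
                         min_spacer = 1L, motifs = "ATACTAA",
                         max_mismatch = 1L) {
  genome <- if (inherits(input, "AnnotatedMitogenome")) input else {
    first <- readLines(input, n = 1L, warn = FALSE)
    if (startsWith(first, "LOCUS")) read_genbank(input)
    else read_fasta_genome(input)
  }
  f <- genome$features
  gcode <- genetic_code(code)
  absent <- function(reason) list(absent = TRUE, reason = reason)

  report <- list()
  report$summary <- list(
    id = genome$id, length_bp = genome$length, topology = genome$topology,
    n_features = nrow(f),
    n_pcg = sum(f$kind == "PCG"), n_trna = sum(f$kind == "tRNA"),
    n_rrna = sum(f$kind == "rRNA"), n_control = sum(f$kind == "control"),
    n_j_strand = sum(f$strand == "J"), n_n_strand = sum(f$strand == "N"),
    n_trna_j = sum(f$strand == "J" & f$kind == "tRNA"),
    n_trna_n = sum(f$strand == "N" & f$kind == "tRNA")
  )

  comp <- partition_composition(genome)
  report$composition <- composition_table(comp)
  report$composition_absent <- attr(comp, "absent")

  # control-region fallback: when no A+T-rich feature is annotated, the
  # largest unannotated gap stands in for the control region
  if (!any(f$kind == "control") && nrow(f) >= 2L) {
    sp0 <- suppressWarnings(catalog_spacers_overlaps(genome))$spacers
    if (nrow(sp0)) {
      big <- sp0[which.max(sp0$length), ]
      message("no control-region feature annotated; using the largest ",
              "unannotated gap (", big$left, "-", big$right, ", ",
              big$length, " bp) as the control region")
      ctrl <- base_composition(big$seq)
      row <- data.frame(partition = "control", A = ctrl$counts[["A"]],
                        C = ctrl$counts[["C"]], G = ctrl$counts[["G"]],
                        T = ctrl$counts[["T"]], denominator = ctrl$denominator,
                        at_percent = ctrl$at_percent,
                        gc_percent = ctrl$gc_percent, at_skew = ctrl$at_skew,
                        gc_skew = ctrl$gc_skew, stringsAsFactors = FALSE)
      report$composition <- rbind(report$composition, row)
      report$composition_absent <- setdiff(report$composition_absent, "control")
      report$control_fallback <- list(left = big$left, right = big$right,
                                      start = big$start, length = big$length)
    }
  }

  if (any(f$kind == "PCG")) {
    report$start_stop <- start_stop_report(genome)
    usage <- codon_usage(genome, gcode)
    report$codon_usage <- as.data.frame(usage, code = gcode)
    report$aa_percent <- as.list(usage$aa_percent)
    report$n_codons <- usage$n_codons
    report$absent_codons <- names(usage$counts)[
      usage$counts == 0 & gcode$codon_to_aa[names(usage$counts)] != "*"]
  } else {
    report$start_stop <- absent("no protein-coding features annotated")
    report$codon_usage <- absent("no protein-coding features annotated")
  }

  trna_names <- f$name[f$kind == "tRNA"]
  if (length(trna_names)) {
    folds <- list()
    rows <- list()
    for (nm in trna_names) {
      sq <- extract_feature_sequence(genome, nm)
      hint <- if (nm %in% names(.trna_anticodon)) .trna_anticodon[[nm]] else NULL
      fold <- if (nchar(sq) >= 55L && nchar(sq) <= 90L) {
        fold_cloverleaf(sq, expected_anticodon = hint, allow_dhu_less = TRUE)
      } else {
        structure(list(seq = sq, length = nchar(sq), topology = "unfoldable",
                       pairs = NULL, anticodon = NA_character_, score = 0L,
                       n_wc = 0L, n_gu = 0L, n_mismatch = NA_integer_),
                  class = "TrnaFold")
      }
      folds[[nm]] <- fold
      rows[[nm]] <- data.frame(
        name = nm, length = nchar(sq), anticodon = fold$anticodon,
        topology = fold$topology,
        unmatched = if (is.na(fold$n_mismatch)) NA_integer_ else
          fold$n_mismatch + fold$n_gu,
        gu = fold$n_gu, stringsAsFactors = FALSE)
    }
    report$trna <- do.call(rbind, rows)
    census <- census_mismatches(folds)
    report$trna_census <- list(total = census$total,
                               by_arm = as.list(census$by_arm),
                               n_gu = census$n_gu,
                               by_class = as.list(census$by_class))
    attr(report, "folds") <- folds
  } else {
    report$trna <- absent("no tRNA features annotated")
  }

  if (nrow(f) >= 2L) {
    cat_so <- catalog_spacers_overlaps(genome)
    sp <- cat_so$spacers
    report$spacers <- sp[sp$length >= min_spacer, , drop = FALSE]
    report$overlaps <- cat_so$overlaps
    report$total_overlap_bp <- cat_so$total_overlap_bp
    report$accounting <- circle_accounting(genome, cat_so)

    # non-coding scans: control region plus every spacer
    regions <- list()
    ctrl <- f[f$kind == "control", , drop = FALSE]
    for (i in seq_len(nrow(ctrl))) {
      regions[[ctrl$name[i]]] <- list(
        seq = extract_feature_sequence(genome, ctrl$name[i]),
        offset = ctrl$start[i])
    }
    for (i in seq_len(nrow(sp))) {
      regions[[paste0(sp$left[i], "|", sp$right[i])]] <-
        list(seq = sp$seq[i], offset = sp$start[i])
    }
    reps <- list(); tracts <- list(); mots <- list()
    for (rn in names(regions)) {
      rg <- regions[[rn]]
      r <- find_tandem_repeats(rg$seq)
      if (nrow(r)) {
        r$region <- rn
        r$genome_start <- rg$offset + r$start - 1L
        reps[[rn]] <- r
      }
      for (b in c("A", "T")) {
        tr <- find_poly_tracts(rg$seq, b, min_len = 8L)
        if (nrow(tr)) {
          tr$base <- b; tr$region <- rn
          tr$genome_start <- rg$offset + tr$start - 1L
          tracts[[paste(rn, b)]] <- tr
        }
      }
      for (mo in motifs) {
        mh <- find_motif(rg$seq, mo, max_mismatches = max_mismatch)
        if (nrow(mh)) {
          mh$motif <- mo; mh$region <- rn
          mh$genome_start <- rg$offset + mh$start - 1L
          mots[[paste(rn, mo)]] <- mh
        }
      }
    }
    bind0 <- function(x, cols) if (length(x)) do.call(rbind, x) else
      stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
    report$repeats <- bind0(reps, c("start", "end", "unit", "canonical_unit",
                                    "unit_len", "copies", "region",
                                    "genome_start"))
    report$tracts <- bind0(tracts, c("start", "end", "length", "base",
                                     "region", "genome_start"))
    report$motifs <- bind0(mots, c("start", "match", "mismatches", "strand",
                                   "motif", "region", "genome_start"))
  } else {
    report$spacers <- absent("fewer than two features annotated")
    report$overlaps <- absent("fewer than two features annotated")
  }

  class(report) <- "CharacterizationReport"
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.CharacterizationReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CharacterizationReport: %s (%s bp, %s)\n", s$id,
              format(s$length_bp, big.mark = ","), s$topology))
  cat(sprintf("  %d features: %d PCG, %d tRNA, %d rRNA, %d control\n",
              s$n_features, s$n_pcg, s$n_trna, s$n_rrna, s$n_control))
  invisible(x)
}

is_absent <- function(section) {
  is.list(section) && isTRUE(section$absent)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  payload <- unclass(report)
  attr(payload, "folds") <- NULL
  jsonlite::write_json(payload, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  dump_tsv <- function(section, file) {
    if (is.data.frame(section)) {
      utils::write.table(section, file.path(outdir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  dump_tsv(report$composition, "composition.tsv")
  dump_tsv(report$start_stop, "start_stop.tsv")
  dump_tsv(report$codon_usage, "codon_usage.tsv")
  dump_tsv(report$trna, "trna.tsv")
  dump_tsv(report$spacers, "spacers.tsv")
  dump_tsv(report$overlaps, "overlaps.tsv")
  dump_tsv(report$repeats, "repeats.tsv")
  dump_tsv(report$motifs, "motifs.tsv")
  folds <- attr(report, "folds")
  if (!is.null(folds)) {
    lines <- character(0)
    for (nm in names(folds)) {
      fd <- folds[[nm]]
      if (fd$topology == "unfoldable") next
      lines <- c(lines, paste0(">", nm, " ", fd$topology), fd$seq,
                 to_dot_bracket(fd))
    }
    writeLines(lines, file.path(outdir, "trna_structures.txt"))
  }
  invisible(outdir)
}
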