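# Genome container, GenBank/FASTA+TSV input-output and circular coordinate
# handling. Internal convention: 0-based half-open coordinates on the stored
# forward strand; the stored forward strand is the J (majority) strand, the one
# that encodes cox1. A feature spanning the origin of a circular molecule is
# encoded with end > length.

#' Construct an annotated mitogenome
#'
#' The universal input of the characterization pipeline: a circular (or linear)
#' DNA sequence plus an ordered gene feature table.
#'
#' @param id Record identifier.
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param features `data.frame` with columns `name`, `kind`
#'   (`"PCG"`, `"tRNA"`, `"rRNA"` or `"control"`), `start` (0-based inclusive),
#'   `end` (exclusive, may exceed the genome length to encode a wrap across the
#'   origin) and `strand` (`"J"` majority / `"N"` minority).
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `AnnotatedMitogenome`.
#' @export
mitogenome <- function(id, seq, features, topology = "circular") {
  seq <- clean_dna(seq)
  n <- nchar(seq)
  stopifnot(is.character(id), length(id) == 1L, n > 0L)
  topology <- match.arg(topology, c("circular", "linear"))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("name", "kind", "start", "end", "strand")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  features <- features[, req, drop = FALSE]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (any(features$end <= features$start)) stop("feature end must exceed start")
    if (any(features$end - features$start > n)) stop("feature longer than genome")
    if (any(features$start < 0L | features$start >= n)) {
      stop("feature start outside [0, length)")
    }
    if (topology == "linear" && any(features$end > n)) {
      stop("wrapped feature on a linear molecule")
    }
    if (anyDuplicated(features$name)) {
      stop("feature names must be unique within a genome: ",
           paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
    }
    if (!all(features$kind %in% c("PCG", "tRNA", "rRNA", "control"))) {
      stop("feature kind must be PCG, tRNA, rRNA or control")
    }
    if (!all(features$strand %in% c("J", "N"))) stop("strand must be J or N")
    pcg <- features$kind == "PCG"
    if (any((features$end - features$start)[pcg] < 2L)) {
      stop("PCG features must span at least 2 bases")
    }
  }
  rownames(features) <- NULL
  structure(
    list(id = id, seq = seq, length = n, topology = topology,
         features = features),
    class = "AnnotatedMitogenome"
  )
}

#' @export
print.AnnotatedMitogenome <- function(x, ...) {
  cat(sprintf("AnnotatedMitogenome %s: %s bp, %s, %d features\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features)) {
    tab <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.AnnotatedMitogenome <- function(x) x$length

# ---------------------------------------------------------------------------
# Gene-name normalization

# Canonical symbols: nad1..nad6, nad4l, cox1..cox3, atp6, atp8, cob, rrnL,
# rrnS, AT_rich, trnX (with trnL1/trnL2 and trnS1/trnS2 disambiguated by the
# codon family they serve).
.aa3_to_trn <- c(
  Ala = "trnA", Arg = "trnR", Asn = "trnN", Asp = "trnD", Cys = "trnC",
  Gln = "trnQ", Glu = "trnE", Gly = "trnG", His = "trnH", Ile = "trnI",
  Lys = "trnK", Met = "trnM", Phe = "trnF", Pro = "trnP", Thr = "trnT",
  Trp = "trnW", Tyr = "trnY", Val = "trnV"
)

.gene_aliases <- local({
  a <- c(
    coi = "cox1", co1 = "cox1", coxi = "cox1", cox1 = "cox1",
    coii = "cox2", co2 = "cox2", coxii = "cox2", cox2 = "cox2",
    coiii = "cox3", co3 = "cox3", coxiii = "cox3", cox3 = "cox3",
    cytb = "cob", cob = "cob", cytochromeb = "cob",
    nd1 = "nad1", nad1 = "nad1", nd2 = "nad2", nad2 = "nad2",
    nd3 = "nad3", nad3 = "nad3", nd4 = "nad4", nad4 = "nad4",
    nd4l = "nad4l", nad4l = "nad4l", nd5 = "nad5", nad5 = "nad5",
    nd6 = "nad6", nad6 = "nad6",
    atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
    `16s` = "rrnL", lrrna = "rrnL", rrnl = "rrnL", lsu = "rrnL",
    `16srrna` = "rrnL", `16sribosomalrna` = "rrnL",
    `12s` = "rrnS", srrna = "rrnS", rrns = "rrnS", ssu = "rrnS",
    `12srrna` = "rrnS", `12sribosomalrna` = "rrnS",
    dloop = "AT_rich", atrich = "AT_rich", atrichregion = "AT_rich",
    at_rich = "AT_rich", controlregion = "AT_rich", atregion = "AT_rich"
  )
  a
})

squash <- function(x) gsub("[^a-z0-9_]", "", tolower(x))

#' Normalize a gene name to its canonical mitochondrial symbol
#'
#' Maps the common aliases found in GenBank records (COI, ND2, 16S rRNA,
#' tRNA-Met products, D-loop, ...) onto the canonical symbols `cox1`, `nad2`,
#' `rrnL`, `trnM`, `AT_rich`, .... tRNA-Leu and tRNA-Ser are disambiguated to
#' `trnL1(CUN)`/`trnL2(UUR)` and `trnS1(AGN)`/`trnS2(UCN)` using the codon
#' family in the product/note or the anticodon when available.
#'
#' @param name Gene name (e.g. the `/gene` qualifier), may be `NA`.
#' @param product Optional `/product` qualifier (e.g. `"tRNA-Met"`).
#' @param anticodon Optional anticodon triplet (DNA alphabet).
#' @return Canonical symbol, or the verbatim input (with a warning from the
#'   reader) when no alias matches.
#' @export
normalize_gene_name <- function(name, product = NULL, anticodon = NULL) {
  cand <- c(name, product)
  cand <- cand[!is.na(cand) & nzchar(cand)]
  for (x in cand) {
    key <- squash(x)
    if (key %in% names(.gene_aliases)) return(unname(.gene_aliases[[key]]))
    # tRNA products/names like "tRNA-Met", "trnM", "tRNA-Leu(CUN)"
    m <- regmatches(x, regexec("t ?RNA[- ]?([A-Za-z]{3})", x))[[1]]
    if (length(m) == 2L) {
      aa <- paste0(toupper(substr(m[2], 1, 1)), tolower(substr(m[2], 2, 3)))
      fam <- toupper(gsub(".*\\(([ACGTUNRWY]+)\\).*", "\\1",
                          ifelse(grepl("\\(", x), x, "")))
      if (aa %in% names(.aa3_to_trn)) return(unname(.aa3_to_trn[[aa]]))
      if (aa == "Leu") {
        if (grepl("CUN|CTN", fam)) return("trnL1(CUN)")
        if (grepl("UUR|TTR", fam)) return("trnL2(UUR)")
        if (!is.null(anticodon)) {
          ac <- chartr("U", "T", toupper(anticodon))
          if (ac == "TAG") return("trnL1(CUN)")
          if (ac == "TAA") return("trnL2(UUR)")
        }
      }
      if (aa == "Ser") {
        if (grepl("AGN|AGY|AGR", fam)) return("trnS1(AGN)")
        if (grepl("UCN|TCN", fam)) return("trnS2(UCN)")
        if (!is.null(anticodon)) {
          ac <- chartr("U", "T", toupper(anticodon))
          if (ac == "GCT") return("trnS1(AGN)")
          if (ac == "TGA") return("trnS2(UCN)")
        }
      }
    }
    m2 <- regmatches(x, regexec("^trn([A-Z])([12])?(\\(.*\\))?$", x))[[1]]
    if (length(m2) >= 2L) return(x)  # already canonical-style
  }
  if (length(cand)) cand[[1]] else NA_character_
}

.canonical_names <- c(
  "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
  "cox1", "cox2", "cox3", "atp6", "atp8", "cob", "rrnL", "rrnS", "AT_rich",
  unname(.aa3_to_trn), "trnL1(CUN)", "trnL2(UUR)", "trnS1(AGN)", "trnS2(UCN)"
)

# ---------------------------------------------------------------------------
# GenBank flat-file reader/writer (single record). No installed R package
# parses local flat files, so a minimal codec for the subset used by
# mitogenome records (LOCUS/FEATURES/ORIGIN, complement/join locations) lives
# here.

parse_gb_location <- function(loc, genome_len) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "J"
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  segs <- strsplit(loc, ",", fixed = TRUE)[[1]]
  parse_seg <- function(s) {
    if (grepl("\\.\\.", s)) {
      p <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    } else {
      p <- c(as.integer(s), as.integer(s))
    }
    if (anyNA(p) || p[2] < p[1]) stop("unparseable location segment: ", s)
    c(p[1] - 1L, p[2])  # 0-based half-open
  }
  segs <- lapply(segs, parse_seg)
  start <- segs[[1]][1]
  total <- sum(vapply(segs, function(s) s[2] - s[1], integer(1)))
  if (length(segs) > 1L) {
    # require contiguity on the circle (mitogenome joins only wrap the origin)
    pos <- segs[[1]][2]
    for (s in segs[-1]) {
      if (s[1] != pos %% genome_len) {
        stop("non-contiguous join location (introns are unsupported): ", loc)
      }
      pos <- s[2]
    }
  }
  list(start = start, end = start + total, strand = strand)
}

.gb_kind_from_key <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       `D-loop` = "control", misc_feature = "control")

#' Read a single-record GenBank flat file
#'
#' Parses LOCUS, the feature table and ORIGIN into an [mitogenome()]. GenBank
#' 1-based inclusive coordinates become 0-based half-open; `complement(...)`
#' features are assigned strand `N`; `join(...)` locations wrapping the origin
#' are encoded with `end > length`. Gene names are normalized to canonical
#' symbols via [normalize_gene_name()]; unknown aliases are kept verbatim with
#' a warning (never dropped).
#'
#' @param path Path to a GenBank flat file containing exactly one record.
#' @return An `AnnotatedMitogenome`.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^LOCUS", lines)) != 1L) {
    stop("expected exactly one LOCUS record in ", path)
  }
  locus <- lines[grepl("^LOCUS", lines)][1]
  len <- as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus))
  topology <- if (grepl("circular", locus, ignore.case = TRUE)) "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  acc <- lines[grepl("^ACCESSION", lines)]
  if (length(acc)) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("record has no ORIGIN sequence")
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  term <- grep("^//", seq_lines)
  if (length(term)) seq_lines <- seq_lines[seq_len(term[1] - 1L)]
  seq <- clean_dna(paste(seq_lines, collapse = ""))
  if (!is.na(len) && nchar(seq) != len) {
    stop("ORIGIN sequence length (", nchar(seq), ") disagrees with LOCUS (", len, ")")
  }
  n <- nchar(seq)

  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    cur <- NULL
    in_location <- FALSE
    for (ln in block) {
      m <- regmatches(ln, regexec("^ {1,10}(\\S+)\\s+(\\S.*)$", ln))[[1]]
      if (length(m) == 3L && !startsWith(m[2], "/")) {
        if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
        cur <- list(key = m[2], location = m[3], quals = character(0))
        in_location <- TRUE
        next
      }
      body <- trimws(ln)
      if (is.null(cur) || !nzchar(body)) next
      if (startsWith(body, "/")) {
        cur$quals <- c(cur$quals, body)
        in_location <- FALSE
      } else if (in_location) {
        cur$location <- paste0(cur$location, body)
      } else if (length(cur$quals)) {
        cur$quals[length(cur$quals)] <- paste(cur$quals[length(cur$quals)], body)
      }
    }
    if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  }

  get_qual <- function(f, name) {
    hit <- grep(paste0("^/", name, "="), f$quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  rows <- list()
  seen <- character(0)
  for (f in feats) {
    if (f$key %in% c("source", "gene")) next
    kind <- .gb_kind_from_key[f$key]
    if (is.na(kind)) {
      warning("skipping unsupported feature key: ", f$key)
      next
    }
    loc <- parse_gb_location(f$location, n)
    if (loc$end - loc$start > n || loc$start < 0L || loc$start >= n + (loc$end - loc$start)) {
      stop("feature outside sequence: ", f$location)
    }
    if (loc$start >= n) stop("feature outside sequence: ", f$location)
    gene <- get_qual(f, "gene")
    product <- get_qual(f, "product")
    note <- get_qual(f, "note")
    anticodon <- get_qual(f, "anticodon")
    nm <- normalize_gene_name(gene, product %||% note, anticodon)
    if (is.na(nm) || !nzchar(nm)) nm <- paste0(f$key, "_", length(rows) + 1L)
    if (!nm %in% .canonical_names && !grepl("^trn", nm)) {
      warning("unknown gene alias kept verbatim: ", nm,
              " (kind inferred from feature key ", f$key, ")")
    }
    if (nm %in% seen) next  # duplicate annotation (e.g. gene + CDS pairs)
    seen <- c(seen, nm)
    rows[[length(rows) + 1L]] <- data.frame(
      name = nm, kind = unname(kind), start = loc$start, end = loc$end,
      strand = loc$strand, stringsAsFactors = FALSE
    )
  }
  features <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), kind = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  mitogenome(id, seq, features, topology)
}

format_gb_location <- function(start, end, strand, n) {
  loc <- if (end <= n) {
    sprintf("%d..%d", start + 1L, end)
  } else {
    sprintf("join(%d..%d,1..%d)", start + 1L, n, end - n)
  }
  if (strand == "N") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a genome as a single-record GenBank flat file
#'
#' Inverse of [read_genbank()]: coordinates are emitted 1-based inclusive,
#' strand-`N` features as `complement(...)`, wrapped features as origin-spanning
#' `join(...)`. Round trip through [read_genbank()] preserves the sequence and
#' every feature's coordinates.
#'
#' @param genome `AnnotatedMitogenome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- genome$length
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control = "misc_feature")
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s INV",
                   genome$id, n, genome$topology),
           sprintf("DEFINITION  %s mitochondrial genome.", genome$id),
           sprintf("ACCESSION   %s", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- format_gb_location(f$start[i], f$end[i], f$strand[i], n)
    out <- c(out,
             sprintf("     %-15s %s", key_of[[f$kind[i]]], loc),
             sprintf("                     /gene=\"%s\"", f$name[i]))
    if (f$kind[i] == "control") {
      out <- c(out, "                     /note=\"A+T rich region\"")
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$seq)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", off, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read a genome from FASTA plus a TSV feature table
#'
#' Alternative input route: the sequence from a single-record FASTA and the
#' features from a tab-separated table with columns `name`, `kind`, `start`
#' (1-based inclusive), `end` (inclusive) and `strand` (`+`/`-`). The table may
#' be omitted, yielding an annotation-free genome usable only by the
#' composition stage.
#'
#' @param fasta Path to a FASTA file with one sequence.
#' @param table Optional path to the feature TSV.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An `AnnotatedMitogenome`.
#' @export
read_fasta_genome <- function(fasta, table = NULL, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected exactly one FASTA record")
  id <- strsplit(names(ss)[1], "\\s+")[[1]][1]
  seq <- as.character(ss[[1]])
  if (is.null(table)) {
    feats <- data.frame(name = character(0), kind = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
  } else {
    tab <- utils::read.delim(table, stringsAsFactors = FALSE)
    feats <- data.frame(
      name = tab$name, kind = tab$kind,
      start = as.integer(tab$start) - 1L, end = as.integer(tab$end),
      strand = ifelse(tab$strand %in% c("+", "J"), "J", "N"),
      stringsAsFactors = FALSE
    )
  }
  mitogenome(id, seq, feats, topology)
}

#' Write the normalized feature table as TSV
#'
#' Coordinates are written 1-based inclusive with `+`/`-` strands, matching the
#' [read_fasta_genome()] input format.
#'
#' @param genome `AnnotatedMitogenome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(genome, path) {
  f <- genome$features
  out <- data.frame(
    name = f$name, kind = f$kind, start = f$start + 1L, end = f$end,
    strand = ifelse(f$strand == "J", "+", "-"), stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the genome sequence as FASTA
#'
#' @param genome `AnnotatedMitogenome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Extract the reading-direction sequence of a feature
#'
#' Forward slice with modular indexing for origin-wrapping features;
#' reverse-complemented for strand-`N` features so the result always reads
#' 5'->3' in the gene's own direction.
#'
#' @param genome `AnnotatedMitogenome`.
#' @param feature A feature name, or a list/one-row data frame with `start`,
#'   `end`, `strand`.
#' @return DNA string of length `end - start`.
#' @export
extract_feature_sequence <- function(genome, feature) {
  if (is.character(feature) && length(feature) == 1L) {
    i <- match(feature, genome$features$name)
    if (is.na(i)) stop("no feature named ", feature)
    feature <- genome$features[i, ]
  }
  s <- circular_substr(genome$seq, feature$start, feature$end)
  if (identical(feature$strand, "N") || identical(feature$strand, "-")) {
    s <- revcomp(s)
  }
  s
}

# ---------------------------------------------------------------------------
# Gene-order comparison on the circle

rotations_equal <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  if (!length(x)) return(TRUE)
  hay <- paste0("\r", paste(c(y, y), collapse = "\r"), "\r")
  needle <- paste0("\r", paste(x, collapse = "\r"), "\r")
  grepl(needle, hay, fixed = TRUE)
}

lcs_length <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) return(0L)
  prev <- integer(ny + 1L)
  for (i in seq_len(nx)) {
    cur <- integer(ny + 1L)
    eq <- x[i] == y
    for (j in seq_len(ny)) {
      cur[j + 1L] <- if (eq[j]) prev[j] + 1L else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[ny + 1L]
}

#' Compare two circular gene orders
#'
#' Reports whether two gene orders are identical up to rotation of the circle
#' and, when they are not, the minimal set of genes whose removal (from both)
#' makes them so. Ties between equally small sets are broken by the
#' alphabetically first displaced name. Names present in only one order are
#' reported separately and excluded from the comparison.
#'
#' @param a,b Character vectors of gene names in circular order, or
#'   `AnnotatedMitogenome` objects (feature order by start coordinate).
#' @return A list with `identical` (flag), `displaced` (character vector),
#'   `only_in_a`, `only_in_b`.
#' @export
compare_gene_order <- function(a, b) {
  get_order <- function(x) {
    if (inherits(x, "AnnotatedMitogenome")) {
      x$features$name[order(x$features$start)]
    } else as.character(x)
  }
  a <- get_order(a); b <- get_order(b)
  shared <- intersect(a, b)
  fa <- a[a %in% shared]
  fb <- b[b %in% shared]
  res <- list(identical = FALSE, displaced = character(0),
              only_in_a = setdiff(a, b), only_in_b = setdiff(b, a))
  if (rotations_equal(fa, fb)) {
    res$identical <- TRUE
    return(res)
  }
  pool <- sort(shared)
  # smallest removal set, searched in lexicographic order of sorted names so
  # that equally small sets resolve to the alphabetically first one
  for (d in seq_len(min(4L, length(pool)))) {
    sets <- utils::combn(pool, d, simplify = FALSE)
    for (drop in sets) {
      if (rotations_equal(fa[!fa %in% drop], fb[!fb %in% drop])) {
        res$displaced <- drop
        return(res)
      }
    }
  }
  # large rearrangements: fall back to a rotation-scanned longest common
  # subsequence; the displaced set is everything outside the best LCS
  best <- 0L; best_rot <- fa
  n <- length(fa)
  for (r in seq_len(n) - 1L) {
    rot <- c(fa[-seq_len(r)], fa[seq_len(r)])
    l <- lcs_length(rot, fb)
    if (l > best) { best <- l; best_rot <- rot }
  }
  # reconstruct one optimal keep-set from the best rotation
  keep <- lcs_set(best_rot, fb)
  res$displaced <- sort(setdiff(shared, keep))
  res
}

lcs_set <- function(x, y) {
  nx <- length(x); ny <- length(y)
  L <- matrix(0L, nx + 1L, ny + 1L)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    L[i + 1L, j + 1L] <- if (x[i] == y[j]) L[i, j] + 1L else
      max(L[i, j + 1L], L[i + 1L, j])
  }
  keep <- character(0)
  i <- nx; j <- ny
  while (i > 0L && j > 0L) {
    if (x[i] == y[j]) { keep <- c(x[i], keep); i <- i - 1L; j <- j - 1L }
    else if (L[i, j + 1L] >= L[i + 1L, j]) i <- i - 1L
    else j <- j - 1L
  }
  keep
}

# ---------------------------------------------------------------------------

#' Locate the deposited reference record, if available
#'
#' The study this package characterizes deposited its genome in GenBank as
#' HQ897685. The record is not redistributed with the package; to reproduce the
#' published numbers, download the flat file and point to it via
#' `options(mitochar.hq897685 = "<path>")`, the `MITOCHAR_HQ897685` environment
#' variable, or by placing it at `inst/extdata/HQ897685.gb` before
#' installation.
#'
#' @return Path to the flat file.
#' @export
deposited_record_path <- function() {
  p <- getOption("mitochar.hq897685", Sys.getenv("MITOCHAR_HQ897685", ""))
  if (nzchar(p) && file.exists(p)) return(p)
  p <- system.file("extdata", "HQ897685.gb", package = "mitochar")
  if (nzchar(p) && file.exists(p)) return(p)
  stop("the deposited GenBank record HQ897685 is not available locally; ",
       "download the flat file from GenBank and set ",
       "options(mitochar.hq897685=...) or MITOCHAR_HQ897685")
}
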