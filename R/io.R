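#' Read GWAS or eQTL summary statistics
#'
#' Reads a TSV of per-variant association statistics. Mandatory columns are
#' `chrom, pos, ref, alt, effect_allele, beta, se, pvalue`; eQTL files
#' additionally require `gene_id, tissue, source`. Indel rows (either allele
#' longer than one nucleotide) are dropped with a logged count, mirroring a
#' SNP-only analysis; rows with `se <= 0` are rejected with a reason. The
#' Z-score is always recomputed as beta/se.
#'
#' @param path TSV file path.
#' @param trait_kind `"gwas"` or `"eqtl"`.
#' @return data.frame of association records (one row per SNP) with columns
#'   chrom, pos, ref, alt, vid, rsid, effect_allele, beta, se, pvalue, z,
#'   ambiguous, gene_id, tissue, source, and a `"dropped"` attribute with
#'   the per-reason drop counts.
#' @export
readSummaryStats <- function(path, trait_kind = c("gwas", "eqtl")) {
  trait_kind <- match.arg(trait_kind)
  # allele columns must stay character: a column of all "T" would
  # otherwise be read as logical TRUE
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", ref = "character",
                                 alt = "character",
                                 effect_allele = "character"))
  mandatory <- c("chrom", "pos", "ref", "alt", "effect_allele", "beta",
                 "se", "pvalue")
  if (trait_kind == "eqtl")
    mandatory <- c(mandatory, "gene_id", "tissue", "source")
  missing <- setdiff(mandatory, names(x))
  if (length(missing))
    stop("summary-statistics file ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  dropped <- list(indel = 0L, bad_se = 0L)
  if (nrow(x)) {
    indel <- nchar(x$ref) != 1L | nchar(x$alt) != 1L
    dropped$indel <- sum(indel)
    if (dropped$indel)
      message("readSummaryStats: dropped ", dropped$indel,
              " indel row(s); analysis is SNP-only")
    x <- x[!indel, , drop = FALSE]
    bad <- !is.finite(x$se) | x$se <= 0
    dropped$bad_se <- sum(bad)
    if (dropped$bad_se)
      message("readSummaryStats: rejected ", dropped$bad_se,
              " row(s) with se <= 0")
    x <- x[!bad, , drop = FALSE]
  }
  if (!nrow(x)) {
    out <- assocRecords(character(), integer(), character(), character(),
                        character(), numeric(), numeric(), numeric())
  } else {
    out <- assocRecords(
      chrom = as.character(x$chrom), pos = x$pos, ref = x$ref, alt = x$alt,
      effect_allele = x$effect_allele, beta = x$beta, se = x$se,
      pvalue = x$pvalue,
      rsid = if ("rsid" %in% names(x)) as.character(x$rsid) else NA_character_,
      gene_id = if ("gene_id" %in% names(x)) as.character(x$gene_id)
                else NA_character_,
      tissue = if ("tissue" %in% names(x)) as.character(x$tissue)
               else NA_character_,
      source = if ("source" %in% names(x)) as.character(x$source)
               else NA_character_)
  }
  attr(out, "dropped") <- dropped
  out
}

#' @rdname readSummaryStats
#' @param records association record data.frame.
#' @export
writeSummaryStats <- function(records, path) {
  cols <- c("chrom", "pos", "ref", "alt", "rsid", "effect_allele", "beta",
            "se", "pvalue", "gene_id", "tissue", "source")
  write.table(records[, intersect(cols, names(records)), drop = FALSE],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split the "dataset|tissue|class" name dialect into mcols
.parseTrackName <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)
  pad <- function(p) c(p, rep(NA_character_, max(0L, 3L - length(p))))[1:3]
  m <- do.call(rbind, lapply(parts, pad))
  data.frame(dataset = m[, 1], tissue = m[, 2], class_label = m[, 3],
             stringsAsFactors = FALSE)
}

#' Read an annotation track (BED4+)
#'
#' BED intervals (0-based half-open on disk) are imported through
#' `rtracklayer` into 1-based closed `GRanges`. The name field carries the
#' package's track dialect `"dataset|tissue|class"`, split into metadata
#' columns. Zero- or negative-length intervals are a format error.
#'
#' @param path BED file.
#' @return `GRanges` with mcols `dataset`, `tissue`, `class_label`.
#' @export
readBedTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  bad <- which(GenomicRanges::width(gr) < 1L)
  if (length(bad))
    stop("zero-length interval(s) in ", path, " at line(s): ",
         paste(bad, collapse = ", "))
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  meta <- .parseTrackName(ifelse(is.na(nm), "NA|NA|NA", nm))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  gr
}

#' @rdname readBedTrack
#' @param gr `GRanges` with the track mcols.
#' @export
writeBedTrack <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  out$name <- paste(gr$dataset, gr$tissue, gr$class_label, sep = "|")
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read gene models from BED12
#'
#' One transcript per line; blocks are exons, the thick region is the CDS.
#' The name field encodes `"gene_id|biotype"` (biotype `mRNA` or `lncRNA`).
#' The transcription start site is the 5'-most transcript boundary with
#' respect to strand.
#'
#' @param path BED12 file.
#' @return `GRanges` (transcript spans) with mcols `gene_id`, `biotype`,
#'   `tss`, `thick` (CDS span) and `blocks` (exon `IRangesList`, genome
#'   coordinates).
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$blocks))
    stop("gene-model file ", path, " is not BED12 (no block fields)")
  if (any(lengths(gr$blocks) == 0L))
    stop("gene model with no exons in ", path)
  nm <- strsplit(gr$name, "|", fixed = TRUE)
  gr$gene_id <- vapply(nm, `[`, "", 1L)
  gr$biotype <- vapply(nm, function(p) if (length(p) > 1L) p[2L] else "mRNA",
                       "")
  if (!all(gr$biotype %in% c("mRNA", "lncRNA")))
    stop("biotype must be mRNA or lncRNA")
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*"))
    stop("gene models must be stranded")
  gr$tss <- ifelse(st == "+", GenomicRanges::start(gr),
                   GenomicRanges::end(gr))
  # blocks come back transcript-relative; shift to genome coordinates
  gr$blocks <- IRanges::shift(gr$blocks, GenomicRanges::start(gr) - 1L)
  gr$name <- NULL
  gr
}

#' Read enhancer-promoter interactions (BEDPE)
#'
#' Standard 6+ column BEDPE; the 7th (name) column carries
#' `"assay|source|celltype"`. Anchors on chromosomes absent from
#' `validChroms` trigger a warning but the pair is kept.
#'
#' @param path BEDPE file.
#' @param validChroms optional character vector of known chromosomes.
#' @return a [S4Vectors::Pairs] of anchor `GRanges` with mcols `assay`,
#'   `source`, `celltype`.
#' @export
readBedpe <- function(path, validChroms = NULL) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 6L)
    stop("BEDPE file ", path, " must have at least 6 columns")
  if (any(x[[2]] >= x[[3]]) || any(x[[5]] >= x[[6]]))
    stop("zero-length anchor(s) in ", path)
  a1 <- GenomicRanges::GRanges(x[[1]],
          IRanges::IRanges(start = x[[2]] + 1L, end = x[[3]]))
  a2 <- GenomicRanges::GRanges(x[[4]],
          IRanges::IRanges(start = x[[5]] + 1L, end = x[[6]]))
  if (!is.null(validChroms)) {
    unk <- !(x[[1]] %in% validChroms) | !(x[[4]] %in% validChroms)
    if (any(unk))
      warning(sum(unk), " interaction(s) with anchor(s) on unknown ",
              "chromosomes; kept")
  }
  meta <- if (ncol(x) >= 7L) .parseTrackName(as.character(x[[7]]))
          else data.frame(dataset = NA_character_, tissue = NA_character_,
                          class_label = NA_character_)
  p <- S4Vectors::Pairs(a1, a2)
  S4Vectors::mcols(p) <- S4Vectors::DataFrame(
    assay = meta$dataset, source = meta$tissue, celltype = meta$class_label)
  p
}

#' @rdname readBedpe
#' @param pairs a `Pairs` object as returned by `readBedpe`.
#' @export
writeBedpe <- function(pairs, path) {
  a1 <- S4Vectors::first(pairs)
  a2 <- S4Vectors::second(pairs)
  m <- S4Vectors::mcols(pairs)
  df <- data.frame(
    as.character(GenomicRanges::seqnames(a1)),
    GenomicRanges::start(a1) - 1L, GenomicRanges::end(a1),
    as.character(GenomicRanges::seqnames(a2)),
    GenomicRanges::start(a2) - 1L, GenomicRanges::end(a2),
    paste(m$assay, m$source, m$celltype, sep = "|"),
    0L, ".", ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA
#'
#' One record per chromosome; record names are truncated at the first
#' whitespace. Sequence lookups downstream are 1-based.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readGenome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a motif library
#'
#' HOMER-like text: a header line `>consensus<TAB>name<TAB>threshold`
#' followed by one line per motif position with four probabilities
#' (A C G T). Probabilities are floored at `floor` and renormalized so no
#' log-odds is infinite. Duplicate motif names are an error.
#'
#' @param path motif text file.
#' @param floor probability smoothing floor.
#' @return list of motifs, each a list with `motif_id`, `consensus`,
#'   `threshold` and an L x 4 probability `matrix` (columns A,C,G,T).
#' @export
readMotifs <- function(path, floor = 0.001) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motifs in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- lapply(seq_along(starts), function(i) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\t")[[1]]
    if (length(hdr) < 2L)
      stop("motif header must be '>consensus<TAB>name[<TAB>threshold]'")
    body <- lines[(starts[i] + 1L):ends[i]]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "[\t ]+"), as.numeric))
    if (ncol(m) != 4L || anyNA(m))
      stop("motif '", hdr[2], "': each position needs 4 probabilities")
    m <- pmax(m, floor)
    m <- m / rowSums(m)
    colnames(m) <- NUCLEOTIDES
    list(motif_id = hdr[2], consensus = hdr[1],
         threshold = if (length(hdr) >= 3L) as.numeric(hdr[3]) else NA_real_,
         matrix = m)
  })
  ids <- vapply(motifs, `[[`, "", "motif_id")
  if (anyDuplicated(ids))
    stop("duplicate motif name(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(motifs) <- ids
  motifs
}

#' @rdname readMotifs
#' @param motifs motif list as returned by `readMotifs`.
#' @export
writeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    thr <- if (is.na(m$threshold)) "" else paste0("\t", m$threshold)
    writeLines(paste0(">", m$consensus, "\t", m$motif_id, thr), con)
    apply(m$matrix, 1L, function(row)
      writeLines(paste(format(row, digits = 10), collapse = "\t"), con))
  }
  invisible(path)
}

#' Write the report bundle
#'
#' Writes each table as TSV plus a JSON run summary carrying the per-stage
#' counts (regions, variants, pairs, genes) and the configuration echo.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @param summary list serialized to `run_summary.json`.
#' @return invisible vector of file paths.
#' @export
writeReport <- function(tables, dir, summary = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, "")
  jp <- file.path(dir, "run_summary.json")
  jsonlite::write_json(summary, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, jp))
}

#' Read/write a haplotype panel TSV
#'
#' Plain-text panel: columns `chrom, pos, ref, alt` then one 0/1 column per
#' haplotype (`hap1..hapN`).
#'
#' @param path TSV file.
#' @return a [HaplotypePanel-class].
#' @export
readHaplotypePanel <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character", ref = "character",
                                 alt = "character"))
  hapcols <- grep("^hap", names(x))
  if (!length(hapcols)) stop("no haplotype columns (hap*) in ", path)
  HaplotypePanel(chrom = x$chrom[1], positions = x$pos, ref = x$ref,
                 alt = x$alt, haplotypes = t(as.matrix(x[, hapcols])))
}

#' @rdname readHaplotypePanel
#' @param panel a `HaplotypePanel`.
#' @export
writeHaplotypePanel <- function(panel, path) {
  h <- t(haplotypeMatrix(panel))
  colnames(h) <- paste0("hap", seq_len(ncol(h)))
  df <- data.frame(chrom = panelChrom(panel), pos = panelPositions(panel),
                   ref = panel@ref, alt = panel@alt, h)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
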