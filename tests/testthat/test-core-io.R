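test_that("vid round-trips through parse/format and rejects malformed input", {
  v <- makeVid("chr7", 54880000, "A", "G")
  expect_identical(v, "chr7:54880000:A:G")
  p <- parseVid(v)
  expect_identical(makeVid(p$chrom, p$pos, p$ref, p$alt), v)
  expect_error(parseVid("chr1:100:A"), "malformed")
  expect_error(makeVid("chr1", 10, "A", "A"))
  expect_true(isStrandAmbiguous("A", "T"))
  expect_true(isStrandAmbiguous("C", "G"))
  expect_false(isStrandAmbiguous("A", "G"))
})

test_that("summary-stats reader drops indels, rejects bad se, recomputes z", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                   ref = c("A", "C", "G", "AT"), alt = c("G", "T", "A", "A"),
                   effect_allele = c("G", "T", "A", "A"),
                   beta = c(0.2, 0.1, -0.3, 0.5),
                   se = c(0.1, 0.05, 0.1, 0.1),
                   pvalue = c(0.04, 0.2, 0.002, 0.01))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec <- readSummaryStats(f, "gwas"), "1 indel")
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "dropped")$indel, 1L)
  expect_equal(rec$z[1], 2.0)  # z = beta/se
  expect_true(all(abs(rec$z - rec$beta / rec$se) < 1e-9))

  # empty file with a valid header is fine
  write.table(df[0, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_silent(rec0 <- readSummaryStats(f, "gwas"))
  expect_equal(nrow(rec0), 0)

  # missing mandatory column is a named format error
  write.table(df[, -6], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSummaryStats(f, "gwas"), "beta")

  # se <= 0 rows are rejected with a reason
  df2 <- df[1:2, ]; df2$se[2] <- 0
  write.table(df2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(rec2 <- readSummaryStats(f, "gwas"), "se <= 0")
  expect_equal(nrow(rec2), 1)
})

test_that("summary-stats writer/reader round-trips", {
  rec <- randomRecords(20, seed = 42)
  f <- tempfile(fileext = ".tsv")
  writeSummaryStats(rec, f)
  back <- readSummaryStats(f, "gwas")
  for (col in c("chrom", "pos", "ref", "alt", "effect_allele", "vid"))
    expect_identical(back[[col]], rec[[col]])
  expect_equal(back$beta, rec$beta)
  expect_equal(back$se, rec$se)
  expect_equal(back$z, rec$z)
})

test_that("BED track reader parses the dataset|tissue|class dialect", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tEpiMAP|brain_cortex|enhancer"), f)
  gr <- readBedTrack(f)
  expect_equal(gr$tissue, "brain_cortex")
  expect_equal(gr$dataset, "EpiMAP")
  expect_equal(GenomicRanges::start(gr), 101L)  # 1-based closed in memory
  expect_equal(GenomicRanges::end(gr), 200L)

  writeLines("chr1\t5\t5\tx", f)
  expect_error(readBedTrack(f), "zero-length")
})

test_that("BED track round-trips through write/read", {
  gr <- GenomicRanges::GRanges("chr2", IRanges::IRanges(c(11, 51), c(30, 99)),
                               dataset = c("d1", "d2"),
                               tissue = c("t1", "t2"),
                               class_label = c("enhancer", "ATAC"))
  f <- tempfile(fileext = ".bed")
  writeBedTrack(gr, f)
  back <- readBedTrack(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(back$tissue, gr$tissue)
  expect_identical(back$class_label, gr$class_label)
})

test_that("BED12 gene models expose exons, CDS and strand-aware TSS", {
  # 2-exon gene on +: tx chr1:101-400 (1-based), exons 101-200 and 301-400,
  # CDS 151-350 -> 5'UTR 101-150, 3'UTR 351-400
  f <- writeGeneBed(bed12Line("chr1", 100, 400, "GENEX|mRNA", "+", 150, 350,
                              c(100, 100), c(0, 200)))
  gm <- readGeneModels(f)
  expect_equal(gm$gene_id, "GENEX")
  expect_equal(gm$tss, 101L)
  ex <- gm$blocks[[1]]
  expect_equal(IRanges::start(ex), c(101L, 301L))
  expect_equal(IRanges::end(ex), c(200L, 400L))
  expect_equal(IRanges::start(gm$thick), 151L)
  expect_equal(IRanges::end(gm$thick), 350L)

  # minus-strand TSS is the right end
  f2 <- writeGeneBed(bed12Line("chr1", 100, 400, "GENEY|mRNA", "-", 150, 350,
                               c(100, 100), c(0, 200)))
  expect_equal(readGeneModels(f2)$tss, 400L)
})

test_that("BEDPE reader/writer round-trip; unknown chrom warns but keeps", {
  f <- tempfile(fileext = ".bedpe")
  writeLines("chr1\t100\t200\tchr1\t5000\t5100\tCaptureC|src1|microglia\t0\t.\t.",
             f)
  p <- readBedpe(f)
  expect_equal(length(p), 1L)
  expect_equal(GenomicRanges::start(S4Vectors::first(p)), 101L)
  expect_equal(S4Vectors::mcols(p)$assay, "CaptureC")
  expect_warning(readBedpe(f, validChroms = "chr9"), "unknown")

  f2 <- tempfile(fileext = ".bedpe")
  writeBedpe(p, f2)
  back <- readBedpe(f2)
  expect_equal(GenomicRanges::start(S4Vectors::first(back)),
               GenomicRanges::start(S4Vectors::first(p)))
  expect_equal(S4Vectors::mcols(back)$source, S4Vectors::mcols(p)$source)
})

test_that("FASTA lookup is 1-based identity; motif reader validates", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGT"), f)
  g <- readGenome(f)
  expect_identical(names(g), "chr1")
  expect_equal(as.character(Biostrings::subseq(g[["chr1"]], 1, 4)), "ACGT")

  mf <- tempfile(fileext = ".txt")
  writeLines(c(">AC\tM1\t5.0", "0.5 0.2 0.2 0.1", "0.1 0.5 0.2 0.2"), mf)
  m <- readMotifs(mf)
  expect_equal(length(m), 1L)
  expect_equal(nrow(m$M1$matrix), 2L)
  expect_true(all(abs(rowSums(m$M1$matrix) - 1) < 1e-6))

  writeLines(c(">AC\tM1", "0.5 0.2 0.2 0.1", ">GG\tM1", "0.1 0.1 0.7 0.1"),
             mf)
  expect_error(readMotifs(mf), "duplicate")

  # round-trip
  mf2 <- tempfile(fileext = ".txt")
  writeMotifs(m, mf2)
  m2 <- readMotifs(mf2)
  expect_equal(m2$M1$matrix, m$M1$matrix, tolerance = 1e-9)
})

test_that("haplotype panel round-trips through TSV", {
  pan <- generateHaplotypePanel(n_hap = 20, n_var = 10, seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeHaplotypePanel(pan, f)
  back <- readHaplotypePanel(f)
  expect_identical(haplotypeMatrix(back), haplotypeMatrix(pan))
  expect_identical(panelVids(back), panelVids(pan))
})

test_that("report writer emits TSVs and a JSON run summary", {
  d <- tempfile()
  writeReport(list(a = data.frame(x = 1:3)), d,
              summary = list(counts = list(regions = 2, variants = 9)))
  expect_true(file.exists(file.path(d, "a.tsv")))
  s <- jsonlite::read_json(file.path(d, "run_summary.json"))
  expect_equal(s$counts$regions, 2)
})
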