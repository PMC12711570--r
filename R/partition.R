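PARTITION_CLASSES <- c("utr5_exon", "utr5_intron", "utr3_exon",
                       "utr3_intron", "promoter", "mrna_exon", "mrna_intron")

# per-transcript feature ranges from a gene-model GRanges row set;
# per-gene interval arithmetic runs in plain IRanges (everything within a
# transcript shares one chromosome), assembled into one GRanges per class
.geneFeatures <- function(models) {
  st <- as.character(GenomicRanges::strand(models))
  chrom <- as.character(GenomicRanges::seqnames(models))
  nms <- c("utr5_exon", "utr5_intron", "utr3_exon", "utr3_intron",
           "promoter", "mrna_exon", "mrna_intron")
  acc <- setNames(vector("list", length(nms)), nms)
  addTo <- function(nm, ir, ch) {
    if (length(ir))
      acc[[nm]][[length(acc[[nm]]) + 1L]] <<- list(ch = ch, ir = ir)
  }
  for (i in seq_along(models)) {
    ex <- models$blocks[[i]]
    txs <- GenomicRanges::start(models)[i]
    txe <- GenomicRanges::end(models)[i]
    intr <- IRanges::setdiff(IRanges::IRanges(txs, txe), ex)
    addTo("mrna_exon", ex, chrom[i])
    addTo("mrna_intron", intr, chrom[i])
    # promoter: 1000 bp immediately upstream of the TSS, strand-aware
    tss <- models$tss[i]
    prom <- if (st[i] == "+")
      IRanges::IRanges(max(1L, tss - 1000L), tss - 1L)
    else IRanges::IRanges(tss + 1L, tss + 1000L)
    if (IRanges::width(prom) > 0L) addTo("promoter", prom, chrom[i])
    # UTR spans from the CDS (thick) region
    thick <- models$thick[i]
    if (length(thick) && IRanges::width(thick) > 0L) {
      cs <- IRanges::start(thick); ce <- IRanges::end(thick)
      up <- if (cs > txs) IRanges::IRanges(txs, cs - 1L) else NULL
      dn <- if (ce < txe) IRanges::IRanges(ce + 1L, txe) else NULL
      u5 <- if (st[i] == "+") up else dn
      u3 <- if (st[i] == "+") dn else up
      if (!is.null(u5)) {
        addTo("utr5_exon", IRanges::intersect(ex, u5), chrom[i])
        addTo("utr5_intron", IRanges::intersect(intr, u5), chrom[i])
      }
      if (!is.null(u3)) {
        addTo("utr3_exon", IRanges::intersect(ex, u3), chrom[i])
        addTo("utr3_intron", IRanges::intersect(intr, u3), chrom[i])
      }
    }
  }
  lapply(acc, function(pieces) {
    if (!length(pieces)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
      rep(vapply(pieces, `[[`, "", "ch"),
          vapply(pieces, function(p) length(p$ir), 0L)),
      do.call(c, lapply(pieces, `[[`, "ir")))
  })
}

#' Build the hierarchical disjoint genome partition
#'
#' Seven primary classes are constructed from protein-coding gene models in
#' the fixed hierarchy 5'UTR exon > 5'UTR intron > 3'UTR exon > 3'UTR
#' intron > promoter > mRNA exon > mRNA intron: each class's merged
#' intervals have every class higher in the hierarchy subtracted, so the
#' seven sets are pairwise disjoint by construction. Promoters are the
#' 1000 bp immediately upstream of the TSS with respect to strand. Repeats
#' and lncRNA exons/introns are kept as auxiliary (non-exclusive) flag
#' sets.
#'
#' @param gene_models gene-model `GRanges` from [readGeneModels()]
#'   (mRNA biotype rows are used for the primary classes).
#' @param repeats optional `GRanges` of repeat elements.
#' @param lncrna_models optional gene-model `GRanges` of lncRNAs (or
#'   lncRNA-biotype rows of `gene_models` are used).
#' @return list of class `"PartitionIndex"`: named `GRanges` per primary
#'   class plus `repeats`, `lncrna_exon`, `lncrna_intron`.
#' @export
buildPartition <- function(gene_models, repeats = NULL,
                           lncrna_models = NULL) {
  if (any(lengths(gene_models$blocks) == 0L))
    stop("gene model with no exons rejected")
  coding <- gene_models[gene_models$biotype == "mRNA"]
  if (is.null(lncrna_models))
    lncrna_models <- gene_models[gene_models$biotype == "lncRNA"]
  feats <- .geneFeatures(coding)
  feats <- lapply(feats, GenomicRanges::reduce)
  # ordered subtraction: strip everything higher in the hierarchy
  higher <- GenomicRanges::GRanges()
  for (cls in PARTITION_CLASSES) {
    cut <- GenomicRanges::setdiff(feats[[cls]], higher)
    higher <- GenomicRanges::reduce(c(higher, feats[[cls]]))
    feats[[cls]] <- cut
  }
  aux_exon <- aux_intron <- GenomicRanges::GRanges()
  if (length(lncrna_models)) {
    lf <- .geneFeatures(lncrna_models)
    aux_exon <- GenomicRanges::reduce(lf$mrna_exon)
    aux_intron <- GenomicRanges::reduce(lf$mrna_intron)
  }
  structure(c(feats, list(
    repeats = if (is.null(repeats)) GenomicRanges::GRanges()
              else GenomicRanges::reduce(GenomicRanges::granges(repeats)),
    lncrna_exon = aux_exon, lncrna_intron = aux_intron)),
    class = "PartitionIndex")
}

#' Classify variants against the partition
#'
#' Total function: every variant receives exactly one primary class (the
#' highest class in the hierarchy containing it, else `"intergenic"`) plus
#' independent repeat / lncRNA exon / lncRNA intron flags.
#'
#' @param variants data.frame with `chrom`, `pos` (and ideally `vid`).
#' @param index a partition from [buildPartition()].
#' @return data.frame with columns `vid`, `class`, `repeat_flag`,
#'   `lncrna_exon`, `lncrna_intron`.
#' @export
classifyVariants <- function(variants, index) {
  vr <- variantRanges(variants$chrom, variants$pos)
  cls <- rep("intergenic", length(vr))
  for (nm in rev(PARTITION_CLASSES)) {
    hit <- IRanges::overlapsAny(vr, index[[nm]])
    cls[hit] <- nm
  }
  flag <- function(nm) IRanges::overlapsAny(vr, index[[nm]])
  data.frame(
    vid = if ("vid" %in% names(variants)) variants$vid
          else makeVid(variants$chrom, variants$pos, variants$ref,
                       variants$alt),
    class = cls, repeat_flag = flag("repeats"),
    lncrna_exon = flag("lncrna_exon"), lncrna_intron = flag("lncrna_intron"),
    stringsAsFactors = FALSE)
}
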