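#' Generate an LD-structured haplotype panel
#'
#' Haplotypes are built by a template-copying model: `n_templates` random
#' template haplotypes are drawn; each simulated haplotype copies one
#' template within a block of `block_len` consecutive variants and switches
#' to a uniformly chosen template between blocks with probability
#' `switch_prob`; independent per-site mutation noise flips alleles with
#' probability `mutation_rate`. This produces high within-block r-squared
#' that decays with distance, the feature of real reference panels the
#' pruning/expansion stages rely on. Columns failing the minor-allele
#' frequency floor are resampled (new template alleles and noise for that
#' column, copying paths kept) until the floor is met.
#'
#' @param n_hap number of haplotypes (>= 4).
#' @param n_var number of variants (>= 2).
#' @param block_len variants per copying block.
#' @param switch_prob template-switch probability between adjacent blocks.
#' @param maf_floor minimum minor allele frequency per column.
#' @param seed integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param n_templates number of template haplotypes.
#' @param mutation_rate per-site allele-flip probability.
#' @param chrom chromosome label.
#' @param spacing_bp mean spacing between adjacent variant positions.
#' @return a [HaplotypePanel-class].
#' @export
generateHaplotypePanel <- function(n_hap = 200, n_var = 100, block_len = 10,
                                   switch_prob = 0.3, maf_floor = 0.05,
                                   seed = 1, n_templates = 4,
                                   mutation_rate = 0.02, chrom = "chr1",
                                   spacing_bp = 1500) {
  stopifnot(n_hap >= 4, n_var >= 2, n_templates >= 2)
  if (maf_floor >= 0.5 || maf_floor * n_hap > n_hap / 2)
    stop("maf_floor unattainable for this n_hap")
  withr::with_seed(as.integer(seed), {
    gaps <- pmax(1L, as.integer(round(runif(n_var, 0.5, 1.5) * spacing_bp)))
    positions <- cumsum(gaps)
    ref <- sample(NUCLEOTIDES, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1L), "")
    n_blocks <- ceiling(n_var / block_len)
    block_of <- rep(seq_len(n_blocks), each = block_len)[seq_len(n_var)]
    # template copying path: Markov chain over blocks
    path <- matrix(0L, n_hap, n_blocks)
    path[, 1] <- sample.int(n_templates, n_hap, replace = TRUE)
    if (n_blocks > 1) for (b in 2:n_blocks) {
      switch <- runif(n_hap) < switch_prob
      path[, b] <- ifelse(switch,
                          sample.int(n_templates, n_hap, replace = TRUE),
                          path[, b - 1])
    }
    drawColumn <- function() {
      tmpl <- sample(0:1, n_templates, replace = TRUE)
      noise <- runif(n_hap) < mutation_rate
      list(tmpl = tmpl, noise = noise)
    }
    h <- matrix(0L, n_hap, n_var)
    for (j in seq_len(n_var)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        cl <- drawColumn()
        col <- cl$tmpl[path[, block_of[j]]]
        col <- as.integer(xor(col == 1L, cl$noise))
        af <- mean(col)
        if (min(af, 1 - af) >= maf_floor) { ok <- TRUE; break }
      }
      if (!ok)
        stop("maf_floor ", maf_floor, " unattainable at column ", j,
             " for n_hap ", n_hap)
      h[, j] <- col
    }
    HaplotypePanel(chrom, positions, ref, alt, h)
  })
}

#' Simulate association summary statistics over a panel
#'
#' Operates directly at the Z level (no individual phenotypes): the Z-score
#' vector is drawn from a multivariate normal with mean r_c * ncp and
#' covariance equal to the panel's signed LD matrix R, the standard
#' LD-propagation model for summary statistics. Marginally every variant j
#' has Z_j ~ Normal(r_jc * ncp, 1) where r_jc is the *signed* allelic
#' correlation with the causal column, so directionality travels through
#' LD, and the noise itself is LD-consistent (proxies of the causal variant
#' fluctuate together, as in real summary statistics). Then
#' se = 1/sqrt(n_samples), beta = z * se, p = 2 * Phi(-|z|), and the effect
#' allele is ALT for every record.
#'
#' @param panel a [HaplotypePanel-class].
#' @param causal_index panel column of the causal variant, or `NA` for a
#'   null trait (all means zero).
#' @param ncp non-centrality (expected |Z| at the causal variant), >= 0.
#' @param n_samples nominal study sample size (sets the SE scale).
#' @param seed integer seed.
#' @param gene_id,tissue,source trait labels for eQTL records; leave `NA`
#'   for a GWAS trait.
#' @return association record data.frame (see [readSummaryStats()]).
#' @export
simulateSummaryStats <- function(panel, causal_index = NA, ncp = 0,
                                 n_samples = 10000, seed = 1,
                                 gene_id = NA_character_,
                                 tissue = NA_character_,
                                 source = NA_character_) {
  stopifnot(ncp >= 0)
  n <- nVariants(panel)
  if (!is.na(causal_index))
    stopifnot(causal_index >= 1, causal_index <= n)
  R <- signedLD(panel)
  mu <- if (is.na(causal_index)) rep(0, n) else R[, causal_index] * ncp
  # small ridge keeps the Cholesky factor defined with perfect proxies
  L <- chol(R + diag(1e-6, n))
  withr::with_seed(as.integer(seed), {
    z <- as.vector(mu + crossprod(L, rnorm(n)))
  })
  se <- 1 / sqrt(n_samples)
  assocRecords(chrom = panelChrom(panel), pos = panelPositions(panel),
               ref = panel@ref, alt = panel@alt, effect_allele = panel@alt,
               beta = z * se, se = se, pvalue = 2 * pnorm(-abs(z)),
               gene_id = gene_id, tissue = tissue, source = source)
}

#' Plant a variant-to-gene scenario
#'
#' Builds a panel plus GWAS and eQTL summary statistics with a known causal
#' configuration: `"shared"` uses one causal column for the GWAS and every
#' eQTL trait; `"distinct"` uses two columns with panel r-squared < 0.1;
#' `"null"` plants no causal variant. The returned truth record carries
#' everything needed to score recovery downstream.
#'
#' @param kind `"shared"`, `"distinct"` or `"null"`.
#' @param panel_params list of arguments for [generateHaplotypePanel()].
#' @param ncp_gwas,ncp_eqtl non-centralities of the two traits.
#' @param tissues character vector of eQTL tissue labels (one trait each,
#'   all for gene `"GENE1"` from source `"eqtl_synth"`).
#' @param seed integer seed; sub-seeds for each simulated trait are derived
#'   from it and recorded.
#' @param n_samples sample size for all traits.
#' @return list of class `"v2gScenario"` with elements `kind`, `panel`,
#'   `gwas`, `eqtls` (named by tissue), `truth`, `seed`.
#' @export
plantScenario <- function(kind = c("shared", "distinct", "null"),
                          panel_params = list(), ncp_gwas = 8, ncp_eqtl = 8,
                          tissues = "brain_cortex", seed = 1,
                          n_samples = 10000) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  panel <- do.call(generateHaplotypePanel,
                   c(panel_params, list(seed = seed)))
  n <- nVariants(panel)
  af <- alleleFreq(panel)
  common <- which(pmin(af, 1 - af) >= 0.1)
  if (!length(common)) common <- seq_len(n)
  withr::with_seed(seed + 7L, {
    causal_gwas <- if (kind == "null") NA_integer_ else sample(common, 1L)
    causal_eqtl <- causal_gwas
    if (kind == "distinct") {
      r2row <- signedLD(panel)[causal_gwas, ]^2
      cand <- intersect(which(r2row < 0.1), common)
      if (!length(cand))
        stop("no column pair with r-squared < 0.1 available in this panel")
      causal_eqtl <- sample(cand, 1L)
    }
  })
  gwas <- simulateSummaryStats(panel, causal_gwas, ncp_gwas, n_samples,
                               seed = seed + 11L)
  eqtls <- lapply(seq_along(tissues), function(i) {
    simulateSummaryStats(panel,
                         if (kind == "null") NA_integer_ else causal_eqtl,
                         ncp_eqtl, n_samples, seed = seed + 100L + i,
                         gene_id = "GENE1", tissue = tissues[i],
                         source = "eqtl_synth")
  })
  names(eqtls) <- tissues
  vids <- panelVids(panel)
  truth <- list(
    causal_gwas = causal_gwas, causal_eqtl = causal_eqtl,
    causal_gwas_vid = if (is.na(causal_gwas)) NA_character_
                      else vids[causal_gwas],
    causal_eqtl_vid = if (is.na(causal_eqtl)) NA_character_
                      else vids[causal_eqtl],
    ncp_gwas = ncp_gwas, ncp_eqtl = ncp_eqtl,
    expected_pairs = if (kind == "shared")
      data.frame(vid = vids[causal_gwas], gene_id = "GENE1",
                 tissue = tissues, stringsAsFactors = FALSE)
    else
      data.frame(vid = character(), gene_id = character(),
                 tissue = character(), stringsAsFactors = FALSE))
  structure(list(kind = kind, panel = panel, gwas = gwas, eqtls = eqtls,
                 truth = truth, seed = seed), class = "v2gScenario")
}

#' Write a truth-consistent annotation bundle
#'
#' Emits the file bundle the downstream stages consume, arranged so the
#' planted causal variant of a shared scenario is a known positive: it sits
#' inside an enhancer whose tissue matches the eQTL tissue, under a planted
#' motif whose delta score exceeds the disruption threshold, inside an
#' enhancer-promoter anchor paired with the target gene's promoter and
#' inside a TAD shared with the gene's TSS; evidence tables satisfy all
#' four variant-tier criteria and both gene-tier criteria. Decoy tracks
#' that overlap nothing are emitted alongside. For `"null"` (or with
#' `truth_placement = FALSE`) only decoys are written.
#'
#' @param scenario a scenario from [plantScenario()].
#' @param dir output directory.
#' @param seed integer seed for the random genome sequence.
#' @param truth_placement place the truth-consistent tracks (default TRUE
#'   when the scenario has a causal variant).
#' @return invisible named list of the file paths written.
#' @export
generateAnnotationBundle <- function(scenario, dir, seed = 1,
                                     truth_placement = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- scenario$panel
  chrom <- panelChrom(panel)
  pos <- panelPositions(panel)
  glen <- max(pos) + 20000L
  if (is.na(truth_placement))
    truth_placement <- !is.na(scenario$truth$causal_gwas)
  withr::with_seed(as.integer(seed), {
    seqchars <- sample(NUCLEOTIDES, glen, replace = TRUE)
  })
  # the genome carries the REF allele at every panel variant
  seqchars[pos] <- panel@ref
  causal <- scenario$truth$causal_eqtl
  tissues <- names(scenario$eqtls)

  paths <- list()
  wp <- function(nm, fn) { p <- file.path(dir, nm); fn(p); paths[[nm]] <<- p }

  # --- motifs: planted motif matching the genome around the causal variant
  motifL <- 8L
  voff <- 4L  # causal variant sits at motif position 4
  decoy <- matrix(0.25, 6, 4, dimnames = list(NULL, NUCLEOTIDES))
  motifs <- list(list(motif_id = "DECOY_UNIF", consensus = "NNNNNN",
                      threshold = NA_real_, matrix = decoy))
  if (truth_placement) {
    win <- seqchars[(causalPos <- pos[causal]) - voff + 1L +
                      seq_len(motifL) - 1L]
    m <- matrix(0.05 / 3, motifL, 4, dimnames = list(NULL, NUCLEOTIDES))
    for (i in seq_len(motifL)) m[i, win[i]] <- 0.95
    # alt allele at the variant column gets the floor -> large delta
    m[voff, ] <- 0.01 / 2
    m[voff, panel@ref[causal]] <- 0.95
    m[voff, panel@alt[causal]] <- 0.04
    m <- m / rowSums(m)
    motifs <- c(list(list(motif_id = "MOTIF_PLANTED",
                          consensus = paste(win, collapse = ""),
                          threshold = NA_real_, matrix = m)), motifs)
  }
  wp("motifs.txt", function(p) writeMotifs(motifs, p))

  # --- genome
  wp("genome.fa", function(p) {
    g <- Biostrings::DNAStringSet(paste(seqchars, collapse = ""))
    names(g) <- chrom
    Biostrings::writeXStringSet(g, p)
  })

  # --- gene models: target gene downstream of the locus, plus a decoy
  tss1 <- max(pos) + 5000L
  gene1 <- sprintf("%s\t%d\t%d\tGENE1|mRNA\t0\t+\t%d\t%d\t0\t2\t%s\t%s",
                   chrom, tss1 - 1L, tss1 + 3000L, tss1 + 199L, tss1 + 2799L,
                   "1000,1200,", "0,1800,")
  gene2 <- sprintf("%s\t%d\t%d\tGENE2|mRNA\t0\t-\t%d\t%d\t0\t1\t%s\t%s",
                   chrom, tss1 + 8000L, tss1 + 9500L, tss1 + 8100L,
                   tss1 + 9300L, "1500,", "0,")
  wp("genes.bed", function(p) writeLines(c(gene1, gene2), p))

  # --- interval tracks
  mkTrack <- function(starts, ends, dataset, tissue, cls) {
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(start = starts, end = ends),
      dataset = dataset, tissue = tissue, class_label = cls)
  }
  decoyStart <- glen - 3000L
  enh <- mkTrack(decoyStart, decoyStart + 200L, "EpiMAP_synth",
                 "decoy_tissue", "enhancer")
  hist <- mkTrack(decoyStart, decoyStart + 400L, "ENCODE_synth",
                  "decoy_tissue", "histone")
  atac <- mkTrack(decoyStart, decoyStart + 300L, "ENCODE_synth",
                  "decoy_tissue", "ATAC")
  if (truth_placement) {
    cp <- pos[causal]
    enh <- c(mkTrack(cp - 50L, cp + 50L, "EpiMAP_synth", tissues[1],
                     "enhancer"), enh)
    hist <- c(mkTrack(cp - 100L, cp + 100L, "ENCODE_synth", tissues[1],
                      "histone"), hist)
    atac <- c(mkTrack(cp - 80L, cp + 80L, "ENCODE_synth", tissues[1],
                      "ATAC"), atac)
  }
  wp("enhancers.bed", function(p) writeBedTrack(enh, p))
  wp("histone.bed", function(p) writeBedTrack(hist, p))
  wp("atac.bed", function(p) writeBedTrack(atac, p))

  # --- EPI (two sources) and TADs
  promoter1 <- c(tss1 - 1000L, tss1)  # 1-based closed promoter span
  mkPair <- function(astart, aend, bstart, bend, assay, src) {
    p <- S4Vectors::Pairs(
      GenomicRanges::GRanges(chrom, IRanges::IRanges(astart, aend)),
      GenomicRanges::GRanges(chrom, IRanges::IRanges(bstart, bend)))
    S4Vectors::mcols(p) <- S4Vectors::DataFrame(
      assay = assay, source = src, celltype = "brain")
    p
  }
  epi <- mkPair(decoyStart, decoyStart + 500L, decoyStart + 6000L,
                decoyStart + 6500L, "HiC", "decoy_source")
  if (truth_placement) {
    cp <- pos[causal]
    epi <- c(mkPair(cp - 100L, cp + 100L, promoter1[1], promoter1[2],
                    "CaptureC", "epi_source_A"),
             mkPair(cp - 150L, cp + 150L, promoter1[1], promoter1[2],
                    "HiC", "epi_source_B"),
             epi)
  }
  wp("epi.bedpe", function(p) writeBedpe(epi, p))

  tad <- mkTrack(max(1L, min(pos) - 1000L), tss1 + 4000L, "TAD_synth",
                 "brain", "TAD")
  wp("tads.bed", function(p) writeBedTrack(tad, p))

  # --- evidence tables
  vids <- panelVids(panel)
  vev <- data.frame(vid = vids, cadd = 1.0, regdb = "7",
                    histone_q = 0.5, atac = FALSE, other_gwas = FALSE,
                    stringsAsFactors = FALSE)
  if (truth_placement) {
    i <- causal
    vev$cadd[i] <- 15; vev$regdb[i] <- "1b"; vev$histone_q[i] <- 0.01
    vev$atac[i] <- TRUE; vev$other_gwas[i] <- TRUE
  }
  wp("variant_evidence.tsv", function(p)
    write.table(vev, p, sep = "\t", quote = FALSE, row.names = FALSE))
  gev <- data.frame(gene_id = c("GENE1", "GENE2"),
                    nominated = c(truth_placement, FALSE),
                    brain_expressed = c(truth_placement, FALSE))
  wp("gene_evidence.tsv", function(p)
    write.table(gev, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- external eQTL replication tables (non-GTEx role), harmonizable
  if (truth_placement) {
    zc <- scenario$eqtls[[1]]$z[causal]
    i <- causal
    ext <- data.frame(
      chrom = chrom, pos = pos[i], ref = panel@ref[i], alt = panel@alt[i],
      effect_allele = c(panel@alt[i], panel@ref[i], panel@alt[i],
                        panel@alt[i]),
      beta = c(zc, -zc, zc * 0.9, zc * 1.1) * 0.01, se = 0.01,
      pvalue = 2 * pnorm(-abs(zc)), gene_id = "GENE1",
      tissue = c("frontal_cortex", "limbic_system", "basal_ganglia",
                 "brain_stem"),
      source = c("metabrain_synth", "metabrain_synth", "eqtlcat_synth",
                 "eqtlcat_synth"), stringsAsFactors = FALSE)
  } else {
    ext <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      effect_allele = character(), beta = numeric(),
                      se = numeric(), pvalue = numeric(),
                      gene_id = character(), tissue = character(),
                      source = character(), stringsAsFactors = FALSE)
  }
  wp("external_eqtl.tsv", function(p)
    write.table(ext, p, sep = "\t", quote = FALSE, row.names = FALSE))

  # --- summary stats + panel
  wp("gwas.tsv", function(p) writeSummaryStats(scenario$gwas, p))
  wp("eqtl.tsv", function(p)
    writeSummaryStats(do.call(rbind, scenario$eqtls), p))
  wp("panel.tsv", function(p) writeHaplotypePanel(panel, p))

  # --- tissue map (eQTL tissue -> track tissues) and brain-region groups
  tm <- data.frame(eqtl_tissue = tissues, track_tissue = tissues,
                   stringsAsFactors = FALSE)
  wp("tissue_map.tsv", function(p)
    write.table(tm, p, sep = "\t", quote = FALSE, row.names = FALSE))
  gm <- data.frame(
    tissue = c("frontal_cortex", "limbic_system", "basal_ganglia",
               "brain_stem"),
    group = c("FrontalCortex", "LimbicSystem", "BasalGanglia", "BrainStem"),
    stringsAsFactors = FALSE)
  wp("groups.tsv", function(p)
    write.table(gm, p, sep = "\t", quote = FALSE, row.names = FALSE))

  invisible(paths)
}
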