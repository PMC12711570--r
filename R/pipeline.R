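#' Pipeline run configuration
#'
#' Collects every input path and every threshold of the four-stage pipeline
#' (Preprocess, Characterize, Validate, Tier) with the framework's named
#' defaults: genome-wide significance 5e-8; pruning r-squared 0.7 in a
#' 500 kb window; expansion r-squared 0.7 within 1 Mb and 1000 variants;
#' PP.H4 > 0.7 and SNP.PP.H4 > 0.5 with > 1 variant for a colocalization
#' call; delta-PWM |2|; CADD > 10; histone q < 0.05; inconsistency fraction
#' 0.5. The configuration is echoed verbatim into the run summary.
#'
#' @param paths named list of input file paths: gwas, eqtl, panel, genes,
#'   enhancers, epi, tads, motifs, genome, variant_evidence, gene_evidence,
#'   external_eqtl, tissue_map, groups.
#' @param out_dir report directory.
#' @param p_thresh,prune_r2,window_bp,expand_r2,max_bp,max_rank_dist
#'   preprocessing thresholds.
#' @param pp_h4_min,snp_pp_min,nominal_p colocalization thresholds.
#' @param delta_threshold TFBS disruption threshold.
#' @param cadd_min,histone_q_max variant-evidence thresholds.
#' @param priors a [colocPriors()] object.
#' @param seed integer seed recorded in the summary.
#' @return list of class `"RunConfig"`.
#' @export
v2gConfig <- function(paths, out_dir, p_thresh = 5e-8, prune_r2 = 0.7,
                      window_bp = 5e5, expand_r2 = 0.7, max_bp = 1e6,
                      max_rank_dist = 1000, pp_h4_min = 0.7,
                      snp_pp_min = 0.5, nominal_p = 0.05,
                      delta_threshold = 2, cadd_min = 10,
                      histone_q_max = 0.05, priors = colocPriors(),
                      seed = 1) {
  structure(list(paths = paths, out_dir = out_dir, p_thresh = p_thresh,
                 prune_r2 = prune_r2, window_bp = window_bp,
                 expand_r2 = expand_r2, max_bp = max_bp,
                 max_rank_dist = max_rank_dist, pp_h4_min = pp_h4_min,
                 snp_pp_min = snp_pp_min, nominal_p = nominal_p,
                 delta_threshold = delta_threshold, cadd_min = cadd_min,
                 histone_q_max = histone_q_max, priors = priors,
                 seed = as.integer(seed)), class = "RunConfig")
}

.requireInput <- function(config, stage, keys) {
  for (k in keys) {
    p <- config$paths[[k]]
    if (is.null(p) || !file.exists(p))
      stop(stage, " stage: required input '", k, "' is missing")
  }
}

#' Run the variant-to-gene pipeline end to end
#'
#' Preprocess (prune + expand), Characterize (partition, colocalization,
#' TFBS, enhancer confluence), Validate (directionality, McNemar
#' comparison, EPI/TAD dual-anchor, replication, evidence profiles), Tier
#' (component tiers, ranking). Writes the stage tables and a JSON run
#' summary with the funnel counts; deterministic given config.
#'
#' @param config a [v2gConfig()] object.
#' @return invisible list with the stage tables and the summary.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  P <- config$paths

  ## ---- Preprocess
  .requireInput(config, "Preprocess", c("gwas", "panel", "eqtl"))
  gwas <- readSummaryStats(P$gwas, "gwas")
  panel <- readHaplotypePanel(P$panel)
  eqtl <- readSummaryStats(P$eqtl, "eqtl")
  n_sig <- sum(gwas$pvalue < config$p_thresh)
  tags <- pruneVariants(gwas, panel, config$p_thresh, config$prune_r2,
                        config$window_bp)
  counts <- list(significant_variants = n_sig, tags = nrow(tags))
  if (!nrow(tags)) {
    summary <- list(counts = c(counts, list(regions = 0L,
                      candidate_variants = 0L, colocalized_pairs = 0L,
                      confluent_pairs = 0L, tiered_pairs = 0L)),
                    config = .echoConfig(config))
    writeReport(list(tags = tags), config$out_dir, summary)
    message("runPipeline: 0 regions; nothing to analyze")
    return(invisible(list(tables = list(tags = tags), summary = summary)))
  }
  regions <- expandRegions(tags, panel, config$expand_r2, config$max_bp,
                           config$max_rank_dist)
  vids <- panelVids(panel)
  pool <- sort(unique(unlist(regionProxies(regions))))
  candidates <- data.frame(vid = vids[pool],
                           chrom = panelChrom(panel),
                           pos = panelPositions(panel)[pool],
                           ref = panel@ref[pool], alt = panel@alt[pool],
                           stringsAsFactors = FALSE)
  counts$regions <- nRegions(regions)
  counts$candidate_variants <- nrow(candidates)

  ## ---- Characterize
  partition_tbl <- NULL
  if (!is.null(P$genes) && file.exists(P$genes)) {
    models <- readGeneModels(P$genes)
    index <- buildPartition(models)
    partition_tbl <- classifyVariants(candidates, index)
  }
  pairs <- .emptyPairs()
  for (k in seq_len(nRegions(regions))) {
    rv <- vids[regionVariants(regions)[[k]]]
    cr <- colocRegion(rv, gwas, eqtl, config$priors, config$pp_h4_min,
                      config$snp_pp_min, config$nominal_p,
                      locus_id = regionTags(regions)$tag[k])
    pairs <- rbind(pairs, cr$pairs)
  }
  if (nrow(pairs)) {  # dedupe pairs discovered from overlapping regions
    key <- paste(pairs$vid, pairs$gene_id, pairs$tissue, pairs$source)
    pairs <- pairs[order(-pairs$pp_h4), ]
    pairs <- pairs[!duplicated(paste(pairs$vid, pairs$gene_id,
                                     pairs$tissue, pairs$source)), ]
    rownames(pairs) <- NULL
  }
  counts$colocalized_pairs <- nrow(pairs)
  counts$colocalized_variants <- length(unique(pairs$vid))
  counts$colocalized_genes <- length(unique(pairs$gene_id))

  .requireInput(config, "Characterize",
                c("genome", "motifs", "enhancers", "tissue_map"))
  genome <- readGenome(P$genome)
  motifs <- readMotifs(P$motifs)
  pair_variants <- unique(merge(
    data.frame(vid = unique(pairs$vid), stringsAsFactors = FALSE),
    candidates, by = "vid", sort = TRUE))
  tfbs <- scanVariants(pair_variants, motifs, genome,
                       config$delta_threshold)
  enhancers <- readBedTrack(P$enhancers)
  tissue_map <- read.delim(P$tissue_map, stringsAsFactors = FALSE)
  confluent <- confluentV2G(pairs, tfbs, enhancers, tissue_map)
  counts$confluent_pairs <- nrow(confluent)

  ## ---- Validate + Tier
  .requireInput(config, "Validate",
                c("epi", "tads", "genes", "external_eqtl",
                  "variant_evidence", "gene_evidence", "groups"))
  epi <- readBedpe(P$epi)
  tads <- readBedTrack(P$tads)
  models <- readGeneModels(P$genes)
  external <- readSummaryStats(P$external_eqtl, "eqtl")
  vev <- read.delim(P$variant_evidence, stringsAsFactors = FALSE)
  gev <- read.delim(P$gene_evidence, stringsAsFactors = FALSE)
  groups <- read.delim(P$groups, stringsAsFactors = FALSE)

  ranked <- .emptyRanked()
  flags_before <- flags_after <- logical(0)
  for (i in seq_len(nrow(confluent))) {
    pr <- confluent[i, ]
    ev_raw <- .pairEvidence(pr, external, groups, harmonized = FALSE)
    ev_h <- .pairEvidence(pr, external, groups, harmonized = TRUE)
    verdict_raw <- directionalityConsistency(ev_raw)
    verdict <- directionalityConsistency(ev_h)
    if (!verdict$undetermined && !verdict_raw$undetermined) {
      flags_before <- c(flags_before, isTRUE(verdict_raw$inconsistent))
      flags_after <- c(flags_after, isTRUE(verdict$inconsistent))
    }
    repl <- eqtlReplication(pr$vid, pr$gene_id, pr$z_eqtl, external)
    supp <- epiTadSupport(pr$vid, pr$gene_id, epi, tads, models)
    evp <- evidenceProfiles(pr$vid, pr$gene_id, vev, gev,
                            cadd_min = config$cadd_min,
                            histone_q_max = config$histone_q_max)
    has_ext <- verdict$n_groups > 0L
    eqtl_flags <- list(
      directionality = has_ext && isFALSE(verdict$inconsistent),
      presence = has_ext,
      agreement = any(repl),
      negative_consistent = !verdict$undetermined &&
        isFALSE(verdict$inconsistent) && verdict$reference_sign < 0)
    tier <- computeTiers(eqtl_flags, supp$n_epi_sources, evp)
    ranked <- rbind(ranked, data.frame(
      vid = pr$vid, gene_id = pr$gene_id, tissue = pr$tissue,
      source = pr$source, pp_h4 = pr$pp_h4, snp_pp_h4 = pr$snp_pp_h4,
      z_eqtl = pr$z_eqtl, v2g_eqtl = tier$v2g_eqtl,
      v2g_epi = tier$v2g_epi, v = tier$v, g = tier$g,
      overall = tier$overall, tad_supported = supp$tad_supported,
      inconsistent = isTRUE(verdict$inconsistent),
      stringsAsFactors = FALSE))
  }
  ranked <- rankPairs(ranked)
  counts$tiered_pairs <- nrow(ranked)
  counts$tiered_genes <- length(unique(ranked$gene_id))
  mcn <- if (length(flags_before))
    mcnemarImprovement(flags_before, flags_after) else NULL

  tables <- list(tags = tags,
                 regions = regionTags(regions),
                 candidates = candidates,
                 coloc_pairs = pairs,
                 confluent_pairs = confluent,
                 ranked_pairs = ranked)
  if (!is.null(partition_tbl)) tables$partition <- partition_tbl
  summary <- list(counts = counts,
                  mcnemar = mcn,
                  config = .echoConfig(config))
  writeReport(tables, config$out_dir, summary)
  invisible(list(tables = tables, summary = summary))
}

# evidence table for one pair: discovery eQTL rows are the reference role,
# external rows are grouped by brain-region group
.pairEvidence <- function(pair, external, groups, harmonized = TRUE) {
  ext <- external[external$vid == pair$vid &
                    external$gene_id == pair$gene_id, , drop = FALSE]
  if (harmonized && nrow(ext)) {
    ext <- harmonizeZ(ext)
    ext <- ext[!ext$excluded, , drop = FALSE]
  }
  grp <- groups$group[match(ext$tissue, groups$tissue)]
  grp[is.na(grp)] <- ext$tissue[is.na(grp)]
  rbind(
    data.frame(z = pair$z_eqtl, group = "reference", role = "reference",
               stringsAsFactors = FALSE),
    if (nrow(ext)) data.frame(z = ext$z, group = grp, role = "external",
                              stringsAsFactors = FALSE))
}

.emptyRanked <- function() {
  data.frame(vid = character(), gene_id = character(), tissue = character(),
             source = character(), pp_h4 = numeric(), snp_pp_h4 = numeric(),
             z_eqtl = numeric(), v2g_eqtl = integer(), v2g_epi = integer(),
             v = integer(), g = integer(), overall = integer(),
             tad_supported = logical(), inconsistent = logical(),
             stringsAsFactors = FALSE)
}

.echoConfig <- function(config) {
  out <- unclass(config)
  out$priors <- unclass(out$priors)
  out
}
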