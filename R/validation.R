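#' Harmonize Z-scores to the alternative allele
#'
#' Re-orients every record's Z (and beta) so the sign refers to the ALT
#' allele of the canonical vid: records reported on the REF allele are
#' sign-flipped. Harmonizing twice is a no-op. Strand-ambiguous (A/T, C/G)
#' variants are never flipped silently: when the reporting strand is
#' unknown they are flagged `excluded = TRUE` so consistency checks can
#' drop them.
#'
#' @param records association record data.frame (columns ref, alt,
#'   effect_allele, z; beta flipped alongside when present).
#' @param strand_known logical (scalar or per-record): is the reporting
#'   strand of the source known?
#' @return the records with harmonized `z` (and `beta`),
#'   `effect_allele = alt`, plus `flipped` and `excluded` columns.
#' @export
harmonizeZ <- function(records, strand_known = TRUE) {
  if (!nrow(records)) {
    records$flipped <- logical(0); records$excluded <- logical(0)
    return(records)
  }
  bad <- records$effect_allele != records$ref &
         records$effect_allele != records$alt
  if (any(bad))
    stop("effect allele matches neither ref nor alt for: ",
         paste(records$vid[bad], collapse = ", "))
  ambiguous <- isStrandAmbiguous(records$ref, records$alt)
  strand_known <- rep_len(strand_known, nrow(records))
  flip <- records$effect_allele == records$ref
  excluded <- ambiguous & !strand_known
  if (any(excluded & flip))
    message("harmonizeZ: ", sum(excluded & flip), " strand-ambiguous ",
            "record(s) with unknown source strand not flipped; flagged ",
            "excluded")
  do_flip <- flip & !excluded
  records$z[do_flip] <- -records$z[do_flip]
  if ("beta" %in% names(records))
    records$beta[do_flip] <- -records$beta[do_flip]
  records$effect_allele[do_flip] <- records$alt[do_flip]
  records$flipped <- do_flip
  records$excluded <- excluded
  records
}

#' Directionality consistency of a pair across brain-region groups
#'
#' The reference sign is the sign of the mean Z over the reference-role
#' (GTEx-like) evidence; each non-reference (source, brain-region group)
#' contributes the sign of its mean harmonized Z. Groups with zero or
#' missing Z are excluded from the denominator. The pair is inconsistent
#' iff more than half of the groups disagree with the reference sign.
#'
#' @param evidence harmonized evidence data.frame for one pair, with
#'   columns `z`, `group`, and `role` (`"reference"` rows set the
#'   reference sign; all other rows are grouped by `group`).
#' @param max_fraction disagreement fraction above which (strictly) the
#'   pair is inconsistent (default 0.5).
#' @return list (class `"ConsistencyVerdict"`): n_groups, n_disagree,
#'   fraction_disagree, inconsistent, reference_sign; or `undetermined =
#'   TRUE` when no reference evidence exists.
#' @export
directionalityConsistency <- function(evidence, max_fraction = 0.5) {
  refz <- evidence$z[evidence$role == "reference"]
  refz <- refz[is.finite(refz)]
  if (!length(refz))
    return(structure(list(undetermined = TRUE, n_groups = 0L,
                          n_disagree = 0L, fraction_disagree = NA_real_,
                          inconsistent = NA), class = "ConsistencyVerdict"))
  ref_sign <- sign(mean(refz))
  oth <- evidence[evidence$role != "reference" & is.finite(evidence$z), ,
                  drop = FALSE]
  gz <- tapply(oth$z, oth$group, mean)
  gz <- gz[is.finite(gz) & gz != 0]
  n <- length(gz)
  nd <- sum(sign(gz) != ref_sign)
  structure(list(undetermined = FALSE, n_groups = n, n_disagree = nd,
                 fraction_disagree = if (n) nd / n else NA_real_,
                 inconsistent = if (n) (nd / n) > max_fraction else NA,
                 reference_sign = ref_sign), class = "ConsistencyVerdict")
}

#' Paired inconsistency comparison (McNemar)
#'
#' Compares per-pair inconsistency flags before and after harmonization.
#' Reports the percent reduction (rounded to an integer) and McNemar's
#' test on the discordant counts b (inconsistent -> consistent) and c
#' (consistent -> inconsistent): chi-squared = (b - c)^2 / (b + c) without
#' continuity correction, with an exact two-sided binomial test
#' auto-selected when b + c < 25 (or forced via `method`).
#'
#' @param before,after logical vectors of per-pair inconsistency flags.
#' @param method `"auto"`, `"exact"` or `"chisq"`.
#' @return list: n_before, n_after, percent_reduction, b, c, statistic,
#'   p_value, method, undefined (TRUE when b + c = 0, where p = 1).
#' @export
mcnemarImprovement <- function(before, after, method = c("auto", "exact",
                                                         "chisq")) {
  method <- match.arg(method)
  stopifnot(length(before) == length(after))
  nb <- sum(before); na_ <- sum(after)
  pct <- if (nb > 0) round(100 * (nb - na_) / nb) else NA_real_
  b <- sum(before & !after)
  cc <- sum(!before & after)
  if (b + cc == 0L)
    return(list(n_before = nb, n_after = na_, percent_reduction = pct,
                b = b, c = cc, statistic = NA_real_, p_value = 1,
                method = "undefined", undefined = TRUE))
  stat <- (b - cc)^2 / (b + cc)
  use_exact <- method == "exact" || (method == "auto" && (b + cc) < 25)
  p <- if (use_exact) binom.test(b, b + cc, 0.5)$p.value
       else pchisq(stat, df = 1, lower.tail = FALSE)
  list(n_before = nb, n_after = na_, percent_reduction = pct, b = b,
       c = cc, statistic = stat, p_value = p,
       method = if (use_exact) "exact" else "chisq", undefined = FALSE)
}

#' Dual-anchor interaction and TAD support for a pair
#'
#' EPI support: the variant falls in one anchor and the gene's promoter
#' (the 1000 bp upstream of the TSS, strand-aware, matching the partition
#' module's definition) intersects the other anchor, in either orientation.
#' TAD support: the variant and the TSS fall inside the same TAD interval.
#' Presence is recorded per EPI source for tiering.
#'
#' @param vid variant id.
#' @param gene_id target gene.
#' @param interactions `Pairs` from [readBedpe()].
#' @param tads `GRanges` of TADs.
#' @param gene_models `GRanges` from [readGeneModels()].
#' @return list: epi_supported, epi_sources (character), n_epi_sources,
#'   tad_supported.
#' @export
epiTadSupport <- function(vid, gene_id, interactions, tads, gene_models) {
  v <- parseVid(vid)
  vr <- variantRanges(v$chrom, v$pos)
  gi <- which(gene_models$gene_id == gene_id)
  if (!length(gi)) {
    message("epiTadSupport: gene ", gene_id, " absent from models; ",
            "no support")
    return(list(epi_supported = FALSE, epi_sources = character(),
                n_epi_sources = 0L, tad_supported = FALSE))
  }
  g <- gene_models[gi[1]]
  tss <- g$tss
  st <- as.character(GenomicRanges::strand(g))
  gchrom <- as.character(GenomicRanges::seqnames(g))
  prom <- GenomicRanges::GRanges(gchrom, if (st == "+")
    IRanges::IRanges(max(1L, tss - 1000L), tss)
  else IRanges::IRanges(tss, tss + 1000L))
  srcs <- character()
  if (length(interactions)) {
    a1 <- S4Vectors::first(interactions)
    a2 <- S4Vectors::second(interactions)
    v_in_1 <- IRanges::overlapsAny(a1, vr)
    v_in_2 <- IRanges::overlapsAny(a2, vr)
    p_in_1 <- IRanges::overlapsAny(a1, prom)
    p_in_2 <- IRanges::overlapsAny(a2, prom)
    supp <- (v_in_1 & p_in_2) | (v_in_2 & p_in_1)
    srcs <- unique(S4Vectors::mcols(interactions)$source[supp])
    srcs <- srcs[!is.na(srcs)]
  }
  tad_ok <- FALSE
  if (length(tads)) {
    tssr <- variantRanges(as.character(GenomicRanges::seqnames(g)), tss)
    tad_ok <- any(IRanges::overlapsAny(tads, vr) &
                  IRanges::overlapsAny(tads, tssr))
  }
  list(epi_supported = length(srcs) > 0L, epi_sources = srcs,
       n_epi_sources = length(srcs), tad_supported = tad_ok)
}

#' Independent eQTL replication of a pair
#'
#' A pair replicates in an external source iff that source has a record for
#' the same vid and gene whose harmonized effect direction matches the
#' pair's harmonized eQTL Z.
#'
#' @param vid,gene_id,z_eqtl the pair (z already ALT-harmonized).
#' @param external association records of external eQTL tables (will be
#'   harmonized here).
#' @return named logical vector of replication flags per source.
#' @export
eqtlReplication <- function(vid, gene_id, z_eqtl, external) {
  if (!nrow(external)) return(setNames(logical(0), character(0)))
  ext <- harmonizeZ(external)
  ext <- ext[!ext$excluded & ext$vid == vid & ext$gene_id == gene_id &
               is.finite(ext$z) & ext$z != 0, , drop = FALSE]
  srcs <- unique(external$source)
  out <- vapply(srcs, function(s) {
    rows <- ext[ext$source == s, , drop = FALSE]
    nrow(rows) > 0L && any(sign(rows$z) == sign(z_eqtl))
  }, logical(1))
  setNames(out, srcs)
}

#' Variant and gene evidence profiles
#'
#' Variant flags: `histone` (overlaps an active histone-mark peak with
#' q < 0.05), `atac` (in an open-chromatin peak), `effect_pred` (CADD
#' strictly > 10 OR RegulomeDB rank 1a-1e), `other_gwas` (associated in
#' another GWAS of the same disease). Gene flags: `nominated`,
#' `brain_expressed`. Malformed RegulomeDB ranks are treated as absent
#' with a warning. Validation requires at least one true flag, not all.
#'
#' @param vid variant id.
#' @param gene_id gene id.
#' @param variant_evidence data.frame with vid, cadd, regdb, histone_q,
#'   atac, other_gwas.
#' @param gene_evidence data.frame with gene_id, nominated, brain_expressed.
#' @param cadd_min CADD threshold (strict >, default 10).
#' @param histone_q_max histone peak q-value threshold (strict <).
#' @return list with `variant` (4 logicals) and `gene` (2 logicals).
#' @export
evidenceProfiles <- function(vid, gene_id, variant_evidence,
                             gene_evidence, cadd_min = 10,
                             histone_q_max = 0.05) {
  vrow <- variant_evidence[variant_evidence$vid == vid, , drop = FALSE]
  grow <- gene_evidence[gene_evidence$gene_id == gene_id, , drop = FALSE]
  regdb_ok <- FALSE
  cadd_ok <- FALSE
  histone <- atac <- other <- FALSE
  if (nrow(vrow)) {
    vrow <- vrow[1, ]
    rd <- as.character(vrow$regdb)
    valid_ranks <- c(paste0("1", letters[1:6]), paste0("2", letters[1:3]),
                     paste0("3", letters[1:2]), "4", "5", "6", "7")
    if (!is.na(rd) && !(rd %in% valid_ranks)) {
      warning("malformed RegulomeDB rank '", rd, "' treated as absent")
      rd <- NA_character_
    }
    regdb_ok <- !is.na(rd) && rd %in% paste0("1", letters[1:5])
    cadd_ok <- isTRUE(vrow$cadd > cadd_min)
    histone <- isTRUE(vrow$histone_q < histone_q_max)
    atac <- isTRUE(as.logical(vrow$atac))
    other <- isTRUE(as.logical(vrow$other_gwas))
  }
  gene <- list(nominated = FALSE, brain_expressed = FALSE)
  if (nrow(grow)) {
    gene$nominated <- isTRUE(as.logical(grow$nominated[1]))
    gene$brain_expressed <- isTRUE(as.logical(grow$brain_expressed[1]))
  }
  list(variant = list(histone = histone, atac = atac,
                      effect_pred = cadd_ok || regdb_ok,
                      other_gwas = other),
       gene = gene)
}
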