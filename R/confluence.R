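#' Enhancer overlaps for a variant
#'
#' All track intervals containing the variant position under the package's
#' half-open convention (pos - 1 in \[start, end) on the 0-based file
#' scale; see [variantRanges()]).
#'
#' @param chrom,pos the variant.
#' @param tracks `GRanges` with `dataset` and `tissue` mcols (from
#'   [readBedTrack()]); several tracks may be concatenated.
#' @return data.frame of hits: dataset, tissue, start, end.
#' @export
overlapEnhancers <- function(chrom, pos, tracks) {
  hits <- IRanges::findOverlaps(variantRanges(chrom, pos), tracks)
  idx <- S4Vectors::subjectHits(hits)
  data.frame(dataset = tracks$dataset[idx], tissue = tracks$tissue[idx],
             start = GenomicRanges::start(tracks)[idx],
             end = GenomicRanges::end(tracks)[idx],
             stringsAsFactors = FALSE)
}

#' Confluent context filtering of colocalized pairs
#'
#' A colocalized pair is retained iff its variant disrupts at least one
#' TFBS, overlaps at least one enhancer, and the enhancer tissue context
#' matches the pair's eQTL tissue under an explicit many-to-many tissue
#' map. A pair failing any criterion is excluded, with the reason logged;
#' pairs whose eQTL tissue is absent from the map are excluded too.
#'
#' @param pairs called-pair data.frame from [callV2G()]/[colocRegion()].
#' @param tfbs_calls disruption data.frame from [scanVariants()].
#' @param enhancers enhancer `GRanges` (track dialect mcols).
#' @param tissue_map data.frame with columns `eqtl_tissue`, `track_tissue`
#'   (many-to-many); NULL means exact label match.
#' @return the retained subset with audit columns `enhancer_hits` (dataset:
#'   tissue, collapsed), `tfbs_hits` (motif ids), `context_matched`.
#' @export
confluentV2G <- function(pairs, tfbs_calls, enhancers, tissue_map = NULL) {
  keep <- logical(nrow(pairs))
  enh_audit <- tfbs_audit <- character(nrow(pairs))
  ctx <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    v <- parseVid(pairs$vid[i])
    motifs <- tfbs_calls$motif_id[tfbs_calls$vid == pairs$vid[i]]
    hits <- overlapEnhancers(v$chrom, v$pos, enhancers)
    allowed <- if (is.null(tissue_map)) pairs$tissue[i]
               else tissue_map$track_tissue[tissue_map$eqtl_tissue ==
                                              pairs$tissue[i]]
    if (!is.null(tissue_map) && !length(allowed)) {
      message("confluentV2G: tissue '", pairs$tissue[i],
              "' absent from tissue map; pair excluded")
      next
    }
    ctx[i] <- any(hits$tissue %in% allowed)
    keep[i] <- length(motifs) > 0L && nrow(hits) > 0L && ctx[i]
    enh_audit[i] <- paste(paste0(hits$dataset, ":", hits$tissue),
                          collapse = ",")
    tfbs_audit[i] <- paste(unique(motifs), collapse = ",")
  }
  out <- pairs
  out$enhancer_hits <- enh_audit
  out$tfbs_hits <- tfbs_audit
  out$context_matched <- ctx
  out[keep, , drop = FALSE]
}
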