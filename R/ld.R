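#' Pairwise linkage disequilibrium from haplotype counts
#'
#' `computeR2` returns the squared allelic correlation
#' r^2 = D^2 / (pA(1-pA) pB(1-pB)) with D = pAB - pA*pB estimated from the
#' phased haplotype matrix. `signedLD` returns the full signed correlation
#' matrix r (the quantity that propagates Z-scores through LD with its
#' direction intact); `computeR2(panel, i, j)` equals `signedLD(panel)[i,j]^2`.
#'
#' @param panel a [HaplotypePanel-class].
#' @param i,j panel column indices.
#' @return `computeR2`: numeric in \[0,1\]; `signedLD`: n_var x n_var matrix.
#' @examples
#' # haplotype counts AB=3, Ab=1, aB=1, ab=3 -> r^2 = 0.25
#' @export
computeR2 <- function(panel, i, j) {
  h <- haplotypeMatrix(panel)
  x <- h[, i]; y <- h[, j]
  pA <- mean(x); pB <- mean(y)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("r-squared undefined for a monomorphic column")
  D <- mean(x * y) - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' @rdname computeR2
#' @export
signedLD <- function(panel) {
  h <- haplotypeMatrix(panel)
  p <- colMeans(h)
  if (any(p %in% c(0, 1)))
    stop("signed LD undefined with monomorphic columns")
  D <- crossprod(h) / nrow(h) - tcrossprod(p)
  sd2 <- sqrt(p * (1 - p))
  D / tcrossprod(sd2)
}

#' Greedy LD pruning of genome-wide significant variants
#'
#' Walks the significant variants (p < `p_thresh`) in ascending p-value
#' order (ties by chrom, pos) and accepts a variant as a tag iff its
#' r-squared with every already-accepted tag within `window_bp` is below
#' `prune_r2`. Significant variants absent from the panel carry no LD
#' information and are logged and excluded.
#'
#' @param gwas association record data.frame.
#' @param panel a [HaplotypePanel-class].
#' @param p_thresh genome-wide significance threshold.
#' @param prune_r2 pruning r-squared threshold (accept iff below).
#' @param window_bp window (± around each tag) within which LD is checked.
#' @return data.frame of tags in acceptance order, with columns `vid`,
#'   `tagIndex` (panel column), `pos`, `pvalue`.
#' @export
pruneVariants <- function(gwas, panel, p_thresh = 5e-8, prune_r2 = 0.7,
                          window_bp = 5e5) {
  sig <- gwas[gwas$pvalue < p_thresh, , drop = FALSE]
  vids <- panelVids(panel)
  idx <- match(sig$vid, vids)
  if (any(is.na(idx))) {
    message("pruneVariants: ", sum(is.na(idx)), " significant variant(s) ",
            "absent from the panel; excluded (no LD information)")
    sig <- sig[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  ord <- order(sig$pvalue, sig$chrom, sig$pos)
  sig <- sig[ord, , drop = FALSE]
  idx <- idx[ord]
  r <- if (nrow(sig)) signedLD(panel) else NULL
  acc <- integer()
  for (k in seq_len(nrow(sig))) {
    i <- idx[k]
    near <- acc[abs(panelPositions(panel)[acc] -
                      panelPositions(panel)[i]) <= window_bp]
    if (!length(near) || all(r[i, near]^2 < prune_r2))
      acc <- c(acc, i)
  }
  data.frame(vid = vids[acc], tagIndex = acc,
             pos = panelPositions(panel)[acc],
             pvalue = sig$pvalue[match(acc, idx)],
             stringsAsFactors = FALSE)
}

#' Expand tags into LD analysis regions
#'
#' Each tag's proxy set contains every panel variant with r-squared to the
#' tag at least `expand_r2`, within `max_bp` of the tag, and within
#' `max_rank_dist` variants of the tag in chromosomal rank order (the tag
#' itself included). Region bounds are the outermost proxy positions, and
#' the region's colocalization input is every panel variant inside the
#' bounds, associated with the trait or not.
#'
#' @param tags tag data.frame from [pruneVariants()].
#' @param panel a [HaplotypePanel-class].
#' @param expand_r2 proxy r-squared threshold (>=).
#' @param max_bp maximum base-pair distance from the tag.
#' @param max_rank_dist maximum rank distance (number of intervening panel
#'   variants) from the tag.
#' @return an [LDRegionSet-class].
#' @export
expandRegions <- function(tags, panel, expand_r2 = 0.7, max_bp = 1e6,
                          max_rank_dist = 1000) {
  pos <- panelPositions(panel)
  r <- if (nrow(tags)) signedLD(panel) else NULL
  proxies <- vector("list", nrow(tags))
  regionv <- vector("list", nrow(tags))
  minp <- maxp <- integer(nrow(tags))
  for (k in seq_len(nrow(tags))) {
    i <- tags$tagIndex[k]
    keep <- which(r[i, ]^2 >= expand_r2 &
                  abs(pos - pos[i]) <= max_bp &
                  abs(seq_along(pos) - i) <= max_rank_dist)
    keep <- union(i, keep)
    proxies[[k]] <- sort(keep)
    minp[k] <- min(pos[keep]); maxp[k] <- max(pos[keep])
    regionv[[k]] <- which(pos >= minp[k] & pos <= maxp[k])
  }
  new("LDRegionSet", chrom = panelChrom(panel),
      tags = data.frame(tag = tags$vid, tagIndex = tags$tagIndex,
                        minPos = minp, maxPos = maxp,
                        stringsAsFactors = FALSE),
      proxies = proxies, regionVariants = regionv)
}

#' Candidate-pool expansion summary
#'
#' The union of all proxy sets across regions is the candidate variant
#' pool; this reports its size next to the significant set it grew from,
#' and the percent increase.
#'
#' @param regions an [LDRegionSet-class].
#' @param n_significant size of the genome-wide significant set.
#' @return list with `n_candidates`, `n_significant`, `pct_increase`.
#' @export
expansionSummary <- function(regions, n_significant) {
  pool <- unique(unlist(regionProxies(regions)))
  list(n_candidates = length(pool), n_significant = n_significant,
       pct_increase = 100 * (length(pool) - n_significant) / n_significant)
}
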