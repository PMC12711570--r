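#' Colocalization priors
#'
#' Per-SNP prior probabilities of causality for each trait and for both,
#' plus the prior variance W of the effect-size prior used by the
#' approximate Bayes factor. Defaults are the standard single-causal
#' colocalization priors for quantitative traits.
#'
#' @param p1,p2 prior a SNP is causal for trait 1 / trait 2.
#' @param p12 prior a SNP is causal for both; must satisfy
#'   0 < p12 <= min(p1, p2).
#' @param W prior effect variance (default 0.15^2).
#' @return list of class `"ColocPriors"`.
#' @export
colocPriors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, W = 0.15^2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), W > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, W = W),
            class = "ColocPriors")
}

#' Wakefield log approximate Bayes factor
#'
#' For a variant with Z-score z and standard error se (V = se^2) under a
#' Normal(0, W) effect prior:
#' log ABF = 1/2 log(V/(V+W)) + 1/2 z^2 W/(V+W) (natural log). Monotone
#' increasing in |z| at fixed V; tends to 0 as V grows (no information) and
#' is negative at z = 0 (shrinks toward no association).
#'
#' @param z signed Z-score(s).
#' @param se standard error(s), > 0.
#' @param W prior effect variance.
#' @return numeric log-ABF vector.
#' @export
logABF <- function(z, se, W = 0.15^2) {
  if (any(se <= 0)) stop("se must be positive")
  V <- se^2
  0.5 * log(V / (V + W)) + 0.5 * z^2 * W / (V + W)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Bayesian colocalization posteriors over causal configurations
#'
#' Enumerates the single-causal configurations of two traits over the SNPs
#' shared between them (intersected on vid): H0 no association, H1/H2 one
#' trait only, H3 two distinct causal variants, H4 one shared variant. With
#' per-SNP log-ABF vectors a and b, the unnormalized weights are 1 (H0),
#' p1*S1, p2*S2, p1*p2*(S1*S2 - S12) and p12*S12 where S1 = sum exp(a),
#' S2 = sum exp(b), S12 = sum exp(a+b). All sums run in log space; the H3
#' term uses log1p(-exp(logS12 - logS1 - logS2)) to avoid cancellation and
#' is clamped at zero (with a warning) if floating point drives it
#' negative. Per-SNP H4 posteriors are exp(a_i + b_i)/S12.
#'
#' @param trait1,trait2 association record data.frames (must share vids).
#' @param priors a [colocPriors()] object.
#' @param locus_id label for the result.
#' @return a [ColocResult-class].
#' @export
colocPosteriors <- function(trait1, trait2, priors = colocPriors(),
                            locus_id = "locus") {
  shared <- intersect(trait1$vid, trait2$vid)
  if (!length(shared))
    stop("no shared variants between the two traits")
  t1 <- trait1[match(shared, trait1$vid), ]
  t2 <- trait2[match(shared, trait2$vid), ]
  a <- logABF(t1$z, t1$se, priors$W)
  b <- logABF(t2$z, t2$se, priors$W)
  lS1 <- logsumexp(a)
  lS2 <- logsumexp(b)
  lS12 <- logsumexp(a + b)
  dd <- lS12 - lS1 - lS2
  lH3 <- if (dd >= 0) {
    if (dd > 1e-12)
      warning("H3 weight negative from floating point; clamped at 0")
    -Inf
  } else lS1 + lS2 + log1p(-exp(dd))
  lw <- c(H0 = 0,
          H1 = log(priors$p1) + lS1,
          H2 = log(priors$p2) + lS2,
          H3 = log(priors$p1) + log(priors$p2) + lH3,
          H4 = log(priors$p12) + lS12)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  snp <- exp(a + b - lS12)
  snp <- snp / sum(snp)
  names(snp) <- shared
  new("ColocResult", locusId = locus_id, nSnps = length(shared), pp = pp,
      snpPPH4 = snp, priors = unclass(priors))
}

#' Call a variant-to-gene pair from a colocalization result
#'
#' A pair is emitted iff PP.H4 > `pp_h4_min`, the maximum per-SNP H4
#' posterior exceeds `snp_pp_min` (its argmax is the pair's variant), and
#' the locus contains more than one variant. All comparisons are strict.
#'
#' @param result a [ColocResult-class].
#' @param eqtl association records of the eQTL trait (for the harmonized
#'   Z of the called variant and the trait labels).
#' @param pp_h4_min locus-level H4 threshold (default 0.7).
#' @param snp_pp_min per-SNP H4 threshold (default 0.5).
#' @return one-row data.frame (vid, gene_id, tissue, source, pp_h4,
#'   snp_pp_h4, z_eqtl, n_snps, locus_id) or NULL when no call.
#' @export
callV2G <- function(result, eqtl, pp_h4_min = 0.7, snp_pp_min = 0.5) {
  pp <- posteriorProb(result)
  snp <- snpPPH4(result)
  if (result@nSnps <= 1L) return(NULL)
  if (!(pp[["H4"]] > pp_h4_min)) return(NULL)
  top <- which.max(snp)
  if (!(snp[top] > snp_pp_min)) return(NULL)
  vid <- names(snp)[top]
  row <- eqtl[match(vid, eqtl$vid), ]
  zh <- harmonizeZ(row)$z
  data.frame(vid = vid,
             gene_id = row$gene_id, tissue = row$tissue,
             source = row$source, pp_h4 = unname(pp[["H4"]]),
             snp_pp_h4 = unname(snp[top]), z_eqtl = zh,
             n_snps = result@nSnps, locus_id = result@locusId,
             stringsAsFactors = FALSE)
}

#' Colocalize one LD region against per-gene, per-tissue eQTL traits
#'
#' Splits the eQTL records by (gene, tissue, source), keeps the nominally
#' significant genes (best-SNP p below `nominal_p`), restricts both traits
#' to the region's variants, and runs [colocPosteriors()] and [callV2G()]
#' for each trait independently; a variant may therefore appear in many
#' tissue-V2G pairs.
#'
#' @param region_variant_vids vids of every panel variant in the region.
#' @param gwas,eqtl association record data.frames.
#' @param priors a [colocPriors()] object.
#' @param pp_h4_min,snp_pp_min calling thresholds.
#' @param nominal_p nominal eQTL significance filter on the best SNP.
#' @param locus_id region label.
#' @return list with `results` (ColocResult list) and `pairs` (data.frame
#'   of called pairs, possibly empty).
#' @export
colocRegion <- function(region_variant_vids, gwas, eqtl,
                        priors = colocPriors(), pp_h4_min = 0.7,
                        snp_pp_min = 0.5, nominal_p = 0.05,
                        locus_id = "region") {
  g <- gwas[gwas$vid %in% region_variant_vids, , drop = FALSE]
  e <- eqtl[eqtl$vid %in% region_variant_vids, , drop = FALSE]
  if (!nrow(g) || !nrow(e))
    return(list(results = list(), pairs = .emptyPairs()))
  key <- paste(e$gene_id, e$tissue, e$source, sep = "\r")
  results <- list(); pairs <- list()
  for (k in unique(key)) {
    ek <- e[key == k, , drop = FALSE]
    if (min(ek$pvalue) >= nominal_p) next  # not nominally significant
    shared <- intersect(g$vid, ek$vid)
    if (!length(shared)) next
    lid <- paste0(locus_id, ":", gsub("\r", ":", k))
    res <- colocPosteriors(g, ek, priors, locus_id = lid)
    results[[lid]] <- res
    p <- callV2G(res, ek, pp_h4_min, snp_pp_min)
    if (!is.null(p)) pairs[[lid]] <- p
  }
  list(results = results,
       pairs = if (length(pairs)) do.call(rbind, pairs) else .emptyPairs())
}

.emptyPairs <- function() {
  data.frame(vid = character(), gene_id = character(), tissue = character(),
             source = character(), pp_h4 = numeric(), snp_pp_h4 = numeric(),
             z_eqtl = numeric(), n_snps = integer(), locus_id = character(),
             stringsAsFactors = FALSE)
}
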