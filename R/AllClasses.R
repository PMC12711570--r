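#' @import methods
#' @importFrom stats pnorm rnorm runif rbinom pchisq binom.test setNames
#'   uniroot
#' @importFrom utils read.delim write.table head tail
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Phased haplotype reference panel
#'
#' Container for a phased 0/1 haplotype matrix over biallelic SNPs on one
#' chromosome, the stand-in for a population LD reference panel. Rows are
#' haplotypes, columns are variants; 1 codes the alternative allele.
#'
#' @slot chrom single chromosome name.
#' @slot positions strictly increasing 1-based positions, one per column.
#' @slot ref,alt single-nucleotide reference/alternative alleles per column.
#' @slot haplotypes integer matrix of 0/1, n_haplotypes x n_variants.
#'
#' @examples
#' pan <- HaplotypePanel("chr1", c(100L, 200L), c("A", "C"), c("G", "T"),
#'                       matrix(c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L), 4, 2))
#' nVariants(pan)
#' @export
setClass("HaplotypePanel",
  slots = c(
    chrom = "character",
    positions = "integer",
    ref = "character",
    alt = "character",
    haplotypes = "matrix"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  n <- length(object@positions)
  if (length(object@chrom) != 1L)
    msg <- c(msg, "chrom must be a single string")
  if (ncol(object@haplotypes) != n)
    msg <- c(msg, "haplotype matrix must have one column per position")
  if (n > 1L && any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@ref) != n || length(object@alt) != n)
    msg <- c(msg, "ref and alt must have one allele per position")
  nts <- c("A", "C", "G", "T")
  if (!all(object@ref %in% nts) || !all(object@alt %in% nts))
    msg <- c(msg, "alleles must be single nucleotides in {A,C,G,T}")
  if (any(object@ref == object@alt))
    msg <- c(msg, "ref and alt must differ at every variant")
  h <- object@haplotypes
  if (!all(h %in% c(0L, 1L)))
    msg <- c(msg, "haplotype matrix must contain only 0/1")
  if (ncol(h) > 0L) {
    af <- colMeans(h)
    if (any(af == 0 | af == 1))
      msg <- c(msg, "every column must be polymorphic")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname HaplotypePanel-class
#' @param chrom,positions,ref,alt,haplotypes see slots.
#' @return a `HaplotypePanel`.
#' @export
HaplotypePanel <- function(chrom, positions, ref, alt, haplotypes) {
  mode(haplotypes) <- "integer"
  dimnames(haplotypes) <- NULL
  new("HaplotypePanel", chrom = as.character(chrom),
      positions = as.integer(positions), ref = as.character(ref),
      alt = as.character(alt), haplotypes = haplotypes)
}

#' Locus-level colocalization result
#'
#' Posterior probabilities of the five causal configurations for one locus
#' (H0 neither trait associated, H1 trait-1 only, H2 trait-2 only, H3 two
#' distinct causal variants, H4 one shared causal variant), plus the per-SNP
#' posterior of being the shared variant given H4.
#'
#' @slot locusId locus label.
#' @slot nSnps number of SNPs entering the enumeration.
#' @slot pp named numeric, posteriors for H0..H4, summing to 1.
#' @slot snpPPH4 named numeric (by vid), per-SNP posteriors given H4,
#'   summing to 1.
#' @slot priors list with elements p1, p2, p12, W.
#' @export
setClass("ColocResult",
  slots = c(
    locusId = "character",
    nSnps = "integer",
    pp = "numeric",
    snpPPH4 = "numeric",
    priors = "list"
  )
)

setValidity("ColocResult", function(object) {
  msg <- character()
  if (!identical(names(object@pp), c("H0", "H1", "H2", "H3", "H4")))
    msg <- c(msg, "pp must be named H0..H4")
  else if (abs(sum(object@pp) - 1) > 1e-9)
    msg <- c(msg, "posteriors must sum to 1 within 1e-9")
  if (object@nSnps >= 1L && abs(sum(object@snpPPH4) - 1) > 1e-9)
    msg <- c(msg, "per-SNP H4 posteriors must sum to 1 within 1e-9")
  if (length(object@snpPPH4) != object@nSnps)
    msg <- c(msg, "snpPPH4 must have one entry per SNP")
  if (length(msg)) msg else TRUE
})

#' LD analysis regions around tag variants
#'
#' One row per tag variant surviving LD pruning, with its proxy set
#' (r-squared >= the expansion threshold, subject to distance and rank caps),
#' region bounds set by the outermost proxies, and the full set of panel
#' variants inside the bounds (the colocalization input).
#'
#' @slot chrom chromosome of the panel.
#' @slot tags data.frame with columns `tag` (vid), `tagIndex`, `minPos`,
#'   `maxPos`.
#' @slot proxies list (one element per tag) of integer panel column indices,
#'   each including the tag itself.
#' @slot regionVariants list (one per tag) of panel column indices inside
#'   the bounds.
#' @export
setClass("LDRegionSet",
  slots = c(
    chrom = "character",
    tags = "data.frame",
    proxies = "list",
    regionVariants = "list"
  )
)

setValidity("LDRegionSet", function(object) {
  msg <- character()
  if (nrow(object@tags) != length(object@proxies) ||
      nrow(object@tags) != length(object@regionVariants))
    msg <- c(msg, "tags, proxies and regionVariants must be parallel")
  ok <- vapply(seq_along(object@proxies), function(i) {
    object@tags$tagIndex[i] %in% object@proxies[[i]]
  }, logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "every tag must be a member of its own proxy set")
  if (length(msg)) msg else TRUE
})
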