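#' @rdname HaplotypePanel-class
setMethod("nHaplotypes", "HaplotypePanel", function(x) nrow(x@haplotypes))

#' @rdname HaplotypePanel-class
setMethod("nVariants", "HaplotypePanel", function(x) ncol(x@haplotypes))

#' @rdname HaplotypePanel-class
setMethod("panelPositions", "HaplotypePanel", function(x) x@positions)

#' @rdname HaplotypePanel-class
setMethod("panelChrom", "HaplotypePanel", function(x) x@chrom)

#' @rdname HaplotypePanel-class
setMethod("panelVids", "HaplotypePanel", function(x) {
  makeVid(x@chrom, x@positions, x@ref, x@alt)
})

#' @rdname HaplotypePanel-class
setMethod("alleleFreq", "HaplotypePanel", function(x) colMeans(x@haplotypes))

#' @rdname HaplotypePanel-class
setMethod("haplotypeMatrix", "HaplotypePanel", function(x) x@haplotypes)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nHaplotypes(object), "haplotypes x",
      nVariants(object), "variants on", object@chrom, "\n")
  if (nVariants(object) > 0L) {
    cat("  positions:", min(object@positions), "-", max(object@positions),
        "\n  alt allele frequency: ",
        sprintf("%.3f-%.3f", min(alleleFreq(object)),
                max(alleleFreq(object))), "\n", sep = "")
  }
})

#' @rdname ColocResult-class
setMethod("posteriorProb", "ColocResult", function(x) x@pp)

#' @rdname ColocResult-class
setMethod("snpPPH4", "ColocResult", function(x) x@snpPPH4)

#' @rdname colocFdr
setMethod("colocFdr", "ColocResult", function(x) {
  unname(1 - x@pp[["H4"]])
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult '", object@locusId, "' (", object@nSnps, " SNPs)\n",
      sep = "")
  print(round(object@pp, 4))
  cat("FDR (1 - PP.H4):", signif(colocFdr(object), 4), "\n")
  if (object@nSnps > 0L) {
    top <- which.max(object@snpPPH4)
    cat("top SNP:", names(object@snpPPH4)[top], "SNP.PP.H4 =",
        signif(object@snpPPH4[top], 4), "\n")
  }
})

#' @rdname LDRegionSet-class
setMethod("nRegions", "LDRegionSet", function(x) nrow(x@tags))

#' @rdname LDRegionSet-class
setMethod("regionTags", "LDRegionSet", function(x) x@tags)

#' @rdname LDRegionSet-class
setMethod("regionProxies", "LDRegionSet", function(x) x@proxies)

#' @rdname LDRegionSet-class
setMethod("regionVariants", "LDRegionSet", function(x) x@regionVariants)

setMethod("show", "LDRegionSet", function(object) {
  cat("LDRegionSet:", nRegions(object), "regions on", object@chrom, "\n")
  if (nRegions(object)) {
    np <- lengths(object@proxies)
    cat("  proxies per region:", min(np), "-", max(np), "\n")
  }
})
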