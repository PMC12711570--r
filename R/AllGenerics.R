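#' @rdname HaplotypePanel-class
#' @param x a `HaplotypePanel`.
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("panelPositions", function(x) standardGeneric("panelPositions"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("panelChrom", function(x) standardGeneric("panelChrom"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("panelVids", function(x) standardGeneric("panelVids"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @rdname HaplotypePanel-class
#' @export
setGeneric("haplotypeMatrix", function(x) standardGeneric("haplotypeMatrix"))

#' @rdname ColocResult-class
#' @param x a `ColocResult`.
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))
#' @rdname ColocResult-class
#' @export
setGeneric("snpPPH4", function(x) standardGeneric("snpPPH4"))

#' Colocalization false-discovery rate
#'
#' The FDR implied by a colocalization result: the cumulative posterior of
#' the non-colocalized configurations, P(H0)+P(H1)+P(H2)+P(H3) = 1 - P(H4).
#' A locus-level H4 posterior of 0.95 therefore corresponds to FDR 0.05.
#'
#' @param x a [ColocResult-class] object.
#' @return numeric in \[0, 1\].
#' @examples
#' # pp.H4 = 0.95 <=> FDR 5%
#' @export
setGeneric("colocFdr", function(x) standardGeneric("colocFdr"))

#' @rdname LDRegionSet-class
#' @param x an `LDRegionSet`.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname LDRegionSet-class
#' @export
setGeneric("regionTags", function(x) standardGeneric("regionTags"))
#' @rdname LDRegionSet-class
#' @export
setGeneric("regionProxies", function(x) standardGeneric("regionProxies"))
#' @rdname LDRegionSet-class
#' @export
setGeneric("regionVariants", function(x) standardGeneric("regionVariants"))
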