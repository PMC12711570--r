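NUCLEOTIDES <- c("A", "C", "G", "T")

#' Canonical variant identifiers
#'
#' Variant identity throughout the package is the string
#' `"chrom:pos:ref:alt"` with a 1-based position and single-nucleotide
#' alleles; rsIDs are display-only labels. `makeVid()` and `parseVid()`
#' round-trip.
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt single-nucleotide alleles.
#' @return `makeVid`: character vector of vids. `parseVid`: data.frame with
#'   columns chrom, pos, ref, alt, vid.
#' @examples
#' makeVid("chr7", 54880000, "A", "G")
#' parseVid("chr7:54880000:A:G")
#' @export
makeVid <- function(chrom, pos, ref, alt) {
  stopifnot(all(ref %in% NUCLEOTIDES), all(alt %in% NUCLEOTIDES),
            all(ref != alt))
  paste(chrom, as.integer(pos), ref, alt, sep = ":")
}

#' @rdname makeVid
#' @param vid character vector of `"chrom:pos:ref:alt"` identifiers.
#' @export
parseVid <- function(vid) {
  parts <- strsplit(vid, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed vid(s): ", paste(vid[bad], collapse = ", "))
  m <- do.call(rbind, parts)
  out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                    ref = m[, 3], alt = m[, 4], vid = vid,
                    stringsAsFactors = FALSE)
  if (any(is.na(out$pos)) || !all(out$ref %in% NUCLEOTIDES) ||
      !all(out$alt %in% NUCLEOTIDES) || any(out$ref == out$alt))
    stop("malformed vid: position must be integer, alleles distinct ",
         "single nucleotides")
  out
}

#' Strand-ambiguous variants
#'
#' A/T and C/G SNPs cannot be oriented across datasets when the source
#' strand is unknown; they are kept but flagged, and harmonization refuses
#' to sign-flip them silently.
#'
#' @param ref,alt allele vectors.
#' @return logical vector.
#' @export
isStrandAmbiguous <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[ref] == alt)
}

#' Variant positions as genomic ranges
#'
#' The single point/interval conversion rule of the package: a 1-based
#' variant position pos overlaps a 0-based half-open interval \[start, end)
#' iff pos - 1 is in \[start, end), i.e. iff the width-1 1-based range
#' \[pos, pos\] intersects the 1-based closed form of the interval.
#' Interval files (BED and friends) are converted once, at read time, into
#' 1-based closed `GRanges`; variants are compared via this function.
#'
#' @param chrom,pos chromosome names and 1-based positions.
#' @return a [GenomicRanges::GRanges] of width-1 ranges.
#' @export
variantRanges <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, width = 1L))
}

# assemble an association record data.frame with derived columns
assocRecords <- function(chrom, pos, ref, alt, effect_allele, beta, se,
                         pvalue, rsid = NA_character_,
                         gene_id = NA_character_, tissue = NA_character_,
                         source = NA_character_) {
  stopifnot(all(se > 0), all(effect_allele == ref | effect_allele == alt))
  n <- length(chrom)
  rsid <- rep_len(rsid, n)
  gene_id <- rep_len(gene_id, n)
  tissue <- rep_len(tissue, n)
  source <- rep_len(source, n)
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             vid = makeVid(chrom, pos, ref, alt), rsid = rsid,
             effect_allele = effect_allele, beta = beta, se = se,
             pvalue = pvalue, z = beta / se,
             ambiguous = isStrandAmbiguous(ref, alt),
             gene_id = gene_id, tissue = tissue, source = source,
             stringsAsFactors = FALSE)
}
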