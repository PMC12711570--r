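#' Log-odds PWM score of a sequence window
#'
#' Score = sum over positions of log2(p_i(base_i) / background(base_i)).
#' Windows containing ambiguous bases (N) are skipped with a warning and
#' return NA.
#'
#' @param pwm a motif from [readMotifs()] (or any list with an L x 4
#'   probability `matrix`, columns A,C,G,T).
#' @param window character string of length L.
#' @param background background probabilities (default uniform 0.25).
#' @return numeric log2-odds score, or NA for an ambiguous window.
#' @export
pwmScore <- function(pwm, window, background = rep(0.25, 4)) {
  m <- pwm$matrix
  bases <- strsplit(toupper(window), "")[[1]]
  if (length(bases) != nrow(m))
    stop("window length must equal motif length")
  idx <- match(bases, NUCLEOTIDES)
  if (anyNA(idx)) {
    warning("window contains ambiguous base(s); skipped")
    return(NA_real_)
  }
  sum(log2(m[cbind(seq_along(idx), idx)] / background[idx]))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# best score over all placements covering position `at` (1-based index into
# seq string), both strands
.bestScore <- function(pwm, seqstr, at) {
  L <- nrow(pwm$matrix)
  n <- nchar(seqstr)
  best <- -Inf
  for (k in seq_len(L)) {       # motif position k aligned to the variant
    s <- at - k + 1L
    e <- s + L - 1L
    if (s < 1L || e > n) next
    w <- substr(seqstr, s, e)
    fs <- suppressWarnings(pwmScore(pwm, w))
    rs <- suppressWarnings(pwmScore(pwm, .revcomp(w)))
    best <- max(best, fs, rs, na.rm = TRUE)
  }
  best
}

#' Allele-specific best motif scores at a variant
#'
#' For each allele, every placement of the motif covering the variant
#' position is scored on both strands (the minus strand scores the reverse
#' complement); the per-allele score is the maximum, and
#' delta = ref_score - alt_score compares these maxima, so a variant that
#' shifts the optimal offset is handled. Variants too close to a contig
#' edge yield no hit.
#'
#' @param pwm one motif.
#' @param genome a `DNAStringSet` from [readGenome()].
#' @param chrom,pos,ref,alt the variant.
#' @return one-row data.frame (motif_id, ref_score, alt_score, delta) or
#'   NULL when the motif cannot be placed.
#' @export
bestAlleleScores <- function(pwm, genome, chrom, pos, ref, alt) {
  L <- nrow(pwm$matrix)
  if (!chrom %in% names(genome)) return(NULL)
  clen <- Biostrings::width(genome[chrom])
  s <- pos - (L - 1L); e <- pos + (L - 1L)
  if (s < 1L || e > clen) {
    message("variant ", chrom, ":", pos, " too close to contig edge for ",
            pwm$motif_id, "; no hit")
    return(NULL)
  }
  win <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
  at <- pos - s + 1L
  if (substr(win, at, at) != ref)
    warning("reference genome does not carry the ref allele at ", chrom,
            ":", pos)
  refwin <- win
  substr(refwin, at, at) <- ref
  altwin <- win
  substr(altwin, at, at) <- alt
  rs <- .bestScore(pwm, refwin, at)
  as <- .bestScore(pwm, altwin, at)
  if (!is.finite(rs) || !is.finite(as)) return(NULL)
  data.frame(motif_id = pwm$motif_id, ref_score = rs, alt_score = as,
             delta = rs - as, stringsAsFactors = FALSE)
}

#' Call TFBS disruptions from motif hits
#'
#' Keeps hits with |delta| strictly above `threshold` (default 2 on the
#' log2 scale); both loss (delta > 0) and gain (delta < 0) of binding
#' count. A variant is TFBS-positive iff the returned list is non-empty.
#'
#' @param hits data.frame of motif hits (rows from [bestAlleleScores()]).
#' @param threshold absolute delta threshold, strict.
#' @return the disrupted subset with a `disrupted` column.
#' @export
callDisruption <- function(hits, threshold = 2) {
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(motif_id = character(), ref_score = numeric(),
                      alt_score = numeric(), delta = numeric(),
                      disrupted = logical(), stringsAsFactors = FALSE))
  }
  hits$disrupted <- abs(hits$delta) > threshold
  hits[hits$disrupted, , drop = FALSE]
}

#' Scan variants against a motif library
#'
#' @param variants data.frame with chrom, pos, ref, alt (and vid).
#' @param motifs motif list from [readMotifs()].
#' @param genome `DNAStringSet`.
#' @param threshold disruption threshold passed to [callDisruption()].
#' @return data.frame with one row per disrupted (variant, motif): vid,
#'   motif_id, ref_score, alt_score, delta.
#' @export
scanVariants <- function(variants, motifs, genome, threshold = 2) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    hits <- do.call(rbind, lapply(motifs, function(m)
      bestAlleleScores(m, genome, variants$chrom[i], variants$pos[i],
                       variants$ref[i], variants$alt[i])))
    dis <- callDisruption(hits, threshold)
    if (nrow(dis)) {
      dis$vid <- variants$vid[i]
      out[[length(out) + 1L]] <- dis
    }
  }
  if (!length(out))
    return(data.frame(motif_id = character(), ref_score = numeric(),
                      alt_score = numeric(), delta = numeric(),
                      disrupted = logical(), vid = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
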