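#' Compute the four-component evidence tier for a pair
#'
#' The overall tier is the sum of four components:
#' * `v2g_eqtl` (1-4): one point per true eQTL feature — directionality
#'   consistent across non-reference eQTL sources, presence of
#'   non-reference brain eQTLs, agreement between non-reference and
#'   reference brain-region eQTLs, and a negative consistent Z across brain
#'   regions — floored at 1 (a colocalized pair starts at 1).
#' * `v2g_epi` (0-2): one point per EPI source containing the pair, capped
#'   at 2.
#' * `v` (0-4): count of true variant-evidence flags (histone, ATAC,
#'   effect prediction, other GWAS).
#' * `g` (0-2): count of true gene-evidence flags (nominated,
#'   brain-expressed).
#' The components sum to at most 12 arithmetically; a value of 12 is
#' surfaced with a warning since the intended overall range is 1-11.
#'
#' @param eqtl_flags named logical: `directionality`, `presence`,
#'   `agreement`, `negative_consistent`.
#' @param n_epi_sources number of EPI sources with the pair present.
#' @param evidence list from [evidenceProfiles()].
#' @param epi_cap cap on the EPI component (default 2).
#' @return list of class `"TierScore"`: v2g_eqtl, v2g_epi, v, g, overall.
#' @export
computeTiers <- function(eqtl_flags, n_epi_sources, evidence, epi_cap = 2) {
  stopifnot(all(c("directionality", "presence", "agreement",
                  "negative_consistent") %in% names(eqtl_flags)))
  v2g_eqtl <- max(1L, sum(unlist(eqtl_flags[c("directionality", "presence",
                                              "agreement",
                                              "negative_consistent")])))
  v2g_epi <- min(epi_cap, as.integer(n_epi_sources))
  v <- sum(unlist(evidence$variant))
  g <- sum(unlist(evidence$gene))
  overall <- v2g_eqtl + v2g_epi + v + g
  if (overall > 11L)
    warning("overall tier of 12 reached; intended range is 1-11")
  structure(list(v2g_eqtl = as.integer(v2g_eqtl),
                 v2g_epi = as.integer(v2g_epi), v = as.integer(v),
                 g = as.integer(g), overall = as.integer(overall)),
            class = "TierScore")
}

#' Rank scored pairs
#'
#' Descending overall tier; ties broken by descending PP.H4 then
#' lexicographic vid (deterministic).
#'
#' @param scored data.frame with columns `overall`, `pp_h4`, `vid` (plus
#'   any component columns).
#' @return the data.frame re-ordered, with a `rank` column.
#' @export
rankPairs <- function(scored) {
  if (!nrow(scored)) {
    scored$rank <- integer(0)
    return(scored)
  }
  ord <- order(-scored$overall, -scored$pp_h4, scored$vid)
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
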