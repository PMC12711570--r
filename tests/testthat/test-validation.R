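mkRecords <- function(effect_allele, z, ref = "A", alt = "G",
                      gene = "GENE1", source = "src", tissue = "t") {
  n <- length(z)
  v2gtier:::assocRecords(chrom = rep("chr1", n), pos = seq_len(n) * 100,
                         ref = rep(ref, n), alt = rep(alt, n),
                         effect_allele = effect_allele, beta = z * 0.1,
                         se = rep(0.1, n), pvalue = 2 * pnorm(-abs(z)),
                         gene_id = gene, tissue = tissue, source = source)
}

test_that("harmonization orients Z to the ALT allele and is idempotent", {
  rec <- mkRecords(c("G", "A"), c(1.7, 1.7))
  h <- harmonizeZ(rec)
  expect_equal(h$z, c(1.7, -1.7))       # ALT unchanged, REF flipped
  expect_equal(h$effect_allele, c("G", "G"))
  expect_equal(h$beta, c(0.17, -0.17))
  # re-harmonizing the harmonized records changes nothing
  h2 <- harmonizeZ(h)
  expect_equal(h2$z, h$z)
  expect_false(any(h2$flipped))
  # effect allele matching neither allele is rejected
  bad <- rec; bad$effect_allele[1] <- "T"
  expect_error(harmonizeZ(bad), "neither")
})

test_that("strand-ambiguous variants are never flipped silently", {
  rec <- mkRecords("A", 2.0, ref = "A", alt = "T")  # A/T ambiguous, REF
  h_known <- harmonizeZ(rec, strand_known = TRUE)
  expect_equal(h_known$z, -2.0)  # strand known: flip is safe
  expect_message(h_unk <- harmonizeZ(rec, strand_known = FALSE),
                 "not flipped")
  expect_equal(h_unk$z, 2.0)     # left alone...
  expect_true(h_unk$excluded)    # ...and excluded from consistency
})

test_that("directionality verdicts count disagreeing groups", {
  ev <- function(ref_z, group_z) {
    rbind(data.frame(z = ref_z, group = "ref", role = "reference"),
          data.frame(z = group_z,
                     group = paste0("g", seq_along(group_z)),
                     role = "external"))
  }
  # all groups share the reference sign -> consistent, fraction 0
  v <- directionalityConsistency(ev(2, c(1, 3, 0.5)))
  expect_false(v$inconsistent)
  expect_equal(v$fraction_disagree, 0)
  # 3 of 4 groups disagree -> fraction 0.75 -> inconsistent
  v2 <- directionalityConsistency(ev(2, c(-1, -2, -0.5, 1)))
  expect_equal(v2$n_disagree, 3L)
  expect_equal(v2$fraction_disagree, 0.75)
  expect_true(v2$inconsistent)
  # exactly half disagreeing is NOT inconsistent (strict > 0.5)
  v3 <- directionalityConsistency(ev(2, c(-1, 1)))
  expect_false(v3$inconsistent)
  # zero-Z groups leave the denominator
  v4 <- directionalityConsistency(ev(2, c(0, -1)))
  expect_equal(v4$n_groups, 1L)
  # no reference evidence -> undetermined
  v5 <- directionalityConsistency(
    data.frame(z = 1, group = "g1", role = "external"))
  expect_true(v5$undetermined)
})

test_that("harmonization repairs sign scrambles from random effect-allele reporting", {
  worse <- 0
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- 12
      true_z <- abs(rnorm(1, 3, 1))          # one true positive direction
      report_ref <- runif(n) < 0.5           # random reporting allele
    })
    z_raw <- ifelse(report_ref, -true_z, true_z)
    rec <- mkRecords(ifelse(report_ref, "A", "G"), z_raw)
    rec$group <- paste0("g", seq_len(n))
    mkev <- function(z) rbind(
      data.frame(z = true_z, group = "ref", role = "reference"),
      data.frame(z = z, group = rec$group, role = "external"))
    v_before <- directionalityConsistency(mkev(z_raw))
    v_after <- directionalityConsistency(mkev(harmonizeZ(rec)$z))
    expect_equal(v_after$n_disagree, 0L)   # truth has a single sign
    if (v_after$n_disagree > v_before$n_disagree) worse <- worse + 1
  }
  expect_equal(worse, 0)  # harmonization never increases inconsistency
})

test_that("McNemar improvement reproduces the printed arithmetic", {
  # 35/41 inconsistent before, 6/41 after, all repaired pairs discordant
  before <- c(rep(TRUE, 35), rep(FALSE, 6))
  after <- c(rep(FALSE, 29), rep(TRUE, 6), rep(FALSE, 6))
  m <- mcnemarImprovement(before, after)
  expect_equal(m$percent_reduction, 83)
  expect_equal(m$b, 29L)
  expect_equal(m$c, 0L)
  expect_equal(m$statistic, 29.0)
  expect_lt(m$p_value, 1e-4)
  # exact two-sided binomial oracle: 2 * 0.5^29
  m_ex <- mcnemarImprovement(before, after, method = "exact")
  expect_equal(m_ex$p_value, 2 * 0.5^29, tolerance = 1e-9)
})

test_that("McNemar degenerate and agreement properties", {
  flags <- c(TRUE, TRUE, FALSE)
  m <- mcnemarImprovement(flags, flags)
  expect_true(m$undefined)
  expect_equal(m$p_value, 1)
  expect_equal(m$percent_reduction, 0)
  # chi-squared and exact agree in significance direction when b+c >= 25
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- 60
      before <- runif(n) < 0.7
      after <- before & (runif(n) < 0.4)
    })
    bc <- sum(before != after)
    if (bc < 25) next
    pe <- mcnemarImprovement(before, after, method = "exact")$p_value
    pc <- mcnemarImprovement(before, after, method = "chisq")$p_value
    expect_equal(pe < 0.05, pc < 0.05)
  }
})

test_that("dual-anchor EPI support is orientation-symmetric; TAD needs both ends", {
  f <- writeGeneBed(bed12Line("chr1", 9999, 12000, "GENE1|mRNA", "+",
                              9999, 12000, 2001, 0))
  models <- readGeneModels(f)  # TSS 10000, promoter 9000-10000
  mkP <- function(a1s, a1e, a2s, a2e, src = "S1") {
    p <- S4Vectors::Pairs(
      GenomicRanges::GRanges("chr1", IRanges::IRanges(a1s, a1e)),
      GenomicRanges::GRanges("chr1", IRanges::IRanges(a2s, a2e)))
    S4Vectors::mcols(p) <- S4Vectors::DataFrame(assay = "HiC", source = src,
                                                celltype = "brain")
    p
  }
  vid <- "chr1:500:A:G"
  # variant in left anchor, promoter in right anchor -> supported
  s1 <- epiTadSupport(vid, "GENE1", mkP(400, 600, 9500, 9700), NULL, models)
  expect_true(s1$epi_supported)
  # swapped orientation still supported
  s2 <- epiTadSupport(vid, "GENE1", mkP(9500, 9700, 400, 600), NULL, models)
  expect_true(s2$epi_supported)
  # promoter outside the partner anchor -> unsupported
  s3 <- epiTadSupport(vid, "GENE1", mkP(400, 600, 20000, 21000), NULL,
                      models)
  expect_false(s3$epi_supported)
  # sources counted once each
  s4 <- epiTadSupport(vid, "GENE1",
                      c(mkP(400, 600, 9500, 9700, "S1"),
                        mkP(450, 650, 9500, 9700, "S1"),
                        mkP(400, 600, 9500, 9700, "S2")), NULL, models)
  expect_equal(s4$n_epi_sources, 2L)
  # TADs: same domain must contain the variant AND the TSS
  tad_both <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 15000))
  tad_one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000))
  expect_true(epiTadSupport(vid, "GENE1", mkP(1, 2, 3, 4), tad_both,
                            models)$tad_supported)
  expect_false(epiTadSupport(vid, "GENE1", mkP(1, 2, 3, 4), tad_one,
                             models)$tad_supported)
  # unknown gene -> no support, logged
  expect_message(s5 <- epiTadSupport(vid, "NOPE", mkP(1, 2, 3, 4), tad_both,
                                     models), "absent")
  expect_false(s5$epi_supported)
})

test_that("eQTL replication needs same vid, gene and harmonized direction", {
  pairz <- -2.5  # harmonized pair effect (ALT decreases expression)
  ext <- mkRecords(c("G", "A", "G"), c(-1, 2.5, -3),
                   source = c("metabrain", "eqtlcat", "other"))
  # metabrain: ALT-reported, same sign -> replicated
  # eqtlcat: REF-reported +2.5 -> flips to -2.5 -> replicated
  # 'other': same sign but wrong gene -> not replicated
  ext$gene_id[3] <- "GENE2"
  ext$vid <- rep(ext$vid[1], 3)
  ext$pos <- rep(ext$pos[1], 3)
  r <- eqtlReplication(ext$vid[1], "GENE1", pairz, ext)
  expect_true(r[["metabrain"]])
  expect_true(r[["eqtlcat"]])
  expect_false(r[["other"]])
  # opposite harmonized sign does not replicate
  r2 <- eqtlReplication(ext$vid[1], "GENE1", 2.5, ext)
  expect_false(r2[["metabrain"]])
})

test_that("evidence profiles apply strict thresholds and OR semantics", {
  vev <- data.frame(vid = "v1", cadd = 10, regdb = "7", histone_q = 0.2,
                    atac = FALSE, other_gwas = FALSE)
  gev <- data.frame(gene_id = "g1", nominated = FALSE,
                    brain_expressed = FALSE)
  # empty tables -> all false
  p0 <- evidenceProfiles("vx", "gx", vev[0, ], gev[0, ])
  expect_false(any(unlist(p0$variant)))
  expect_false(any(unlist(p0$gene)))
  # CADD exactly 10 fails the strict > 10 rule
  p1 <- evidenceProfiles("v1", "g1", vev, gev)
  expect_false(p1$variant$effect_pred)
  # RegDB 1d rescues the disjunction even with low CADD
  vev$cadd <- 3; vev$regdb <- "1d"
  expect_true(evidenceProfiles("v1", "g1", vev, gev)$variant$effect_pred)
  # malformed RegDB rank warns and is treated as absent
  vev$regdb <- "zz"
  expect_warning(p3 <- evidenceProfiles("v1", "g1", vev, gev), "malformed")
  expect_false(p3$variant$effect_pred)
  # histone strict q < 0.05
  vev$regdb <- "7"
  vev$histone_q <- 0.05
  expect_false(evidenceProfiles("v1", "g1", vev, gev)$variant$histone)
  vev$histone_q <- 0.049
  expect_true(evidenceProfiles("v1", "g1", vev, gev)$variant$histone)
})
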