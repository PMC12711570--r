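test_that("r-squared matches the haplotype-count formula", {
  # identical columns -> self-LD of 1
  pan <- panelFromCounts(c(4, 0, 0, 4))
  expect_equal(computeR2(pan, 1, 2), 1.0)
  expect_equal(computeR2(pan, 1, 1), 1.0)

  # perfectly balanced counts -> independence
  expect_equal(computeR2(panelFromCounts(c(2, 2, 2, 2)), 1, 2), 0.0)

  # AB=3, Ab=1, aB=1, ab=3: pA=pB=0.5, pAB=0.375, D=0.125 -> 0.25
  expect_equal(computeR2(panelFromCounts(c(3, 1, 1, 3)), 1, 2), 0.25)

  # symmetric, agrees with signed correlation squared
  pan2 <- panelFromCounts(c(5, 2, 1, 4))
  expect_equal(computeR2(pan2, 1, 2), computeR2(pan2, 2, 1))
  expect_equal(computeR2(pan2, 1, 2),
               cor(haplotypeMatrix(pan2))[1, 2]^2)
  expect_equal(signedLD(pan2), cor(haplotypeMatrix(pan2)),
               ignore_attr = TRUE)
})

test_that("greedy pruning keeps the lowest-p variant among linked ones", {
  # three variants in perfect LD: the single tag is the lowest-p variant
  h <- matrix(rep(c(0L, 1L), each = 4), 8, 3)
  pan <- panelFromMatrix(h, positions = c(1000L, 2000L, 3000L))
  g <- gwasOverPanel(pan, z = c(7, 7, 7))
  g$pvalue <- c(1e-9, 1e-10, 1e-8)
  tags <- pruneVariants(g, pan, p_thresh = 5e-8)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$vid, g$vid[2])

  # a single significant variant is its own tag
  g1 <- g; g1$pvalue <- c(1e-9, 0.5, 0.5)
  expect_equal(pruneVariants(g1, pan)$vid, g$vid[1])
})

test_that("pruning window: linked variants beyond the window both tag", {
  h <- matrix(rep(c(0L, 1L), each = 8), 16, 2)
  h[1, 2] <- 1L - h[1, 2]  # r2 high but < 1
  pan <- panelFromMatrix(h, positions = c(1000L, 601000L))
  expect_gt(computeR2(pan, 1, 2), 0.7)
  g <- gwasOverPanel(pan, z = c(7, 7))
  g$pvalue <- c(1e-10, 1e-9)
  tags <- pruneVariants(g, pan, window_bp = 5e5)
  expect_equal(nrow(tags), 2L)
  # same pair inside the window collapses to one tag
  pan2 <- panelFromMatrix(h, positions = c(1000L, 401000L))
  expect_equal(nrow(pruneVariants(g <- gwasOverPanel(pan2, c(7, 7)),
                                  pan2)), 1L)
})

test_that("variants absent from the panel are logged and excluded", {
  pan <- generateHaplotypePanel(n_hap = 40, n_var = 10, seed = 1)
  g <- gwasOverPanel(pan, z = rep(8, 10))
  g$vid[1] <- "chr1:999999999:A:G"
  expect_message(tags <- pruneVariants(g, pan), "absent from the panel")
  expect_false("chr1:999999999:A:G" %in% tags$vid)
})

test_that("pruning is idempotent and accepted tags are pairwise unlinked", {
  pan <- generateHaplotypePanel(n_hap = 100, n_var = 80, seed = 11,
                                switch_prob = 0.3)
  withr::with_seed(5, z <- rnorm(80, 0, 4))
  g <- gwasOverPanel(pan, z)
  tags <- pruneVariants(g, pan, p_thresh = 0.05, prune_r2 = 0.5,
                        window_bp = 1e6)
  # every accepted pair within the window has r2 < threshold
  if (nrow(tags) > 1) {
    for (i in 1:(nrow(tags) - 1)) for (j in (i + 1):nrow(tags)) {
      if (abs(tags$pos[i] - tags$pos[j]) <= 1e6)
        expect_lt(computeR2(pan, tags$tagIndex[i], tags$tagIndex[j]), 0.5)
    }
  }
  # idempotence: pruning the tag set returns the tag set
  g2 <- g[match(tags$vid, g$vid), ]
  tags2 <- pruneVariants(g2, pan, p_thresh = 0.05, prune_r2 = 0.5,
                         window_bp = 1e6)
  expect_identical(tags2$vid, tags$vid)
  # every tag is genome-wide significant at the configured threshold
  expect_true(all(tags$pvalue < 0.05))
})

test_that("region expansion applies r2, distance and rank caps", {
  # tag with no qualifying proxies -> region is the tag alone
  h <- cbind(rep(c(0L, 1L), 4), rep(c(0L, 1L, 1L, 0L), 2))
  pan <- panelFromMatrix(h, positions = c(1000L, 2000L))
  expect_lt(computeR2(pan, 1, 2), 0.7)
  tags <- data.frame(vid = panelVids(pan)[1], tagIndex = 1L, pos = 1000L,
                     pvalue = 1e-9)
  reg <- expandRegions(tags, pan)
  expect_equal(regionProxies(reg)[[1]], 1L)
  expect_equal(regionTags(reg)$minPos, 1000L)
  expect_equal(regionTags(reg)$maxPos, 1000L)

  # a perfect proxy 2 Mb away is excluded by the base-pair cap
  h2 <- matrix(rep(c(0L, 1L), each = 4), 8, 2)
  pan2 <- panelFromMatrix(h2, positions = c(1000L, 2001000L))
  tags2 <- data.frame(vid = panelVids(pan2)[1], tagIndex = 1L,
                      pos = 1000L, pvalue = 1e-9)
  expect_equal(regionProxies(expandRegions(tags2, pan2))[[1]], 1L)
  # ... and included once the cap allows it
  expect_equal(regionProxies(expandRegions(tags2, pan2, max_bp = 3e6))[[1]],
               c(1L, 2L))

  # rank-distance cap
  expect_equal(regionProxies(expandRegions(tags2, pan2, max_bp = 3e6,
                                           max_rank_dist = 0))[[1]], 1L)
})

test_that("every proxy is in LD with its tag; region variants fill bounds", {
  pan <- generateHaplotypePanel(n_hap = 120, n_var = 60, seed = 9)
  g <- gwasOverPanel(pan, c(rep(0, 29), 8, rep(0, 30)))
  tags <- pruneVariants(g, pan)
  reg <- expandRegions(tags, pan)
  for (k in seq_len(nRegions(reg))) {
    ti <- regionTags(reg)$tagIndex[k]
    for (p in regionProxies(reg)[[k]])
      expect_gte(computeR2(pan, ti, p), 0.7)
    pos <- panelPositions(pan)[regionVariants(reg)[[k]]]
    expect_true(all(pos >= regionTags(reg)$minPos[k] &
                    pos <= regionTags(reg)$maxPos[k]))
    # every panel variant inside the bounds is included
    expect_setequal(regionVariants(reg)[[k]],
                    which(panelPositions(pan) >= regionTags(reg)$minPos[k] &
                          panelPositions(pan) <= regionTags(reg)$maxPos[k]))
  }
  s <- expansionSummary(reg, nrow(tags))
  expect_gte(s$n_candidates, s$n_significant)
})
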