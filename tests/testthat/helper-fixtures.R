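# Shared fixtures, all built in code.

# panel with two columns whose joint haplotype counts are given:
# counts = c(AB, Ab, aB, ab) where the "A"/"B" alleles are coded 1
panelFromCounts <- function(counts, positions = c(100L, 200L)) {
  combos <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  h <- combos[rep(1:4, counts), , drop = FALSE]
  HaplotypePanel("chr1", positions, ref = c("A", "A"), alt = c("G", "G"),
                 haplotypes = h)
}

# panel from an explicit haplotype matrix (alleles A>G everywhere)
panelFromMatrix <- function(h, positions = NULL, chrom = "chr1") {
  if (is.null(positions)) positions <- seq_len(ncol(h)) * 100L
  HaplotypePanel(chrom, positions, ref = rep("A", ncol(h)),
                 alt = rep("G", ncol(h)), haplotypes = h)
}

# association records over a panel with chosen p-values/z
gwasOverPanel <- function(panel, z, n_samples = 10000) {
  se <- 1 / sqrt(n_samples)
  v2gtier:::assocRecords(
    chrom = panelChrom(panel), pos = panelPositions(panel),
    ref = panel@ref, alt = panel@alt, effect_allele = panel@alt,
    beta = z * se, se = se, pvalue = 2 * pnorm(-abs(z)))
}

# brute-force colocalization oracle: explicit enumeration of every
# single-causal configuration (plain arithmetic, no log-space tricks)
oracleColoc <- function(z1, se1, z2, se2, p1 = 1e-4, p2 = 1e-4,
                        p12 = 1e-5, W = 0.15^2) {
  abf <- function(z, se) {
    V <- se^2
    sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))
  }
  A <- abf(z1, se1)
  B <- abf(z2, se2)
  n <- length(A)
  w0 <- 1
  w1 <- sum(p1 * A)
  w2 <- sum(p2 * B)
  w3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) w3 <- w3 + p1 * p2 * A[i] * B[j]
  w4v <- p12 * A * B
  w <- c(H0 = w0, H1 = w1, H2 = w2, H3 = w3, H4 = sum(w4v))
  list(pp = w / sum(w), snp = w4v / sum(w4v))
}

# random association records for property tests
randomRecords <- function(n, seed) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(1e6, n))
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    z <- rnorm(n, 0, 3)
    se <- runif(n, 0.01, 0.5)
    v2gtier:::assocRecords("chr1", pos, ref, alt, effect_allele = alt,
                           beta = z * se, se = se,
                           pvalue = 2 * pnorm(-abs(z)))
  })
}

# write a BED12 line
bed12Line <- function(chrom, start, end, name, strand, thickStart,
                      thickEnd, sizes, starts) {
  sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s", chrom, start,
          end, name, strand, thickStart, thickEnd, length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","))
}

writeGeneBed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# random plausible gene models for partition property tests
randomGeneModels <- function(n_genes, seed) {
  withr::with_seed(seed, {
    lines <- character(n_genes)
    for (i in seq_len(n_genes)) {
      start <- sample.int(5e5, 1)
      n_ex <- sample(1:4, 1)
      sizes <- sample(100:500, n_ex, replace = TRUE)
      gaps <- if (n_ex > 1) sample(200:2000, n_ex - 1, replace = TRUE)
              else integer(0)
      starts <- cumsum(c(0, head(sizes, -1) + gaps))
      end <- start + starts[n_ex] + sizes[n_ex]
      # CDS somewhere inside the transcript
      cs <- start + sample.int(starts[n_ex] + sizes[n_ex] - 2L, 1)
      ce <- cs + sample.int(max(1L, end - cs - 1L), 1)
      lines[i] <- bed12Line("chr1", start, end,
                            paste0("G", i, "|mRNA"),
                            sample(c("+", "-"), 1), cs, ce, sizes, starts)
    }
    writeGeneBed(lines)
  })
}
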