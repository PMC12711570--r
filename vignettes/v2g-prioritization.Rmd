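---
title: "Prioritizing variant-to-gene pairs from GWAS summary statistics"
author: "v2gtier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing variant-to-gene pairs from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v2gtier)
```

# The problem

Most disease-associated variants found by genome-wide association studies
(GWAS) are non-coding, and the gene a variant regulates — its *effector*
gene — is rarely the nearest one. Linking a risk variant V to its gene G (a
"V2G pair") requires combining several independent lines of regulatory
evidence: shared causal signals between the GWAS and expression QTLs,
disruption of transcription-factor binding, enhancer context in the right
tissue, chromatin contact between the variant and the gene's promoter, and
replication of the effect direction in independent expression datasets.
`v2gtier` implements this post-GWAS framework as a four-stage pipeline —
Preprocess, Characterize, Validate, Tier — driven entirely by plain-text
inputs, plus a synthetic-data module that generates every input with a
planted, known answer so the whole pipeline is testable without any
external download.

# Stage 1 — Preprocess: LD pruning and expansion

Starting from genome-wide significant variants (p < 5×10⁻⁸), greedy
pruning walks candidates in ascending p-value order and accepts a variant
as a *tag* iff its r² with every previously accepted tag within a 500 kb
window stays below 0.7. Each tag is then expanded into an analysis region:
all panel variants with r² ≥ 0.7 to the tag, within 1 Mb and within 1000
variants of it (rank distance along the chromosome). Region bounds are the
outermost proxies, and *every* panel variant inside the bounds — associated
or not — enters colocalization, since the eQTL side needs the full local
signal.

Choices the method leaves open, resolved here:

* **Pruning order.** Ascending p-value with ties broken by (chrom, pos),
  matching standard clumping practice; the acceptance order is the tag
  order.
* **Window convention.** The 500 kb window is applied as ± 500 kb around
  each tag (configurable).
* **"Within 1000 variants".** Interpreted as rank distance among panel
  variants on the chromosome; configurable.
* Variants absent from the panel carry no LD information and can be
  neither tags nor proxies; they are logged and excluded.

LD itself is the squared allelic correlation from phased haplotype counts,
r² = D²/(pA(1−pA)pB(1−pB)) with D = pAB − pA·pB. The *signed* correlation
r is retained because the synthetic simulator propagates Z-score direction
through it.

# Stage 2 — Characterize

## Genome partition

Candidate variants are classified against a hierarchical, disjoint genome
partition built from gene models: 5′UTR exon > 5′UTR intron > 3′UTR exon >
3′UTR intron > promoter > mRNA exon > mRNA intron, each class's merged
intervals minus everything higher in the hierarchy, so the seven sets are
pairwise disjoint by construction and every variant receives exactly one
primary label (else "intergenic") plus independent repeat and lncRNA
flags. Promoters are the 1000 bp immediately upstream of the TSS,
strand-aware. UTR boundaries derive from the BED12 thick (CDS) region —
the portable equivalent of a transcript-model database. Coordinates follow
one rule everywhere: interval files are 0-based half-open on disk,
converted once at read time to 1-based closed ranges; a variant at 1-based
position *pos* overlaps a file interval [start, end) iff pos − 1 ∈
[start, end).

## Colocalization

For each region and each (gene, tissue, source) eQTL trait that is
nominally significant (best SNP p < 0.05; the nominal threshold is a
package choice, configurable), the package computes Wakefield approximate
Bayes factors per SNP,

log ABF = ½·log(V/(V+W)) + ½·z²·W/(V+W),  V = se²,

and enumerates the five single-causal configurations: H0 (neither trait),
H1/H2 (one trait only), H3 (two distinct causal variants), H4 (one shared
variant). With per-SNP log-ABF vectors a, b and S1 = Σeᵃ, S2 = Σeᵇ,
S12 = Σeᵃ⁺ᵇ, the unnormalized weights are 1, p1·S1, p2·S2,
p1·p2·(S1·S2 − S12), p12·S12. Defaults p1 = p2 = 10⁻⁴, p12 = 10⁻⁵ and
W = 0.15² (quantitative traits) are the standard single-causal priors; the
method paper names the software version but not priors, so these are
explicit, configurable defaults. All sums run in log space; the H3 term is
computed as log S1 + log S2 + log1p(−exp(log S12 − log S1 − log S2)) to
avoid catastrophic cancellation, clamped at zero probability with a
warning if floating point drives it negative (e.g. single-SNP loci, where
S1·S2 = S12 exactly).

A V2G pair is *called* iff PP.H4 > 0.7, the top per-SNP posterior
SNP.PP.H4 > 0.5 (its argmax is the pair's variant), and the locus holds
more than one variant — all comparisons strict. The implied false-discovery
rate is the identity FDR = P(H0)+P(H1)+P(H2)+P(H3) = 1 − P(H4), so
PP.H4 = 0.95 corresponds to FDR 5%. Correctness is pinned by an exhaustive
configuration-enumeration oracle in the test suite (≤ 8-SNP loci, 10⁻⁸
relative agreement).

## TFBS disruption and enhancer confluence

Each called variant is scored against a motif library: for each allele,
every placement of the motif covering the variant is scored on both
strands (score = Σ log₂(pᵢ(base)/background), uniform background,
probability floor 0.001), and the per-allele maximum is kept. The delta is
the difference of maxima — comparing per-allele optima rather than
same-placement scores is the one free choice the method leaves open, and
is robust when the variant shifts the optimal offset. A motif is disrupted
iff |delta| > 2 (strict; gains and losses both count). The original
pipeline uses a different software stack whose score scale is not
restated, so the |2| threshold applies on this package's log₂ scale and is
exposed as a parameter.

A called pair survives confluence iff the variant additionally overlaps at
least one enhancer interval *and* some enhancer's tissue maps to the
pair's eQTL tissue under an explicit many-to-many tissue map (default:
exact label match). The original's metadata-driven tissue matching is not
reproducible, so the map is an explicit input. Whether the binding site
must lie inside the enhancer is unstated in the method; the two criteria
are applied independently to the variant.

# Stage 3 — Validate

Effect directions are harmonized to the ALT allele of the canonical
variant id (`chrom:pos:ref:alt`): records reported on REF are sign-flipped;
harmonization is idempotent. Strand-ambiguous A/T and C/G SNPs are never
flipped silently — when the reporting strand is unknown they are flagged
and excluded from consistency counting, preserving auditability.

Directionality consistency compares, per pair, the sign of each
(source, brain-region group) mean Z against a reference sign, chosen as
the sign of the mean Z over the reference-role (discovery) eQTL evidence —
the middle-panel "average Z" convention; majority vote is an alternative
the package exposes through the evidence table. A pair is inconsistent
iff more than half the groups disagree (strict). Pre- vs
post-harmonization inconsistency is compared by McNemar's test on the
discordant counts b and c: χ² = (b−c)²/(b+c) without continuity
correction, switching to the exact two-sided binomial automatically when
b + c < 25.

Chromatin support uses the dual-anchor rule: a pair has EPI support iff
the variant falls in one anchor and the gene's promoter (same 1000 bp
definition as the partition; the gene-body alternative is configurable by
supplying wider anchors) intersects the other, in either orientation; TAD
support iff variant and TSS share a TAD interval. Independent eQTL
replication requires the same variant, same gene and same harmonized
direction in an external source. Variant-level evidence flags are histone
peak overlap at q < 0.05, open chromatin, effect prediction (CADD > 10 or
RegulomeDB rank 1a–1e), and association in another GWAS of the same
disease; gene-level flags are nomination and brain expression. Each family
of checks requires at least one, not all, criteria.

# Stage 4 — Tier

Four additive components: V2G_eQTL (1–4; one point per eQTL feature —
non-reference directionality consistency, non-reference presence,
reference/non-reference agreement, negative consistent Z — floored at 1
because a colocalized pair starts with one point; which feature is the
guaranteed baseline is unstated in the method, so the floor is the
documented choice), V2G_EPI (0–2; one point per EPI source, capped at 2),
V_tier (0–4 variant flags), G_tier (0–2 gene flags). The overall tier is
the plain sum. Arithmetically the components can reach 12 while the
intended range is 1–11; the constraint making 12 unreachable is not
stated, so the package keeps the plain sum and emits a warning when 12
occurs. Ranking is by descending overall tier, then descending PP.H4, then
lexicographic variant id — fully deterministic.

# The synthetic-data generator

The generator defines the package's study conditions; it is not a tuning
dial.

* **Haplotypes** follow a template-copying model: 4 template haplotypes,
  blocks of 10 variants, a 0.3 chance of switching to a random template at
  each block boundary, 2% per-site mutation noise, minor allele frequency
  floor 0.05 (columns are resampled until the floor holds), ~1.5 kb mean
  spacing. These values are chosen once to give the two features the
  pipeline exercises — near-perfect local LD and long-range r² below 0.1 so
  that distinct-causal configurations exist — and approximate the scale of
  LD decay in a dense reference panel.
* **Summary statistics** are simulated at the Z level: Z ~ MVN(r_c·ncp, R)
  where R is the panel's signed LD matrix and r_c its causal column, the
  standard LD-propagation model for summary statistics (a 10⁻⁶ ridge keeps
  the Cholesky factor defined with perfect proxies). Marginally each
  variant has Z ~ N(r·ncp, 1); using the full covariance makes the noise
  LD-consistent, which is what real summary statistics look like and what
  colocalization assumes. Defaults: ncp = 8 for both traits (a strong,
  unambiguous planted signal), n = 10 000 samples (se = 1/√n = 0.01),
  effect allele always ALT.
* **Scenarios** plant `shared` (one causal column for both traits),
  `distinct` (two columns with r² < 0.1) or `null` configurations, and
  record the truth. The annotation bundle is truth-consistent: the planted
  causal variant sits inside an enhancer matching the eQTL tissue, under a
  motif whose reference allele matches the genome (delta ≈ log₂(0.95/0.04)
  at the variant column), inside EPI anchors paired with the target gene's
  promoter and a TAD containing both, with evidence tables satisfying all
  four variant criteria and both gene criteria — so the expected tier of
  the planted pair is known by construction. Decoy tracks overlap nothing.

What the generator does *not* emulate: realistic human LD maps or
coalescent genealogies, indels, allele-frequency/effect-size coupling,
sample overlap between GWAS and eQTL, or case-control asymmetry (one
effect-variance prior W serves both traits; whether the original analysis
used a binary-trait prior for the disease side is unstated, so W is
configurable per run). Passing tests therefore demonstrate correctness of
the machinery and calibrated behavior under the stated model, not
performance on real cohort data — in particular, the real-data headline
counts of the original study are out of reach by design.

# Numerical and scale choices

Problem sizes used by the test suite are desk-scale by choice: panels of
200 haplotypes × 100 variants for power runs (100 replicates per
scenario kind), 1000 randomized loci for normalization checks, 50 seeds
for sign-scramble cohorts, the full 4096-point flag lattice for tier
monotonicity. Degenerate inputs are handled explicitly: single-SNP loci
(H3 weight exactly zero, no V2G call), monomorphic panel columns
(rejected), variants at contig edges (no motif hit, logged), zero-length
BED intervals (format error), empty GWAS (clean "0 regions" exit),
b + c = 0 in McNemar (p = 1 with an undefined flag). Ties in ranking are
broken deterministically; reruns of the pipeline with the same
configuration are byte-identical.

# Known limitations

Single-causal colocalization only (no multi-causal/fine-mapped variant
sets); no conditional analysis; no multi-ancestry panels; minimal
haplotype-panel input format rather than full VCF genotype parsing; the
effect-allele convention of input files must be explicit (an
`effect_allele` column is required rather than assumed to be ALT).
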