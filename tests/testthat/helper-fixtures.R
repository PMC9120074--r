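# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small LD cohort: 12 blocks x 20 variants, 800 samples.
smallCohort <- function() memo("smallCohort", {
  blocks <- lapply(1:12, function(b) ldBlockSpec(20, 0.8))
  simulateLDGenotypes(blocks, 800, seed = 42)
})

# A polygenic study on the small cohort: phenotype, base stats, harmonized.
smallStudy <- function() memo("smallStudy", {
  G <- smallCohort()
  arch <- architectureSpec(25, 0.5, 0.1, seed = 42)
  phen <- simulateLiabilityPhenotype(G, arch)
  ss <- simulateBaseSumstats(G, arch, 50000, seed = 43)
  harm <- harmonizeAlleles(ss, G)
  list(G = G, arch = arch, phen = phen, ss = ss, harm = harm)
})

# Random small GenotypeMatrix with independent variants (no LD model),
# handy for oracle fixtures.
randomPanel <- function(n_var, n_samp, seed, rho = 0.3) {
  blocks <- lapply(seq_len(ceiling(n_var / 10)), function(b)
    ldBlockSpec(min(10L, n_var - (b - 1L) * 10L), rho,
                freq_range = c(0.1, 0.5)))
  simulateLDGenotypes(blocks, n_samp, seed = seed)
}

# Hand-built GenotypeMatrix from an explicit dosage matrix.
manualG <- function(dosage, pos = NULL, chrom = "1", a1 = NULL, a2 = NULL) {
  m <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(a1)) a1 <- rep(c("A", "C"), length.out = m)
  if (is.null(a2)) a2 <- rep(c("G", "T"), length.out = m)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos, width = 1),
    id = paste0("v", seq_len(m)), a1 = a1, a2 = a2)
  GenotypeMatrix(dosage, gr, paste0("s", seq_len(ncol(dosage))))
}

# ExtremeGroups built directly from a score vector.
groupsFromScores <- function(scores, q = 0.25) {
  prs <- new("PRSResult", sample_id = sprintf("s%05d", seq_along(scores)),
             raw = scores, rescaled = rep(NA_real_, length(scores)),
             n_variants_used = 1L, variant_ids_used = "x")
  assignExtremes(prs, q)
}
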