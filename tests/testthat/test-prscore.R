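# Clumping against the brute-force oracle, region arithmetic, score algebra,
# and tail assignment.

ssFromPanel <- function(G, p, beta = NULL) {
  gr <- variantInfo(G)
  mc <- S4Vectors::mcols(gr)
  if (is.null(beta)) beta <- rep(0.1, length(p))
  SummaryStats(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr), id = mc$id,
    effect_allele = mc$a1, other_allele = mc$a2,
    beta = beta, se = 0.1, p = p, freq = 0.3, n = 1000))
}

test_that("ldR2 handles identity, flips, independence and monomorphs", {
  G <- simulateLDGenotypes(
    ldBlockSpec(2, 0, freq_range = c(0.3, 0.3)), 10000, seed = 31)
  D <- rbind(dosages(G), dosages(G)[1, ], 2 - dosages(G)[1, ],
             rep(1, 10000))
  Gx <- manualG(D)
  expect_equal(ldR2(Gx, 1, 3), 1.0)
  expect_equal(ldR2(Gx, 1, 4), 1.0)  # allele-flipped duplicate
  expect_lt(ldR2(Gx, 1, 2), 0.01)    # independent, n = 10k
  expect_true(is.na(ldR2(Gx, 1, 5))) # monomorphic
})

test_that("three-SNP clump keeps the independent pair", {
  # SNP2 in tight LD with SNP1; SNP3 independent; all within the window
  set.seed(101)
  d1 <- rbinom(2000, 2, 0.4)
  d2 <- d1; sw <- sample(2000, 60); d2[sw] <- rbinom(60, 2, 0.4)
  d3 <- rbinom(2000, 2, 0.4)
  G <- manualG(rbind(d1, d2, d3), pos = c(1000L, 2000L, 3000L))
  expect_gt(ldR2(G, 1, 2), 0.8)
  expect_lt(ldR2(G, 1, 3), 0.05)
  ss <- ssFromPanel(G, c(1e-10, 1e-8, 1e-4))
  kept <- clumpVariants(ss, G, clumpParams(p_threshold = 0.05,
                                           clump_kb = 250, clump_r2 = 0.1))
  expect_equal(as.integer(kept), c(1L, 3L))
  # identical variants: only the smaller-p copy survives
  G2 <- manualG(rbind(d1, d1), pos = c(1000L, 2000L))
  ss2 <- ssFromPanel(G2, c(1e-4, 1e-8))
  expect_equal(as.integer(clumpVariants(ss2, G2, clumpParams())), 2L)
})

test_that("mutually independent variants all survive thresholding", {
  G <- randomPanel(40, 3000, seed = 33, rho = 0)
  p <- seq(0.001, 0.4, length.out = 40)
  kept <- clumpVariants(ssFromPanel(G, p), G,
                        clumpParams(p_threshold = 0.05, clump_r2 = 0.9))
  expect_equal(as.integer(kept), which(p < 0.05))
  expect_error(clumpVariants(ssFromPanel(G, rep(0.9, 40)), G,
                             clumpParams(p_threshold = 0.05, clump_p = 0.5)),
               "no variants pass")
})

test_that("clump matches the brute-force greedy oracle on random fixtures", {
  for (s in 1:30) {
    G <- randomPanel(30, 150, seed = 700 + s, rho = 0.6)
    set.seed(s)
    p <- runif(30)^3
    params <- clumpParams(p_threshold = 0.5, clump_kb = 5,
                          clump_r2 = 0.2, clump_p = 0.9)
    got <- as.integer(clumpVariants(ssFromPanel(G, p), G, params))
    gr <- variantInfo(G)
    want <- oracle_clump(p, as.character(GenomicRanges::seqnames(gr)),
                         GenomicRanges::start(gr), full_r2(G),
                         params$p_threshold, params$clump_r2,
                         params$clump_kb, params$clump_p)
    expect_identical(got, want)
    # retained-set validity: no pair violates the window/r2 predicate
    r2 <- full_r2(G)
    pos <- GenomicRanges::start(gr)
    for (a in got) for (b in got) if (a < b)
      expect_false(abs(pos[a] - pos[b]) <= 5000 &&
                   !is.na(r2[a, b]) && r2[a, b] >= 0.2)
  }
})

test_that("excludeRegion is inclusive at both ends and supports anchors", {
  ss <- SummaryStats(data.frame(
    chrom = "19", pos = c(45236728, 45236729, 45618959, 45618960,
                          44411940, 44411941, 45411941),
    id = paste0("v", 1:7), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.1, p = c(rep(0.5, 6), 1e-300), freq = 0.3,
    n = 1000))
  out <- excludeRegion(ss, "19", 45236729, 45618959)
  expect_setequal(statsTable(out)$id, c("v1", "v4", "v5", "v6"))
  expect_equal(attr(out, "n_removed"), 3)
  # region covering nothing is the identity
  out2 <- excludeRegion(ss, "19", 1, 2)
  expect_equal(length(out2), length(ss))
  # anchor: lowest-p variant sits at 45,411,941; +/- 1 Mb removes
  # 44,411,941 but keeps 44,411,940
  out3 <- excludeRegion(ss, "19", 45000000, 46000000, anchor = TRUE)
  kept <- statsTable(out3)$pos
  expect_true(44411940 %in% kept)
  expect_false(44411941 %in% kept)
  expect_error(excludeRegion(ss, "19", 1, 2, anchor = TRUE), "no variants")
})

test_that("single-variant scores and rescaling are exact", {
  G <- manualG(matrix(c(0, 1, 2), 1, 3))
  w <- data.frame(g_idx = 1L, beta = 1, sign_flip = FALSE, id = "v1")
  prs <- scorePRS(G, w)
  expect_equal(unname(rawScores(prs)), c(0, 1, 2))
  expect_equal(unname(rescaledScores(prs)), c(0, 0.5, 1))
})

test_that("score is linear in weights and invariant to allele orientation", {
  st <- smallStudy()
  w <- prsWeights(st$harm, st$ss)
  wA <- w[1:100, ]; wB <- w[101:200, ]
  both <- scorePRS(st$G, rbind(wA, wB), rescale = FALSE)
  expect_equal(rawScores(both),
               rawScores(scorePRS(st$G, wA, rescale = FALSE)) +
               rawScores(scorePRS(st$G, wB, rescale = FALSE)),
               tolerance = 1e-12)
  # flipping every allele label and beta sign shifts raw by -2*sum(beta)
  wf <- w[1:100, ]
  wf$beta <- -wf$beta
  wf$sign_flip <- !wf$sign_flip
  a <- scorePRS(st$G, w[1:100, ])
  b <- scorePRS(st$G, wf)
  expect_equal(unname(rawScores(b) - rawScores(a)),
               rep(-2 * sum(w$beta[1:100]), nSamples(st$G)),
               tolerance = 1e-9)
  expect_equal(rescaledScores(a), rescaledScores(b), tolerance = 1e-9)
  expect_identical(order(rawScores(a)), order(rawScores(b)))
})

test_that("missing dosages are mean-imputed with the cohort frequency", {
  D <- matrix(c(0, 1, 2, 1, NA, 1), nrow = 2, byrow = TRUE)
  G <- manualG(D)
  w <- data.frame(g_idx = 1:2, beta = c(1, 1), sign_flip = FALSE)
  prs <- scorePRS(G, w, rescale = FALSE)
  expect_equal(unname(rawScores(prs))[2], 1 + 1)  # NA -> mean dosage 1
})

test_that("tail assignment sizes, ordering and tie handling are exact", {
  g <- groupsFromScores(rnorm(100), q = 0.05)
  expect_equal(tailCount(g), 5L)
  sc <- setNames(rnorm(1000), sprintf("s%05d", 1:1000))
  g2 <- groupsFromScores(unname(sc), q = 0.3)
  expect_lte(max(sc[lowSamples(g2)]), min(sc[highSamples(g2)]))
  expect_equal(length(lowSamples(g2)), length(highSamples(g2)))
  # all-equal scores: sizes still k, stable id order, warning emitted
  expect_warning(g3 <- groupsFromScores(rep(1, 10), q = 0.2), "tie")
  expect_equal(lowSamples(g3), sprintf("s%05d", 1:2))
  expect_equal(highSamples(g3), sprintf("s%05d", 9:10))
  expect_error(assignExtremes(
    new("PRSResult", sample_id = c("a", "b"), raw = c(1, 2),
        rescaled = rep(NA_real_, 2), n_variants_used = 1L,
        variant_ids_used = "v"), 0.9))
})

test_that("high tail carries higher liability, growing with h2", {
  gaps <- vapply(c(0.1, 0.3, 0.5), function(h2) {
    G <- simulateLDGenotypes(
      lapply(1:10, function(b) ldBlockSpec(15, 0.5)), 1200, seed = 77)
    arch <- architectureSpec(20, h2, 0.1, seed = 77)
    phen <- simulateLiabilityPhenotype(G, arch)
    ss <- simulateBaseSumstats(G, arch, 1e5, seed = 78)
    harm <- harmonizeAlleles(ss, G)
    idx <- clumpVariants(ss, G, clumpParams())
    prs <- scorePRS(G, prsWeights(harm, ss, idx))
    grp <- assignExtremes(prs, 0.1)
    liab <- setNames(phen$phenotype$liability, phen$phenotype$sample_id)
    mean(liab[highSamples(grp)]) - mean(liab[lowSamples(grp)])
  }, numeric(1))
  expect_true(all(gaps > 0))
  expect_true(all(diff(gaps) > 0))
})
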