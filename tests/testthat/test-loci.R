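# Locus hierarchy vs brute-force oracle, envelope merging, nearest-gene tie
# rules, and base-study classification.

gwasFromP <- function(G, p, status = NULL) {
  gr <- variantInfo(G)
  m <- length(p)
  if (is.null(status)) status <- rep("ok", m)
  rec <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr),
    id = S4Vectors::mcols(gr)$id,
    beta = 0.1, se = 0.05, or_ = exp(0.1),
    ci_low = 1, ci_high = 1.2, p = p,
    maf_all = 0.3, maf_low = 0.3, maf_high = 0.3,
    n_used = nSamples(G), status = status)
  rec$p[status != "ok"] <- NA
  new("GwasRun", records = rec, lambda_gc = 1,
      n_high = 10L, n_low = 10L, covariate_names = character(0))
}

test_that("independent-significant clumping respects the r2 0.6 rule", {
  set.seed(61)
  d1 <- rbinom(3000, 2, 0.4)
  mk <- function(src, nflip) {
    out <- src; i <- sample(3000, nflip); out[i] <- rbinom(nflip, 2, 0.4)
    out
  }
  d2 <- mk(d1, 500)   # r2 ~ 0.7 with d1
  d3 <- mk(d1, 1700)  # r2 ~ 0.4-0.5 with d1
  G <- manualG(rbind(d1, d2, d3), pos = c(1e5L, 2e5L, 3e5L))
  r12 <- ldR2(G, 1, 2); r13 <- ldR2(G, 1, 3)
  expect_gt(r12, 0.6); expect_lt(r13, 0.6)
  gw <- gwasFromP(G, c(1e-10, 1e-9, 1e-9))
  ind <- independentSignificant(gw, G)
  expect_setequal(ind$id, c("v1", "v3"))  # v2 clumped by v1, v3 survives
})

test_that("locus envelopes merge at <= 250 kb and split above", {
  # independent variants (r2 ~ 0), each its own lead; envelope = own position
  G <- randomPanel(3, 2000, seed = 62, rho = 0)
  gr <- variantInfo(G)
  # rebuild with controlled positions: 1 Mb, +200 kb, +251 kb
  G2 <- GenotypeMatrix(dosages(G), GenomicRanges::GRanges(
    "1", IRanges::IRanges(c(1000000L, 1200000L, 1451001L), width = 1),
    id = paste0("v", 1:3), a1 = "A", a2 = "G"), sampleIDs(G))
  gw <- gwasFromP(G2, c(1e-9, 1e-9, 1e-9))
  params <- locusParams(cand_p = 1e-20)  # no candidate envelope growth
  ind <- independentSignificant(gw, G2, params)
  ll <- leadAndLoci(ind, gw, G2, params)
  expect_equal(nrow(ll$loci), 2)
  expect_equal(ll$loci$n_ind_sig, c(2, 1))  # v1+v2 merged, v3 separate
  expect_equal(ll$members$locus_id, c(1L, 1L, 2L))
})

test_that("locus construction matches the brute-force oracle on fixtures", {
  params <- locusParams(sig_p = 1e-5, cand_p = 0.05)
  for (s in 1:25) {
    G <- randomPanel(30, 200, seed = 900 + s, rho = 0.7)
    set.seed(s)
    p <- runif(30)
    p[sample(30, 6)] <- 10^-runif(6, 6, 12)
    gw <- gwasFromP(G, p)
    ind <- independentSignificant(gw, G, params)
    ll <- leadAndLoci(ind, gw, G, params)
    gr <- variantInfo(G)
    want <- oracle_loci(p, as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr), full_r2(G), params)
    expect_equal(nrow(ll$loci), want$n_loci)
    # same partition of independent significant SNPs into loci
    got_m <- ll$members$locus_id[order(ll$members$pos)]
    vidx <- match(ll$members$id[order(ll$members$pos)],
                  S4Vectors::mcols(gr)$id)
    want_m <- want$membership[as.character(vidx)]
    expect_identical(as.integer(as.factor(got_m)),
                     as.integer(as.factor(want_m)))
    # hierarchy invariants
    expect_gte(nrow(ind), sum(ll$loci$n_lead))
    expect_gte(sum(ll$loci$n_lead), nrow(ll$loci))
    expect_true(all(table(ll$members$id) == 1))
  }
})

test_that("nearest gene distances and tie rules are exact", {
  genes <- GenomicRanges::GRanges(
    "1", IRanges::IRanges(c(1000, 20000, 40000), width = 5000),
    gene_id = c("gB", "gA", "gC"))
  expect_equal(nearestGene("1", 3000, genes),
               list(gene = "gB", distance = 0))
  # equidistant between gene ends at 24999 and start 40000: pos 32500 is
  # 7501 from gA end, 7500 from gC start -> gC; shift to exact tie
  expect_equal(nearestGene("1", 32499, genes)$gene, "gA")
  expect_equal(nearestGene("2", 1, genes)$gene, "none")
  # exhaustive-scan oracle over random fixtures
  set.seed(63)
  for (i in 1:200) {
    st <- sort(sample(1:100000, 5) * 10L)
    gn <- GenomicRanges::GRanges(
      "1", IRanges::IRanges(st, width = sample(1000:5000, 5)),
      gene_id = paste0("g", sample(5)))
    pos <- sample(1:1100000, 1)
    expect_equal(nearestGene("1", pos, gn)$gene,
                 oracle_nearest("1", pos, rep("1", 5),
                                GenomicRanges::start(gn),
                                GenomicRanges::end(gn), gn$gene_id))
  }
})

test_that("base comparison classifies replicated, novel and not-tested", {
  G <- randomPanel(8, 500, seed = 64, rho = 0)
  pos <- c(1e6, 2e6, 3e6, 4e6, 10e6, 11e6, 20e6, 30e6)
  G2 <- GenotypeMatrix(dosages(G), GenomicRanges::GRanges(
    "1", IRanges::IRanges(as.integer(pos), width = 1),
    id = paste0("v", 1:8), a1 = "A", a2 = "G"), sampleIDs(G))
  status <- rep("ok", 8); status[7] <- "filtered_maf"
  p <- c(1e-9, 0.5, 0.5, 0.5, 1e-16, 0.5, NA, 0.5)
  gw <- gwasFromP(G2, p, status)
  params <- locusParams(cand_p = 1e-20)
  ll <- leadAndLoci(independentSignificant(gw, G2, params), gw, G2, params)
  reported <- data.frame(chrom = "1",
                         pos = c(1499000, 20e6, 30e6),
                         id = c("b1", "b2", "b3"))
  cmp <- compareWithBase(gw, reported, ll$loci)
  # b1: hit 499 kb away at 1e-9 -> replicated (boundary inclusive)
  expect_equal(cmp$reported$status[1], "replicated")
  expect_equal(cmp$reported$best_id[1], "v1")
  # b2: its variant was dropped for MAF -> not_tested(maf)
  expect_equal(cmp$reported$status[2], "not_tested(maf)")
  # b3: testable but null -> not_replicated
  expect_equal(cmp$reported$status[3], "not_replicated")
  # locus at 10 Mb has no reported variant within 500 kb -> novel, and its
  # top p <= 1e-15 puts it on the strict list
  cls <- setNames(cmp$loci$class, cmp$loci$top_snp)
  expect_equal(unname(cls["v1"]), "replicated")
  expect_equal(unname(cls["v5"]), "novel")
  expect_equal(cmp$novel_strict$top_snp, "v5")
  expect_error(compareWithBase(gw, data.frame(chrom = "7", pos = 1,
                                              id = "x")),
               "build mismatch")
})
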