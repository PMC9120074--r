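# LD score construction vs the analytic threshold-model oracle, exact and
# stochastic heritability recovery, genetic correlation identities.

# A panel with heterogeneous LD: the regression on LD scores is only
# identified when l_j actually varies, so block rho cycles over a range.
ldscPanel <- function(n_blocks, n_samples, seed) {
  rhos <- rep(c(0, 0.25, 0.5, 0.75, 0.9), length.out = n_blocks)
  blocks <- lapply(seq_len(n_blocks), function(b)
    ldBlockSpec(25, rhos[b]))
  simulateLDGenotypes(blocks, n_samples, seed = seed)
}

test_that("LD scores are exact for isolated and duplicated variants", {
  set.seed(81)
  d <- rbinom(4000, 2, 0.3)
  e <- rbinom(4000, 2, 0.4)
  # v1/v2 duplicated within the window; v3 isolated far away
  G <- manualG(rbind(d, d, e), pos = c(1000L, 2000L, 90000000L))
  ld <- ldScores(G, window_kb = 1000)
  expect_equal(ld$ell[1:2], c(2, 2), tolerance = 1e-12)
  expect_equal(ld$ell[3], 1, tolerance = 1e-12)
})

test_that("LD scores match the closed-form AR(1) threshold-model sum", {
  G <- simulateLDGenotypes(
    ldBlockSpec(20, 0.9, freq_range = c(0.3, 0.3)), 6000, seed = 82)
  ld <- ldScores(G, window_kb = 1000)
  truth <- sapply(1:20, function(j)
    sum(sapply(1:20, function(k)
      if (k == j) 1 else oracle_threshold_r2(0.3, 0.3, 0.9^abs(j - k)))))
  expect_equal(ld$ell, truth, tolerance = 0.08)
})

test_that("noise-free chi-squares recover h2 and intercept exactly", {
  G <- randomPanel(300, 800, seed = 83, rho = 0.5)
  ld <- ldScores(G, window_kb = 50)
  M <- nrow(ld); N <- 10000
  chi2 <- 1 + N * 0.4 * ld$ell / M
  fit <- h2Regression(chi2, N, ld)
  expect_equal(fit$h2, 0.4, tolerance = 1e-8)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-8)
})

test_that("h2 scales as c^2 when all z are scaled by c", {
  G <- randomPanel(200, 500, seed = 84)
  ld <- ldScores(G, window_kb = 50)
  set.seed(84)
  z <- rnorm(200, 0, 1.2)
  f1 <- suppressWarnings(h2Regression(z^2, 5000, ld))
  f2 <- suppressWarnings(h2Regression((2 * z)^2, 5000, ld))
  expect_equal(f2$h2, 4 * f1$h2, tolerance = 1e-10)
})

test_that("null z-scores give h2 near 0 and intercept near 1", {
  G <- randomPanel(2000, 600, seed = 85, rho = 0.6)
  ld <- ldScores(G, window_kb = 100)
  set.seed(85)
  z <- rnorm(2000)
  fit <- suppressWarnings(h2Regression(z^2, 20000, ld))
  expect_lt(abs(fit$h2 - 0), 3 * fit$se_h2 + 1e-6)
  expect_lt(abs(fit$intercept - 1), 3 * fit$se_intercept + 0.05)
})

test_that("simulated summary statistics recover the generating h2", {
  G <- ldscPanel(40, 1000, seed = 86)
  ld <- ldScores(G, window_kb = 100)
  N <- 20000
  ests <- sapply(1:4, function(r) {
    arch <- architectureSpec(100, 0.3, seed = 860 + r)
    ss <- simulateBaseSumstats(G, arch, N, seed = 1000 + r)
    fit <- h2Regression(chiSq(ss), N, ld)
    c(fit$h2, fit$se_h2)
  })
  expect_lt(abs(mean(ests[1, ]) - 0.3), 3 * mean(ests[2, ]))
})

test_that("rg of a trait with itself is exactly 1", {
  G <- ldscPanel(20, 500, seed = 87)
  ld <- ldScores(G, window_kb = 100)
  M <- nrow(ld); N <- 5000
  set.seed(87)
  z <- rnorm(M, 0, sqrt(1 + N * 0.5 * ld$ell / M))
  rg <- rgRegression(z, z, N, N, ld)
  expect_equal(rg$rg, 1, tolerance = 1e-6)
  # symmetry in trait order
  set.seed(88)
  z2 <- rnorm(M, 0, sqrt(1 + N * 0.5 * ld$ell / M))
  a <- rgRegression(z, z2, N, 6000, ld)
  b <- rgRegression(z2, z, 6000, N, ld)
  expect_equal(a$rg, b$rg, tolerance = 1e-10)
})

test_that("independent traits give rg near 0, shared effects near 0.5", {
  G <- ldscPanel(30, 1200, seed = 89)
  ld <- ldScores(G, window_kb = 100)
  M <- nrow(ld); N <- 30000; h2 <- 0.4
  D <- t(scale(t(dosages(G))))  # standardized variants x samples
  set.seed(90)
  makeZ <- function(beta) {
    # marginal std effects via within-block panel LD, plus unit noise
    marg <- sapply(seq_len(M), function(j) {
      blk <- S4Vectors::mcols(variantInfo(G))$block
      inb <- which(blk == blk[j] & beta != 0)
      if (!length(inb)) return(0)
      r <- suppressWarnings(cor(D[j, ], t(D[inb, , drop = FALSE])))
      sum(r * beta[inb])
    })
    sqrt(N) * marg + rnorm(M)
  }
  cidx <- sample(M, 150)
  b1 <- rep(0, M); b1[cidx] <- rnorm(150) * sqrt(h2 / 150)
  b2 <- rep(0, M)
  b2[cidx[1:75]] <- b1[cidx[1:75]]                # shared half
  b2[cidx[76:150]] <- rnorm(75) * sqrt(h2 / 150)  # independent half
  b3 <- rep(0, M); b3[sample(M, 150)] <- rnorm(150) * sqrt(h2 / 150)
  z1 <- makeZ(b1); z2 <- makeZ(b2); z3 <- makeZ(b3)
  shared <- rgRegression(z1, z2, N, N, ld)
  indep <- rgRegression(z1, z3, N, N, ld)
  expect_lt(abs(shared$rg - 0.5), 3 * shared$se_rg + 0.05)
  expect_lt(abs(indep$rg - 0), 3 * indep$se_rg + 0.05)
})

test_that("excluding a dominant locus lowers the h2 estimate", {
  G <- simulateLDGenotypes(
    lapply(1:20, function(b) ldBlockSpec(20, 0.8)), 1000, seed = 91)
  ld <- ldScores(G, window_kb = 100)
  # one large-effect variant at a known position
  arch <- architectureSpec(1, 0.5, effect_dist_sd = 2, seed = 91)
  ss <- simulateBaseSumstats(G, arch, 20000, seed = 92)
  tbl <- statsTable(ss)
  cpos <- tbl$pos[which.max(abs(tbl$beta / tbl$se))]
  res <- suppressWarnings(regionExcludeRerun(
    ss, ld, 20000, "1", cpos - 50000, cpos + 50000))
  expect_gt(res$n_excluded, 0)
  expect_lt(res$without_region$h2, res$with_region$h2)
  # region covering nothing: identical estimates
  res0 <- suppressWarnings(regionExcludeRerun(
    ss, ld, 20000, "1", 2e9, 2e9 + 1))
  expect_equal(res0$with_region$h2, res0$without_region$h2)
  expect_equal(res0$n_excluded, 0)
})
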