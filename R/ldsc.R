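## LD score regression: score construction with the small-sample r2
## adjustment, heritability regression with a free intercept, cross-trait
## genetic correlation, and block-jackknife standard errors.

#' Per-variant LD scores from a genotype panel
#'
#' `l_j` is the sum over neighbours within `window_kb` (self included) of
#' the adjusted squared correlation `r2_adj = r2 - (1 - r2)/(n - 2)`, which
#' is unbiased for the population r2 under the null. The self term
#' contributes exactly 1. Monomorphic variants get `NA` with a warning.
#'
#' @param panel a [GenotypeMatrix-class] with at least 10 samples.
#' @param window_kb window half-width in kb (default 1 Mb; a physical
#'   window is used because synthetic data carry no genetic map).
#' @return data.frame of class `LDScoreTable`: chrom, pos, id, ell, plus
#'   `window_kb` and panel size `n` as attributes.
#' @export
ldScores <- function(panel, window_kb = 1000) {
    n <- nSamples(panel)
    stopifnot(n >= 10)
    D <- dosages(panel)
    gr <- variantInfo(panel)
    chrom <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    sds <- apply(D, 1, stats::sd, na.rm = TRUE)
    mono <- sds == 0 | is.na(sds)
    if (any(mono))
        warning(sum(mono), " monomorphic variants get NA LD scores")
    w <- window_kb * 1000
    ell <- rep(NA_real_, nrow(D))
    Dt <- t(D)
    for (ch in unique(chrom)) {
        jj <- which(chrom == ch & !mono)
        if (!length(jj)) next
        chunk <- 256L
        for (s in seq(1, length(jj), by = chunk)) {
            blk <- jj[s:min(s + chunk - 1L, length(jj))]
            lo <- min(pos[blk]) - w; hi <- max(pos[blk]) + w
            nb <- jj[pos[jj] >= lo & pos[jj] <= hi]
            r <- suppressWarnings(stats::cor(
                Dt[, blk, drop = FALSE], Dt[, nb, drop = FALSE],
                use = "pairwise.complete.obs"))
            r2 <- r^2
            r2adj <- r2 - (1 - r2) / (n - 2)
            inwin <- abs(outer(pos[blk], pos[nb], "-")) <= w
            r2adj[!inwin | is.na(r2adj)] <- 0
            ell[blk] <- rowSums(r2adj)
        }
    }
    out <- data.frame(chrom = chrom, pos = pos,
                      id = S4Vectors::mcols(gr)$id, ell = ell)
    attr(out, "window_kb") <- window_kb
    attr(out, "n_panel") <- n
    class(out) <- c("LDScoreTable", class(out))
    out
}

## Shared weighted-regression core: y ~ intercept + ell with the two-pass
## LDSC weight update, plus delete-one-block jackknife. `scale_fac` maps the
## slope to the estimand (h2 = slope*M/N; rho_g = slope*M/sqrt(N1*N2)).
.ldscFit <- function(y, ell, scale_fac, n_blocks) {
    ok <- !is.na(y) & !is.na(ell)
    y <- y[ok]; ell <- ell[ok]
    M <- length(y)
    if (M < 10) stop("too few variants for LD score regression")
    if (M < 2000) n_blocks <- min(n_blocks, 20L)
    if (n_blocks > M) {
        warning("fewer variants than jackknife blocks; reducing blocks")
        n_blocks <- max(2L, M %/% 2L)
    }
    X <- cbind(1, ell)
    fit0 <- stats::lm.fit(X, y)
    slope0 <- fit0$coefficients[2]
    ## heteroskedasticity weights at the first-pass estimate
    wts <- 1 / (pmax(ell, 1) * (1 + pmax(slope0, 0) * ell)^2)
    wfit <- function(idx) {
        Xw <- X[idx, , drop = FALSE] * sqrt(wts[idx])
        yw <- y[idx] * sqrt(wts[idx])
        stats::lm.fit(Xw, yw)$coefficients
    }
    co <- wfit(seq_len(M))
    blocks <- split(seq_len(M),
                    cut(seq_len(M), n_blocks, labels = FALSE))
    jk <- vapply(blocks, function(b) wfit(setdiff(seq_len(M), b)),
                 numeric(2))
    B <- length(blocks)
    jk_se <- sqrt((B - 1) / B * rowSums((jk - rowMeans(jk))^2))
    list(slope = unname(co[2]), intercept = unname(co[1]),
         est = unname(co[2]) * scale_fac,
         se_est = unname(jk_se[2]) * scale_fac,
         se_intercept = unname(jk_se[1]),
         jk_slopes = unname(jk[2, ]), jk_intercepts = unname(jk[1, ]),
         M = M, n_blocks = B, weights_ok = ok)
}

#' LD score regression for heritability
#'
#' Fits `E[chi2_j] = 1 + N*a + (N*h2/M) * l_j` by two-pass weighted least
#' squares with a free intercept: an unweighted first pass sets the
#' heteroskedasticity weights `1/(l_j * (1 + slope*l_j)^2)` for the second.
#' Standard errors come from a delete-one-block jackknife over contiguous
#' variant blocks (200 by default, at most 20 when fewer than 2000
#' variants). Negative estimates are reported as-is and flagged.
#'
#' @param chi2 per-variant association chi-square statistics.
#' @param N GWAS sample size.
#' @param ld an `LDScoreTable` from [ldScores()] (aligned to `chi2`).
#' @param n_blocks jackknife blocks.
#' @return list of class `H2Estimate`: h2, intercept, se_h2, se_intercept,
#'   M, mean_chi2, n_blocks, flagged.
#' @export
h2Regression <- function(chi2, N, ld, n_blocks = 200L) {
    stopifnot(N > 1, length(chi2) == nrow(ld))
    fit <- .ldscFit(chi2, ld$ell, scale_fac = nrow(ld) / N, n_blocks)
    out <- list(h2 = fit$est, intercept = fit$intercept,
                se_h2 = fit$se_est, se_intercept = fit$se_intercept,
                M = fit$M, mean_chi2 = mean(chi2, na.rm = TRUE),
                n_blocks = fit$n_blocks, flagged = fit$est < 0)
    if (out$flagged)
        warning("negative h2 estimate (", format(out$h2, digits = 3),
                "); reported unclamped")
    class(out) <- "H2Estimate"
    out
}

#' @export
print.H2Estimate <- function(x, ...) {
    cat("LDSC h2 =", format(x$h2, digits = 4),
        "(jackknife se", format(x$se_h2, digits = 3), ")\n")
    cat("  intercept =", format(x$intercept, digits = 4),
        "(se", format(x$se_intercept, digits = 3), "), M =", x$M,
        ", mean chi2 =", format(x$mean_chi2, digits = 4), "\n")
    invisible(x)
}

#' Cross-trait LD score regression (genetic correlation)
#'
#' Regresses the z-score product on LD scores
#' (`E[z1 z2] = sqrt(N1 N2) * rho_g * l_j / M + intercept`, the free
#' intercept absorbing sample overlap), estimates each trait's h2 the same
#' way, and reports `rg = rho_g / sqrt(h2_1 * h2_2)`. The jackknife
#' recomputes the full ratio per deleted block. Undefined (flagged) when
#' either component h2 is non-positive.
#'
#' @param z1,z2 aligned per-variant z-scores, oriented to a shared effect
#'   allele.
#' @param N1,N2 component sample sizes.
#' @param ld an `LDScoreTable` aligned to the z vectors.
#' @param n_blocks jackknife blocks.
#' @return list of class `RgEstimate`: rg, rho_g, se_rg, h2_1, h2_2,
#'   intercept, M, flagged.
#' @export
rgRegression <- function(z1, z2, N1, N2, ld, n_blocks = 200L) {
    stopifnot(length(z1) == length(z2), length(z1) == nrow(ld))
    M <- nrow(ld)
    f1 <- .ldscFit(z1^2, ld$ell, scale_fac = M / N1, n_blocks)
    f2 <- .ldscFit(z2^2, ld$ell, scale_fac = M / N2, n_blocks)
    fx <- .ldscFit(z1 * z2, ld$ell, scale_fac = M / sqrt(N1 * N2),
                   n_blocks)
    h2_1 <- f1$est; h2_2 <- f2$est; rho_g <- fx$est
    flagged <- h2_1 <= 0 || h2_2 <= 0
    rg <- if (flagged) NA_real_ else rho_g / sqrt(h2_1 * h2_2)
    ## per-block ratio jackknife (blocks are identical across the three fits)
    se_rg <- NA_real_
    if (!flagged) {
        B <- fx$n_blocks
        sc1 <- M / N1; sc2 <- M / N2; scx <- M / sqrt(N1 * N2)
        rg_jk <- vapply(seq_len(B), function(b) {
            h1 <- f1$jk_slopes[b] * sc1
            h2 <- f2$jk_slopes[b] * sc2
            rg_b <- fx$jk_slopes[b] * scx / sqrt(max(h1, 1e-12) *
                                                 max(h2, 1e-12))
            rg_b
        }, numeric(1))
        se_rg <- sqrt((B - 1) / B * sum((rg_jk - mean(rg_jk))^2))
    }
    out <- list(rg = rg, rho_g = rho_g, se_rg = se_rg,
                h2_1 = h2_1, h2_2 = h2_2, intercept = fx$intercept,
                M = M, flagged = flagged)
    class(out) <- "RgEstimate"
    out
}

#' @export
print.RgEstimate <- function(x, ...) {
    cat("LDSC rg =", format(x$rg, digits = 4),
        "(jackknife se", format(x$se_rg, digits = 3), ")\n")
    cat("  rho_g =", format(x$rho_g, digits = 4),
        ", component h2:", format(x$h2_1, digits = 3), "/",
        format(x$h2_2, digits = 3),
        if (x$flagged) " [flagged: non-positive h2]" else "", "\n")
    invisible(x)
}

#' Heritability with and without an excluded region
#'
#' Re-runs [h2Regression()] on the full variant set and on the set with the
#' given region removed (both ends inclusive, the dominant-locus sensitivity
#' analysis), and reports both estimates with the excluded count.
#'
#' @param ss a [SummaryStats-class] (chi-squares from `chiSq(ss)`).
#' @param ld an `LDScoreTable` aligned to `ss`.
#' @param N GWAS sample size.
#' @param chrom,start,end region to exclude (1-based inclusive).
#' @param n_blocks jackknife blocks.
#' @return list: `with_region` and `without_region` (`H2Estimate`s) plus
#'   `n_excluded`.
#' @export
regionExcludeRerun <- function(ss, ld, N, chrom, start, end,
                               n_blocks = 200L) {
    tb <- statsTable(ss)
    stopifnot(nrow(tb) == nrow(ld))
    drop <- tb$chrom == chrom & tb$pos >= start & tb$pos <= end
    all_fit <- h2Regression(chiSq(ss), N, ld, n_blocks)
    sub_fit <- h2Regression(chiSq(ss)[!drop], N,
                            ld[!drop, , drop = FALSE], n_blocks)
    list(with_region = all_fit, without_region = sub_fit,
         n_excluded = sum(drop))
}
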