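## Variant QC, covariate-adjusted logistic association between the PRS
## extremes (high tail coded as case), and the genomic inflation factor.

#' Hardy-Weinberg equilibrium exact test
#'
#' The standard conditional exact test: given the observed allele counts,
#' the p-value is the total probability of heterozygote counts no more
#' probable than the observed one. Computed by the usual stable recurrence
#' over heterozygote counts (no factorials). Invariant under swapping the
#' homozygote labels; monomorphic input gives p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total > 0).
#' @return p-value in (0, 1\].
#' @examples
#' hweExact(0, 0, 100)  # monomorphic: 1
#' @export
hweExact <- function(n_AA, n_Aa, n_aa) {
    if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
    n <- n_AA + n_Aa + n_aa
    if (n == 0) stop("total genotype count is zero")
    nA <- 2 * n_AA + n_Aa
    rare <- min(nA, 2 * n - nA)
    if (rare == 0) return(1)
    ## enumerate every heterozygote count compatible with the allele counts
    ## (parity fixed by the rare-allele count); log conditional probability
    ## from the multinomial / hypergeometric closed form, then normalize
    hets <- seq(rare %% 2L, rare, by = 2L)
    n_rr <- (rare - hets) / 2          # rare homozygotes
    n_cc <- n - n_rr - hets            # common homozygotes
    logp <- lfactorial(n) - lfactorial(n_rr) - lfactorial(hets) -
        lfactorial(n_cc) + hets * log(2) +
        lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
    prob <- exp(logp - max(logp))
    prob <- prob / sum(prob)
    obs <- prob[match(n_Aa, hets)]
    min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Variant QC on a sample subset
#'
#' A variant is kept iff its minor allele frequency is at least `maf_min`,
#' its Hardy-Weinberg exact p at least `hwe_p_min`, and its missing-call
#' fraction at most `miss_max`, all computed on the given samples. Dosages
#' are rounded to genotype calls for the HWE counts. Reason codes (first
#' failing filter, in the order maf, hwe, missingness) are recorded for
#' every dropped variant.
#'
#' @param G a [GenotypeMatrix-class].
#' @param samples sample ids (default: all).
#' @param params a [qcParams()].
#' @return data.frame: idx, id, maf, hwe_p, miss_frac, keep, reason.
#' @export
qcFilter <- function(G, samples = NULL, params = qcParams()) {
    stopifnot(inherits(params, "QCParams"))
    D <- dosages(G)
    if (!is.null(samples)) {
        stopifnot(length(samples) > 0, all(samples %in% colnames(D)))
        D <- D[, samples, drop = FALSE]
    }
    nn <- rowSums(!is.na(D))
    miss <- 1 - nn / ncol(D)
    f <- rowMeans(D, na.rm = TRUE) / 2
    maf <- pmin(f, 1 - f)
    maf[nn == 0] <- 0
    R <- round(D)
    nAA <- rowSums(R == 2, na.rm = TRUE)
    nAa <- rowSums(R == 1, na.rm = TRUE)
    naa <- rowSums(R == 0, na.rm = TRUE)
    hwe <- vapply(seq_len(nrow(D)), function(i)
        hweExact(nAA[i], nAa[i], naa[i]), numeric(1))
    reason <- rep(NA_character_, nrow(D))
    reason[miss > params$miss_max] <- "missingness"
    reason[hwe < params$hwe_p_min] <- "hwe"
    reason[maf < params$maf_min] <- "maf"
    keep <- is.na(reason)
    if (!any(keep)) warning("no variants pass QC")
    data.frame(idx = seq_len(nrow(D)),
               id = rownames(D),
               maf = maf, hwe_p = hwe, miss_frac = miss,
               keep = keep, reason = reason)
}

#' Single-variant logistic association
#'
#' Maximum-likelihood logistic regression of group membership on dosage plus
#' covariates (IRLS via `stats::glm.fit`, convergence at relative deviance
#' change < 1e-8, at most 100 iterations), with a two-sided Wald test on the
#' dosage coefficient. Non-convergence or a diverging coefficient
#' (|beta| > 20) is reported as `separated` with no p-value, mirroring how
#' standard GWAS tools report NA under perfect separation.
#'
#' @param dosage numeric vector.
#' @param y 0/1 group label (high tail = 1).
#' @param X optional numeric covariate matrix (no intercept column).
#' @return one-row data.frame: beta, se, or_, ci_low, ci_high, p, n_used,
#'   status (`ok`, `separated`, or `filtered_constant`).
#' @export
logisticAssoc <- function(dosage, y, X = NULL) {
    keep <- !is.na(dosage) & !is.na(y)
    if (!is.null(X)) keep <- keep & !apply(is.na(X), 1, any)
    d <- dosage[keep]; yy <- y[keep]
    if (length(unique(yy)) < 2) stop("y must contain both classes")
    rec <- data.frame(beta = NA_real_, se = NA_real_, or_ = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                      n_used = length(yy), status = "ok")
    if (stats::var(d) == 0) {
        rec$status <- "filtered_constant"
        return(rec)
    }
    x <- cbind(`(Intercept)` = 1, dosage = d,
               if (!is.null(X)) X[keep, , drop = FALSE])
    if (qr(x)$rank < ncol(x))
        stop("covariate matrix is not full rank")
    fit <- suppressWarnings(stats::glm.fit(
        x, yy, family = stats::binomial(),
        control = list(epsilon = 1e-8, maxit = 100)))
    beta <- fit$coefficients[2]
    if (!fit$converged || abs(beta) > 20) {
        rec$status <- "separated"
        return(rec)
    }
    w <- fit$weights
    cov <- tryCatch(chol2inv(chol(crossprod(x * sqrt(w)))),
                    error = function(e) NULL)
    if (is.null(cov)) {
        rec$status <- "separated"
        return(rec)
    }
    se <- sqrt(diag(cov))[2]
    rec$beta <- beta; rec$se <- se
    rec$or_ <- exp(beta)
    rec$ci_low <- exp(beta - 1.96 * se)
    rec$ci_high <- exp(beta + 1.96 * se)
    rec$p <- 2 * stats::pnorm(-abs(beta / se))
    rec
}

#' Extremes GWAS: QC + per-variant logistic association
#'
#' Applies [qcFilter()] on the union of the two extreme groups, runs
#' [logisticAssoc()] for every passing variant (high tail coded 1), records
#' per-group minor allele frequencies (folded to the overall minor allele),
#' and computes the genomic inflation factor over ok-status p-values.
#' Output rows are ordered by (chrom, pos); QC failures are retained with a
#' `filtered_<reason>` status so downstream comparisons can distinguish
#' "not significant" from "not tested".
#'
#' @param G a [GenotypeMatrix-class].
#' @param groups an [ExtremeGroups-class].
#' @param covariates optional data.frame with `sample_id` plus covariate
#'   columns (factors allowed; expanded via `model.matrix`).
#' @param qc a [qcParams()] (GWAS-stage defaults).
#' @return A [GwasRun-class].
#' @export
runGwas <- function(G, groups, covariates = NULL, qc = qcParams()) {
    lab <- groupLabels(groups)
    ids <- names(lab)[lab != "unassigned"]
    if (!length(lowSamples(groups)) || !length(highSamples(groups)))
        stop("both extreme groups must be non-empty")
    stopifnot(all(ids %in% sampleIDs(G)))
    y <- as.integer(lab[ids] == "high")
    X <- NULL; covnames <- character(0)
    if (!is.null(covariates)) {
        stopifnot("sample_id" %in% colnames(covariates),
                  all(ids %in% covariates$sample_id))
        cv <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
        cv$sample_id <- NULL
        covnames <- colnames(cv)
        X <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    }
    qcres <- qcFilter(G, samples = ids, params = qc)
    D <- dosages(G)[, ids, drop = FALSE]
    gr <- variantInfo(G)
    mc <- S4Vectors::mcols(gr)
    low <- y == 0
    recs <- vector("list", nrow(qcres))
    for (i in seq_len(nrow(qcres))) {
        if (qcres$keep[i]) {
            r <- logisticAssoc(D[i, ], y, X)
        } else {
            r <- data.frame(beta = NA_real_, se = NA_real_, or_ = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p = NA_real_, n_used = 0L,
                            status = paste0("filtered_", qcres$reason[i]))
        }
        recs[[i]] <- r
    }
    recs <- do.call(rbind, recs)
    f_all <- rowMeans(D, na.rm = TRUE) / 2
    f_low <- rowMeans(D[, low, drop = FALSE], na.rm = TRUE) / 2
    f_high <- rowMeans(D[, !low, drop = FALSE], na.rm = TRUE) / 2
    minor_is_a1 <- f_all <= 0.5
    fold <- function(f) ifelse(minor_is_a1, f, 1 - f)
    records <- cbind(
        data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   pos = GenomicRanges::start(gr), id = mc$id),
        recs,
        data.frame(maf_all = fold(f_all), maf_low = fold(f_low),
                   maf_high = fold(f_high)))
    ord <- order(records$chrom, records$pos)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
    okp <- records$p[records$status == "ok"]
    lam <- if (length(okp)) genomicLambda(okp) else NA_real_
    new("GwasRun", records = records, lambda_gc = lam,
        n_high = sum(y == 1), n_low = sum(y == 0),
        covariate_names = covnames)
}

#' Genomic inflation factor
#'
#' Lambda is the median of the chi-square(1) quantile-transformed p-values
#' divided by the chi-square(1) median (about 0.4549).
#'
#' @param p_values vector of p-values in (0, 1\].
#' @return lambda.
#' @examples
#' genomicLambda(rep(0.5, 10))  # exactly 1
#' @export
genomicLambda <- function(p_values) {
    if (!length(p_values)) stop("empty p-value vector")
    p <- p_values[!is.na(p_values)]
    if (!length(p)) stop("empty p-value vector")
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
        stats::qchisq(0.5, df = 1)
}
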