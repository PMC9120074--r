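#' Derive a per-stage child seed from a global seed
#'
#' A single pipeline seed is expanded into independent per-stage seeds by a
#' documented splitting rule: the stage name is folded into an integer by a
#' polynomial string hash and combined with the parent seed modulo 2^31 - 1.
#' Deterministic, stage-order independent, and always a valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param stage stage name (character scalar).
#' @return integer seed in \[0, 2^31 - 2\].
#' @export
childSeed <- function(seed, stage) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
    m <- 2147483647  # 2^31 - 1
    h <- 0
    for (cc in utf8ToInt(stage)) h <- (h * 31 + cc) %% m
    as.integer((abs(seed) %% m * 69069 + h) %% m)
}

## internal: stop unless all named conditions hold, with the condition text
.assertAll <- function(...) {
    conds <- c(...)
    bad <- names(conds)[!vapply(conds, isTRUE, logical(1))]
    if (length(bad))
        stop("invalid arguments: ", paste(bad, collapse = "; "),
             call. = FALSE)
    invisible(TRUE)
}

#' Clumping + thresholding parameters
#'
#' Defaults mirror common PRS practice: only the base-study inclusion
#' threshold (`p_threshold = 0.05`) is dictated by the design; window and r2
#' are the scoring tool's defaults and are configurable and logged.
#'
#' @param p_threshold base-GWAS inclusion p cutoff for retained index SNPs.
#' @param clump_kb window half-width in kb.
#' @param clump_r2 LD pruning threshold.
#' @param clump_p maximum p for a variant to enter clumping at all.
#' @return validated list of class `ClumpParams`.
#' @export
clumpParams <- function(p_threshold = 0.05, clump_kb = 250,
                        clump_r2 = 0.1, clump_p = 1) {
    .assertAll(
        p_threshold = p_threshold > 0 && p_threshold <= 1,
        clump_p = clump_p > 0 && clump_p <= 1,
        clump_r2 = clump_r2 > 0 && clump_r2 <= 1,
        clump_kb = clump_kb > 0)
    structure(list(p_threshold = p_threshold, clump_kb = clump_kb,
                   clump_r2 = clump_r2, clump_p = clump_p),
              class = "ClumpParams")
}

#' Variant QC parameters
#'
#' Two canonical presets exist in this design: the score-construction stage
#' (`qcParamsPRS()`: MAF >= 0.1%, HWE exact p > 1e-15, missingness < 1%) and
#' the extremes-GWAS stage (`qcParams()`: MAF >= 5%, HWE p >= 1e-6,
#' missingness <= 1%).
#'
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p.
#' @param miss_max maximum missing-call fraction.
#' @return validated list of class `QCParams`.
#' @export
qcParams <- function(maf_min = 0.05, hwe_p_min = 1e-6, miss_max = 0.01) {
    .assertAll(
        maf_min = maf_min >= 0 && maf_min < 0.5,
        hwe_p_min = hwe_p_min >= 0 && hwe_p_min <= 1,
        miss_max = miss_max >= 0 && miss_max <= 1)
    structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                   miss_max = miss_max), class = "QCParams")
}

#' @rdname qcParams
#' @export
qcParamsPRS <- function(maf_min = 0.001, hwe_p_min = 1e-15,
                        miss_max = 0.01) {
    qcParams(maf_min, hwe_p_min, miss_max)
}

#' Genomic risk locus parameters
#'
#' The FUMA-style three-tier hierarchy: genome-wide significant SNPs are
#' clumped at `r2_independent` into independent significant SNPs, those at
#' `r2_lead` into lead SNPs, and candidate-SNP LD-block envelopes closer than
#' `merge_kb` are merged into one locus.
#'
#' @param sig_p genome-wide significance threshold.
#' @param cand_p candidate-SNP inclusion p.
#' @param r2_independent first clumping r2 threshold.
#' @param r2_lead second clumping r2 threshold.
#' @param merge_kb locus merge distance (kb).
#' @return validated list of class `LocusParams`.
#' @export
locusParams <- function(sig_p = 5e-8, cand_p = 0.05,
                        r2_independent = 0.6, r2_lead = 0.1,
                        merge_kb = 250) {
    .assertAll(
        sig_p = sig_p > 0 && sig_p <= 1,
        cand_p = cand_p > 0 && cand_p <= 1,
        r2 = r2_lead <= r2_independent,
        merge_kb = merge_kb > 0)
    structure(list(sig_p = sig_p, cand_p = cand_p,
                   r2_independent = r2_independent, r2_lead = r2_lead,
                   merge_kb = merge_kb), class = "LocusParams")
}
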