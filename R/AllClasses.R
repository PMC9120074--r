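#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## GenotypeMatrix
## ---------------------------------------------------------------------------

#' Dosage genotypes with variant metadata
#'
#' A `GenotypeMatrix` is a [SummarizedExperiment::RangedSummarizedExperiment]
#' with a single `"dosage"` assay (variants in rows, samples in columns,
#' values in \[0, 2\] or `NA` for missing) and per-variant metadata in
#' `rowRanges()`: `id`, `a1` (the counted, effect allele), `a2`, and for
#' simulated data the generating allele frequency (`true_freq`) and LD block
#' index (`block`). The genome build label is kept in `metadata()$build`
#' (GRCh37 by convention).
#'
#' @slot .Data see `RangedSummarizedExperiment`.
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
    msg <- character(0)
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- SummarizedExperiment::assay(object, "dosage")
        rng <- suppressWarnings(range(d, na.rm = TRUE))
        if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
            msg <- c(msg, "dosages must lie in [0, 2] or be NA")
    }
    rr <- SummarizedExperiment::rowRanges(object)
    mc <- S4Vectors::mcols(rr)
    need <- c("id", "a1", "a2")
    if (!all(need %in% colnames(mc)))
        msg <- c(msg, "rowRanges must carry mcols id, a1, a2")
    else {
        key <- paste(as.character(GenomicRanges::seqnames(rr)),
                     GenomicRanges::start(rr), mc$a1, mc$a2)
        if (anyDuplicated(key))
            msg <- c(msg, "(chrom, pos, a1, a2) must be unique")
        ## positions sorted within chromosome
        sp <- split(GenomicRanges::start(rr),
                    as.character(GenomicRanges::seqnames(rr)))
        if (any(vapply(sp, is.unsorted, logical(1))))
            msg <- c(msg, "positions must be sorted within chromosome")
    }
    if (length(msg)) msg else TRUE
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric matrix, variants x samples, values in \[0,2\] or NA.
#' @param variants `GRanges` (one range per variant, width 1) with mcols
#'   `id`, `a1`, `a2` and optionally `true_freq`, `block`.
#' @param sample_ids character vector of sample identifiers.
#' @param build genome build label (free text; default `"GRCh37"`).
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'                              id = c("v1", "v2"), a1 = "A", a2 = "G")
#' G <- GenotypeMatrix(matrix(c(0, 1, 2, 1), 2, 2), gr, c("s1", "s2"))
#' nVariants(G)
#' @export
GenotypeMatrix <- function(dosage, variants, sample_ids,
                           build = "GRCh37") {
    dosage <- as.matrix(dosage)
    stopifnot(nrow(dosage) == length(variants),
              ncol(dosage) == length(sample_ids))
    rownames(dosage) <- S4Vectors::mcols(variants)$id
    colnames(dosage) <- sample_ids
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dosage),
        rowRanges = variants,
        colData = S4Vectors::DataFrame(row.names = sample_ids))
    obj <- new("GenotypeMatrix", se)
    S4Vectors::metadata(obj)$build <- build
    obj
}

#' @describeIn GenotypeMatrix variants x samples dosage matrix.
#' @param x,object a `GenotypeMatrix`.
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeMatrix per-variant `GRanges` (mcols `id`, `a1`, `a2`, ...).
#' @export
variantInfo <- function(x) SummarizedExperiment::rowRanges(x)

#' @describeIn GenotypeMatrix sample identifiers.
#' @export
sampleIDs <- function(x) colnames(x)

#' @describeIn GenotypeMatrix number of variants.
#' @export
nVariants <- function(x) nrow(x)

#' @describeIn GenotypeMatrix number of samples.
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GenotypeMatrix empirical effect-allele (a1) frequencies,
#'   computed over non-missing dosages.
#' @export
alleleFreq <- function(x) {
    rowMeans(dosages(x), na.rm = TRUE) / 2
}

setMethod("show", "GenotypeMatrix", function(object) {
    cat("GenotypeMatrix:", nrow(object), "variants x", ncol(object),
        "samples;", "build", S4Vectors::metadata(object)$build, "\n")
    chr <- table(as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(object))))
    cat("  chromosomes:", paste(names(chr), collapse = " "), "\n")
    nmiss <- sum(is.na(SummarizedExperiment::assay(object, "dosage")))
    cat("  missing dosages:", nmiss, "\n")
})

## ---------------------------------------------------------------------------
## SummaryStats
## ---------------------------------------------------------------------------

#' GWAS summary statistics
#'
#' Per-variant association statistics of a (base or extremes) GWAS:
#' `chrom`, `pos` (1-based), `id`, `effect_allele`, `other_allele`,
#' `beta` (log-odds scale), `se`, `p`, `freq` (effect-allele fraction) and
#' `n` (effective sample size). Rows with undefined statistics (e.g.
#' monomorphic variants) carry `NA` and are flagged in the optional
#' `flagged` column.
#'
#' @slot tbl data.frame with the columns above.
#' @export
setClass("SummaryStats", representation(tbl = "data.frame"))

.SS_COLS <- c("chrom", "pos", "id", "effect_allele", "other_allele",
              "beta", "se", "p", "freq", "n")

.validSummaryStats <- function(object) {
    tb <- object@tbl
    msg <- character(0)
    if (!all(.SS_COLS %in% colnames(tb)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(.SS_COLS, colnames(tb)),
                                  collapse = ", ")))
    else {
        ok <- !is.na(tb$p)
        if (any(tb$p[ok] <= 0 | tb$p[ok] > 1))
            msg <- c(msg, "p must lie in (0, 1]")
        ok <- !is.na(tb$se)
        if (any(tb$se[ok] <= 0))
            msg <- c(msg, "se must be > 0 where present")
        ok <- !is.na(tb$freq)
        if (any(tb$freq[ok] <= 0 | tb$freq[ok] >= 1))
            msg <- c(msg, "freq must lie in (0, 1) where present")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SummaryStats", .validSummaryStats)

#' Construct SummaryStats from a data.frame
#'
#' @param tbl data.frame with columns `chrom`, `pos`, `id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`, `freq`, `n` (extra columns kept).
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(tbl) {
    tbl$chrom <- as.character(tbl$chrom)
    tbl$pos <- as.integer(tbl$pos)
    rownames(tbl) <- NULL
    new("SummaryStats", tbl = tbl)
}

#' @describeIn SummaryStats underlying data.frame.
#' @param x,object a `SummaryStats`.
#' @export
statsTable <- function(x) x@tbl

#' @export
setMethod("length", "SummaryStats", function(x) nrow(x@tbl))

#' @export
setMethod("[", "SummaryStats", function(x, i, j, ..., drop = TRUE) {
    SummaryStats(x@tbl[i, , drop = FALSE])
})

setMethod("show", "SummaryStats", function(object) {
    tb <- object@tbl
    cat("SummaryStats:", nrow(tb), "variants\n")
    if (nrow(tb)) {
        cat("  chromosomes:",
            paste(unique(tb$chrom), collapse = " "), "\n")
        cat("  min p:", format(suppressWarnings(min(tb$p, na.rm = TRUE))),
            " flagged:", sum(is.na(tb$p)), "\n")
    }
})

#' Per-variant Wald chi-square statistics
#'
#' @param ss a [SummaryStats-class] object.
#' @return numeric vector `(beta/se)^2`.
#' @export
chiSq <- function(ss) (statsTable(ss)$beta / statsTable(ss)$se)^2

## ---------------------------------------------------------------------------
## PRSResult
## ---------------------------------------------------------------------------

#' Polygenic risk scores
#'
#' Raw scores are weighted sums of effect-allele dosages; rescaled scores are
#' the cosmetic min-max transform to \[0,1\] used for display only — group
#' assignment always uses raw scores.
#'
#' @slot sample_id character.
#' @slot raw numeric raw scores.
#' @slot rescaled numeric min-max rescaled scores (`NA` when not requested).
#' @slot n_variants_used integer.
#' @slot variant_ids_used character.
#' @export
setClass("PRSResult", representation(
    sample_id = "character", raw = "numeric", rescaled = "numeric",
    n_variants_used = "integer", variant_ids_used = "character"))

setValidity("PRSResult", function(object) {
    msg <- character(0)
    if (length(object@raw) != length(object@sample_id))
        msg <- c(msg, "raw and sample_id lengths differ")
    if (object@n_variants_used != length(object@variant_ids_used))
        msg <- c(msg, "n_variants_used must equal length(variant_ids_used)")
    if (length(msg)) msg else TRUE
})

#' @describeIn PRSResult raw scores, named by sample.
#' @param x,object a `PRSResult`.
#' @export
rawScores <- function(x) stats::setNames(x@raw, x@sample_id)

#' @describeIn PRSResult min-max rescaled scores, named by sample.
#' @export
rescaledScores <- function(x) stats::setNames(x@rescaled, x@sample_id)

setMethod("show", "PRSResult", function(object) {
    cat("PRSResult:", length(object@sample_id), "samples,",
        object@n_variants_used, "variants used\n")
    cat("  raw score range:",
        paste(format(range(object@raw)), collapse = " .. "), "\n")
})

## ---------------------------------------------------------------------------
## ExtremeGroups
## ---------------------------------------------------------------------------

#' Extreme-tail group assignment
#'
#' Per-sample label in `{low, high, unassigned}` derived from the raw PRS
#' distribution: the `k = ceiling(q * N)` lowest scores form the low group
#' and the `k` highest the high group, with boundary ties broken by stable
#' sample-id order.
#'
#' @slot sample_id character.
#' @slot label factor with levels low, high, unassigned.
#' @slot q tail fraction.
#' @slot k per-tail count.
#' @export
setClass("ExtremeGroups", representation(
    sample_id = "character", label = "factor", q = "numeric", k = "integer"))

setValidity("ExtremeGroups", function(object) {
    msg <- character(0)
    if (!identical(levels(object@label), c("low", "high", "unassigned")))
        msg <- c(msg, "label levels must be low, high, unassigned")
    if (length(object@label) != length(object@sample_id))
        msg <- c(msg, "label and sample_id lengths differ")
    tab <- table(object@label)
    if (tab[["low"]] != object@k || tab[["high"]] != object@k)
        msg <- c(msg, "low and high groups must each contain k samples")
    if (length(msg)) msg else TRUE
})

#' @describeIn ExtremeGroups labels named by sample.
#' @param x,object an `ExtremeGroups`.
#' @export
groupLabels <- function(x) stats::setNames(x@label, x@sample_id)

#' @describeIn ExtremeGroups ids of the low tail.
#' @export
lowSamples <- function(x) x@sample_id[x@label == "low"]

#' @describeIn ExtremeGroups ids of the high tail.
#' @export
highSamples <- function(x) x@sample_id[x@label == "high"]

#' @describeIn ExtremeGroups per-tail count k.
#' @export
tailCount <- function(x) x@k

setMethod("show", "ExtremeGroups", function(object) {
    cat("ExtremeGroups: q =", object@q, "-> k =", object@k, "per tail;",
        sum(object@label == "unassigned"), "unassigned of",
        length(object@label), "samples\n")
})

## ---------------------------------------------------------------------------
## GwasRun
## ---------------------------------------------------------------------------

#' Extremes GWAS result
#'
#' Association records for every variant (QC-passing variants carry logistic
#' regression estimates, QC failures carry a `filtered(...)` status) plus the
#' genomic inflation factor computed over ok-status p-values.
#'
#' @slot records data.frame: chrom, pos, id, beta, se, or_, ci_low, ci_high,
#'   p, maf_all, maf_low, maf_high, n_used, status.
#' @slot lambda_gc genomic inflation factor.
#' @slot n_high,n_low group sizes (high tail coded as case).
#' @slot covariate_names character.
#' @export
setClass("GwasRun", representation(
    records = "data.frame", lambda_gc = "numeric",
    n_high = "integer", n_low = "integer", covariate_names = "character"))

setValidity("GwasRun", function(object) {
    msg <- character(0)
    if (length(object@lambda_gc) && !is.na(object@lambda_gc) &&
        object@lambda_gc <= 0)
        msg <- c(msg, "lambda_gc must be > 0")
    ok <- object@records$status == "ok"
    if (any(ok) && any(object@records$or_[ok] <= 0, na.rm = TRUE))
        msg <- c(msg, "odds ratios must be positive for ok records")
    if (length(msg)) msg else TRUE
})

#' @describeIn GwasRun association table.
#' @param x,object a `GwasRun`.
#' @export
assocRecords <- function(x) x@records

#' @describeIn GwasRun genomic inflation factor over ok-status p-values.
#' @export
lambdaGC <- function(x) x@lambda_gc

setMethod("show", "GwasRun", function(object) {
    cat("GwasRun:", nrow(object@records), "variants (",
        sum(object@records$status == "ok"), "ok );",
        "cases (high):", object@n_high, "controls (low):", object@n_low, "\n")
    cat("  lambda_gc:", format(object@lambda_gc, digits = 4), "\n")
    if (length(object@covariate_names))
        cat("  covariates:", paste(object@covariate_names, collapse = ", "),
            "\n")
})

## ---------------------------------------------------------------------------
## TraitTable
## ---------------------------------------------------------------------------

#' Mixed-type phenotype table for the phenome scan
#'
#' Trait values per sample plus a type manifest
#' (`id`, `type` in continuous/binary/ordered/unordered, and for simulated
#' tables the generating effect size and missingness rate).
#'
#' @slot values data.frame, first column `sample_id`, one column per trait.
#' @slot manifest data.frame with at least `id` and `type`.
#' @export
setClass("TraitTable", representation(
    values = "data.frame", manifest = "data.frame"))

setValidity("TraitTable", function(object) {
    msg <- character(0)
    if (!identical(colnames(object@values)[1], "sample_id"))
        msg <- c(msg, "first column of values must be sample_id")
    if (!all(object@manifest$id %in% colnames(object@values)))
        msg <- c(msg, "manifest ids must match trait columns")
    if (!all(object@manifest$type %in%
             c("continuous", "binary", "ordered", "unordered")))
        msg <- c(msg, "manifest types must be continuous/binary/ordered/unordered")
    if (length(msg)) msg else TRUE
})

#' @describeIn TraitTable trait values (first column sample_id).
#' @param x,object a `TraitTable`.
#' @export
traitValues <- function(x) x@values

#' @describeIn TraitTable the type manifest.
#' @export
traitManifest <- function(x) x@manifest

setMethod("show", "TraitTable", function(object) {
    cat("TraitTable:", nrow(object@values), "samples x",
        nrow(object@manifest), "traits\n")
    print(table(object@manifest$type))
})
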