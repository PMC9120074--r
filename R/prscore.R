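## Clumping + thresholding PRS construction, region exclusion, min-max
## rescaling, and extreme-tail group assignment.

#' Pairwise LD between two variants
#'
#' Squared Pearson correlation of dosages over samples non-missing at both
#' variants. Symmetric; `ldR2(G, i, i)` is 1 for any polymorphic variant.
#' Monomorphic variants have undefined correlation: `NA` is returned and
#' clumping treats it as 0.
#'
#' @param G a [GenotypeMatrix-class].
#' @param i,j variant indices.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
ldR2 <- function(G, i, j) {
    D <- dosages(G)
    r <- suppressWarnings(stats::cor(D[i, ], D[j, ],
                                     use = "pairwise.complete.obs"))
    if (is.na(r)) NA_real_ else r^2
}

## internal clumping engine shared by PRS clumping and locus definition.
## cand: candidate row indices into `pos`/`chrom`/columns of Dt, already
## sorted by priority (best first). window_bp = Inf clumps chromosome-wide.
## Returns list(index = retained cand positions, assigned_to = for every
## candidate, the retained index that clumped it (itself for survivors)).
.greedyClump <- function(Dt, chrom, pos, cand, r2_thresh, window_bp) {
    n_cand <- length(cand)
    clumped <- rep(FALSE, n_cand)
    assigned <- rep(NA_integer_, n_cand)
    keep <- integer(0)
    for (u in seq_len(n_cand)) {
        if (clumped[u]) next
        v <- cand[u]
        keep <- c(keep, u)
        assigned[u] <- u
        live <- which(!clumped & seq_len(n_cand) > u)
        if (!length(live)) next
        w <- live[chrom[cand[live]] == chrom[v] &
                  abs(pos[cand[live]] - pos[v]) <= window_bp]
        if (!length(w)) next
        r <- suppressWarnings(stats::cor(
            Dt[, v], Dt[, cand[w], drop = FALSE],
            use = "pairwise.complete.obs"))
        r2 <- as.vector(r)^2
        r2[is.na(r2)] <- 0  # monomorphic partner: no evidence of LD
        hit <- w[r2 >= r2_thresh]
        clumped[hit] <- TRUE
        assigned[hit] <- u
    }
    list(index = keep, assigned_to = assigned)
}

#' Greedy LD clumping of summary statistics against an LD panel
#'
#' Candidates with `p < clump_p` are visited in ascending p order (ties by
#' chrom, pos); each unclumped variant in turn becomes an index SNP and
#' removes all unclumped variants within `clump_kb` kb with
#' `r2 >= clump_r2`. Index SNPs with `p < p_threshold` are returned. The
#' retained set therefore never contains a pair that is both within the
#' window and at or above the r2 threshold.
#'
#' @param ss a [SummaryStats-class], harmonized to the panel (every variant
#'   must match a panel variant on chrom and pos).
#' @param panel LD reference [GenotypeMatrix-class] (by default the analysis
#'   cohort itself).
#' @param params a [clumpParams()].
#' @return integer vector of retained row indices into `ss`, in ascending
#'   index order, with the retained ids in `attr(, "ids")`.
#' @export
clumpVariants <- function(ss, panel, params = clumpParams()) {
    stopifnot(inherits(params, "ClumpParams"))
    tb <- statsTable(ss)
    gr <- variantInfo(panel)
    gpos <- GenomicRanges::start(gr)
    gchr <- as.character(GenomicRanges::seqnames(gr))
    gi <- match(paste0(tb$chrom, ":", tb$pos), paste0(gchr, ":", gpos))
    if (anyNA(gi))
        stop("summary statistics are not harmonized to the panel: ",
             sum(is.na(gi)), " variants unmatched")
    cand <- which(!is.na(tb$p) & tb$p < params$clump_p)
    if (!length(cand)) stop("no variants pass p threshold")
    ord <- cand[order(tb$p[cand], tb$chrom[cand], tb$pos[cand])]
    Dt <- t(dosages(panel))
    res <- .greedyClump(Dt, gchr, gpos, gi[ord],
                        params$clump_r2, params$clump_kb * 1000)
    idx <- ord[res$index]
    idx <- idx[tb$p[idx] < params$p_threshold]
    if (!length(idx)) stop("no variants pass p threshold")
    idx <- sort(idx)
    attr(idx, "ids") <- tb$id[idx]
    idx
}

#' Exclude variants in a genomic region
#'
#' Removes variants with position in `[start, end]` (both inclusive) on
#' `chrom`. In anchor mode the window instead locates the most significant
#' variant inside it and the excluded region becomes that position
#' `+/- radius_bp` (the score-stage convention for a dominant locus; the
#' fixed-window mode matches the correlation-stage convention).
#'
#' @param x a [SummaryStats-class] or a data.frame with `chrom` and `pos`
#'   (e.g. a weight table).
#' @param chrom chromosome label.
#' @param start,end region bounds, 1-based inclusive.
#' @param anchor if `TRUE`, use `[start, end]` only to find the lowest-p
#'   variant and exclude `anchor_pos +/- radius_bp`.
#' @param radius_bp anchor-mode radius (default 1 Mb).
#' @return `x` minus the excluded variants; removed count in
#'   `attr(, "n_removed")`.
#' @export
excludeRegion <- function(x, chrom, start, end, anchor = FALSE,
                          radius_bp = 1e6) {
    stopifnot(end >= start)
    tb <- if (inherits(x, "SummaryStats")) statsTable(x) else x
    stopifnot(all(c("chrom", "pos") %in% colnames(tb)))
    if (anchor) {
        if (!"p" %in% colnames(tb))
            stop("anchor mode requires a p column")
        inwin <- which(tb$chrom == chrom & tb$pos >= start & tb$pos <= end &
                       !is.na(tb$p))
        if (!length(inwin))
            stop("anchor locus contains no variants")
        apos <- tb$pos[inwin[which.min(tb$p[inwin])]]
        start <- apos - radius_bp
        end <- apos + radius_bp
    }
    drop <- tb$chrom == chrom & tb$pos >= start & tb$pos <= end
    out <- if (inherits(x, "SummaryStats")) x[!drop]
           else tb[!drop, , drop = FALSE]
    attr(out, "n_removed") <- sum(drop)
    out
}

#' Build a PRS weight table from a harmonized pair
#'
#' @param harm a `HarmonizedPair` from [harmonizeAlleles()].
#' @param ss the [SummaryStats-class] that was harmonized.
#' @param retained optional subset of `ss` row indices (e.g. the output of
#'   [clumpVariants()]); defaults to all harmonized variants.
#' @return data.frame with `g_idx`, `beta`, `sign_flip`, `id`, `chrom`, `pos`.
#' @export
prsWeights <- function(harm, ss, retained = NULL) {
    stopifnot(inherits(harm, "HarmonizedPair"))
    tb <- statsTable(ss)
    use <- if (is.null(retained)) seq_along(harm$ss_idx)
           else {
               m <- match(retained, harm$ss_idx)
               m[!is.na(m)]
           }
    data.frame(g_idx = harm$g_idx[use],
               beta = tb$beta[harm$ss_idx[use]],
               sign_flip = harm$sign_flip[use],
               id = tb$id[harm$ss_idx[use]],
               chrom = tb$chrom[harm$ss_idx[use]],
               pos = tb$pos[harm$ss_idx[use]])
}

#' Compute polygenic risk scores
#'
#' Raw score per sample is `sum_j beta_j * d_ij` over the weight table,
#' where dosages at sign-flipped variants are reoriented as `d -> 2 - d`
#' and missing dosages are mean-imputed as twice the cohort effect-allele
#' frequency. Min-max rescaling to \[0,1\] is display-only and never feeds
#' statistics.
#'
#' @param G a [GenotypeMatrix-class].
#' @param weights data.frame from [prsWeights()] (columns `g_idx`, `beta`,
#'   optionally `sign_flip`, `id`).
#' @param rescale compute the min-max rescaled score (default `TRUE`).
#' @return A [PRSResult-class].
#' @export
scorePRS <- function(G, weights, rescale = TRUE) {
    stopifnot(nrow(weights) > 0,
              all(weights$g_idx >= 1 & weights$g_idx <= nVariants(G)))
    D <- dosages(G)[weights$g_idx, , drop = FALSE]
    flip <- if (is.null(weights$sign_flip)) rep(FALSE, nrow(weights))
            else weights$sign_flip
    if (any(flip)) D[flip, ] <- 2 - D[flip, , drop = FALSE]
    all_na <- rowSums(!is.na(D)) == 0
    if (any(all_na)) {
        warning(sum(all_na), " all-missing variants excluded from score")
        D <- D[!all_na, , drop = FALSE]
        weights <- weights[!all_na, , drop = FALSE]
    }
    if (anyNA(D)) {
        f2 <- rowMeans(D, na.rm = TRUE)  # = 2 * effect-allele frequency
        miss <- which(is.na(D), arr.ind = TRUE)
        D[miss] <- f2[miss[, 1]]
    }
    raw <- as.vector(crossprod(D, weights$beta))
    resc <- rep(NA_real_, length(raw))
    if (rescale) {
        rng <- range(raw)
        if (rng[1] == rng[2]) {
            warning("degenerate score distribution: max == min; ",
                    "rescaled scores set to 0.5")
            resc <- rep(0.5, length(raw))
        } else resc <- (raw - rng[1]) / (rng[2] - rng[1])
    }
    ids <- if (is.null(weights$id)) as.character(weights$g_idx)
           else as.character(weights$id)
    new("PRSResult", sample_id = sampleIDs(G), raw = raw, rescaled = resc,
        n_variants_used = nrow(weights), variant_ids_used = ids)
}

#' Assign extreme-tail groups from the score distribution
#'
#' `k = ceiling(q * N)` samples with the smallest raw scores form the low
#' group and the `k` largest the high group; boundary ties are broken by
#' stable sample-id order (with a warning), everyone else is unassigned.
#'
#' @param prs a [PRSResult-class].
#' @param q tail fraction, in (0, 0.5).
#' @return An [ExtremeGroups-class].
#' @examples
#' prs <- new("PRSResult", sample_id = paste0("s", 1:100),
#'            raw = rnorm(100), rescaled = rep(NA_real_, 100),
#'            n_variants_used = 1L, variant_ids_used = "v")
#' tailCount(assignExtremes(prs, 0.05))  # ceiling(5) = 5
#' @export
assignExtremes <- function(prs, q) {
    stopifnot(q > 0, q < 0.5)
    n <- length(prs@raw)
    stopifnot(n >= 2)
    k <- as.integer(ceiling(q * n))
    if (2 * k > n)
        stop("2k = ", 2 * k, " exceeds cohort size ", n)
    ord <- order(prs@raw, prs@sample_id)
    lab <- factor(rep("unassigned", n),
                  levels = c("low", "high", "unassigned"))
    lab[ord[seq_len(k)]] <- "low"
    lab[ord[seq(n - k + 1L, n)]] <- "high"
    r <- prs@raw[ord]
    if (r[k] == r[k + 1L] || r[n - k + 1L] == r[n - k])
        warning("score ties at a tail boundary broken by sample-id order")
    new("ExtremeGroups", sample_id = prs@sample_id, label = lab,
        q = q, k = k)
}
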