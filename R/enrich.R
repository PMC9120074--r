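## Positional gene mapping of significant SNPs and hypergeometric gene-set
## overlap enrichment with Benjamini-Hochberg FDR.

#' Positional gene mapping
#'
#' A gene is mapped when some significant SNP lies within its boundaries or
#' immediately up/downstream within `window_kb` kb (default 10 kb, both
#' boundaries inclusive). Output is deduplicated and sorted by position.
#'
#' @param snps data.frame with `chrom` and `pos` of significant SNPs.
#' @param genes `GRanges` with mcol `gene_id`.
#' @param window_kb flank in kb.
#' @return character vector of mapped gene ids.
#' @export
mapGenesPositional <- function(snps, genes, window_kb = 10) {
    if (!nrow(snps) || !length(genes)) return(character(0))
    w <- window_kb * 1000
    gchr <- as.character(GenomicRanges::seqnames(genes))
    gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
    hit <- vapply(seq_along(genes), function(i)
        any(snps$chrom == gchr[i] &
            snps$pos >= gs[i] - w & snps$pos <= ge[i] + w),
        logical(1))
    genes$gene_id[hit][order(gs[hit])]
}

#' Hypergeometric gene-set overlap enrichment
#'
#' One-sided overlap test per set: with a background of `N` genes of which
#' `K` are in the set and `n` are in the input, the p-value is
#' `P[X >= observed]` for hypergeometric X. Every catalog set with at least
#' one background gene enters the multiple-testing family (BH across all of
#' them); sets overlapping fewer than `min_overlap` input genes are excluded
#' from the *reported* table only.
#'
#' @param input_genes character vector (must be a subset of `background`).
#' @param catalog named list of gene-id vectors (sets are intersected with
#'   the background).
#' @param background gene universe (defaults to the union of catalog genes
#'   and input).
#' @param min_overlap minimum overlap for reporting (default 2).
#' @return data.frame of class `EnrichmentResult`: set, overlap,
#'   overlap_genes, set_size, input_size, background_size, p, p_adj,
#'   reported; ordered by adjusted then raw p.
#' @export
hypergeomEnrichment <- function(input_genes, catalog, background = NULL,
                                min_overlap = 2) {
    if (is.null(background))
        background <- unique(c(unlist(catalog), input_genes))
    if (!length(background)) stop("empty background universe")
    if (!all(input_genes %in% background))
        stop("input genes must be a subset of the background")
    input_genes <- unique(input_genes)
    N <- length(unique(background))
    n <- length(input_genes)
    rows <- lapply(names(catalog), function(nm) {
        set <- intersect(unique(catalog[[nm]]), background)
        K <- length(set)
        if (!K) return(NULL)
        ov <- intersect(set, input_genes)
        p <- stats::phyper(length(ov) - 1, K, N - K, n,
                           lower.tail = FALSE)
        data.frame(set = nm, overlap = length(ov),
                   overlap_genes = paste(sort(ov), collapse = ","),
                   set_size = K, input_size = n, background_size = N,
                   p = min(1, p))
    })
    res <- do.call(rbind, rows)
    if (is.null(res)) stop("no catalog set has background genes")
    res$p_adj <- bhAdjust(res$p)
    res$reported <- res$overlap >= min_overlap
    res <- res[order(res$p_adj, res$p), , drop = FALSE]
    rownames(res) <- NULL
    class(res) <- c("EnrichmentResult", class(res))
    res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), with input
#' validation.
#'
#' @param p_values p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p_values) {
    if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p_values, method = "BH")
}
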