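## FUMA-style genomic risk loci: independent significant SNPs (first clump,
## r2 0.6), lead SNPs (second clump, r2 0.1), candidate-SNP LD-block
## envelopes merged within 250 kb, nearest-gene labels, and classification
## against the base study.

#' Independent significant SNPs
#'
#' Greedy chromosome-wide clumping of genome-wide significant, ok-status
#' variants at `r2_independent` (ascending p, ties by chrom and pos). The
#' returned SNPs are pairwise below the r2 threshold or on different
#' chromosomes.
#'
#' @param gwas a [GwasRun-class].
#' @param panel LD panel ([GenotypeMatrix-class]); by default the analysis
#'   cohort itself stands in for an external reference.
#' @param params a [locusParams()].
#' @return data.frame: record_idx (row in `assocRecords(gwas)`), id, chrom,
#'   pos, p, panel_idx. Zero rows when nothing is significant.
#' @export
independentSignificant <- function(gwas, panel, params = locusParams()) {
    stopifnot(inherits(params, "LocusParams"))
    rec <- assocRecords(gwas)
    sig <- which(rec$status == "ok" & !is.na(rec$p) & rec$p <= params$sig_p)
    empty <- data.frame(record_idx = integer(0), id = character(0),
                        chrom = character(0), pos = integer(0),
                        p = numeric(0), panel_idx = integer(0))
    if (!length(sig)) return(empty)
    pidx <- .matchPanel(rec[sig, ], panel)
    ord <- order(rec$p[sig], rec$chrom[sig], rec$pos[sig])
    gr <- variantInfo(panel)
    res <- .greedyClump(t(dosages(panel)),
                        as.character(GenomicRanges::seqnames(gr)),
                        GenomicRanges::start(gr),
                        pidx[ord], params$r2_independent, Inf)
    keep <- sig[ord[res$index]]
    out <- data.frame(record_idx = keep, id = rec$id[keep],
                      chrom = rec$chrom[keep], pos = rec$pos[keep],
                      p = rec$p[keep], panel_idx = pidx[ord[res$index]])
    out[order(out$chrom, out$pos), , drop = FALSE]
}

.matchPanel <- function(rec, panel) {
    if (!nrow(rec)) return(integer(0))
    gr <- variantInfo(panel)
    gi <- match(paste0(rec$chrom, ":", rec$pos),
                paste0(as.character(GenomicRanges::seqnames(gr)), ":",
                       GenomicRanges::start(gr)))
    if (anyNA(gi))
        stop("GWAS variants missing from the LD panel: ", sum(is.na(gi)))
    gi
}

#' Lead SNPs and merged genomic risk loci
#'
#' Lead SNPs are a second greedy clump of the independent significant SNPs
#' at `r2_lead`; every independent significant SNP is assigned to the lead
#' that clumped it. Candidate SNPs (`p <= cand_p`, r2 >= `r2_independent`
#' with any member, searched within 1 Mb) define each group's LD-block
#' envelope (min/max candidate position), and envelopes closer than
#' `merge_kb` on one chromosome are merged into a single locus, numbered in
#' genome order.
#'
#' @param ind_sig output of [independentSignificant()].
#' @param gwas the [GwasRun-class].
#' @param panel the LD panel.
#' @param params a [locusParams()].
#' @return list: `loci` (locus_id, chrom, start_bp, end_bp, n_ind_sig,
#'   n_lead, lead_ids, top_snp, top_p) and `members` (per independent
#'   significant SNP: id, chrom, pos, p, lead_id, locus_id).
#' @export
leadAndLoci <- function(ind_sig, gwas, panel, params = locusParams()) {
    empty <- list(loci = data.frame(), members = data.frame())
    if (!nrow(ind_sig)) return(empty)
    rec <- assocRecords(gwas)
    gr <- variantInfo(panel)
    gchr <- as.character(GenomicRanges::seqnames(gr))
    gpos <- GenomicRanges::start(gr)
    Dt <- t(dosages(panel))
    ord <- order(ind_sig$p, ind_sig$chrom, ind_sig$pos)
    cl <- .greedyClump(Dt, gchr, gpos, ind_sig$panel_idx[ord],
                       params$r2_lead, Inf)
    lead_of <- integer(nrow(ind_sig))  # row in ind_sig of each SNP's lead
    lead_of[ord] <- ord[cl$assigned_to]
    lead_rows <- ord[cl$index]
    ## candidate envelope per lead group
    cand <- which(!is.na(rec$p) & rec$p <= params$cand_p &
                  rec$status == "ok")
    cand_pidx <- .matchPanel(rec[cand, ], panel)
    groups <- split(seq_len(nrow(ind_sig)), lead_of)
    env <- lapply(groups, function(g) {
        lo <- min(ind_sig$pos[g]); hi <- max(ind_sig$pos[g])
        chrom <- ind_sig$chrom[g[1]]
        near <- which(rec$chrom[cand] == chrom &
                      rec$pos[cand] >= lo - 1e6 &
                      rec$pos[cand] <= hi + 1e6)
        if (length(near)) {
            r <- suppressWarnings(stats::cor(
                Dt[, cand_pidx[near], drop = FALSE],
                Dt[, ind_sig$panel_idx[g], drop = FALSE],
                use = "pairwise.complete.obs"))
            r[is.na(r)] <- 0
            inblock <- apply(r^2 >= params$r2_independent, 1, any)
            if (any(inblock)) {
                lo <- min(lo, rec$pos[cand[near[inblock]]])
                hi <- max(hi, rec$pos[cand[near[inblock]]])
            }
        }
        data.frame(chrom = chrom, start_bp = lo, end_bp = hi,
                   lead_row = g[1])
    })
    env <- do.call(rbind, env)
    env$group <- as.integer(names(groups))
    env <- env[order(env$chrom, env$start_bp), , drop = FALSE]
    ## merge envelopes within merge_kb on one chromosome
    merge_bp <- params$merge_kb * 1000
    locus_no <- integer(nrow(env))
    cur <- 0; cur_end <- -Inf; cur_chr <- ""
    for (i in seq_len(nrow(env))) {
        if (env$chrom[i] != cur_chr ||
            env$start_bp[i] - cur_end > merge_bp) {
            cur <- cur + 1
            cur_chr <- env$chrom[i]
            cur_end <- env$end_bp[i]
        } else cur_end <- max(cur_end, env$end_bp[i])
        locus_no[i] <- cur
    }
    members <- data.frame(id = ind_sig$id, chrom = ind_sig$chrom,
                          pos = ind_sig$pos, p = ind_sig$p,
                          lead_id = ind_sig$id[lead_of],
                          locus_id = NA_integer_)
    loci <- lapply(unique(locus_no), function(l) {
        e <- env[locus_no == l, , drop = FALSE]
        rows <- unlist(groups[as.character(e$group)])
        members$locus_id[rows] <<- l
        top <- rows[which.min(ind_sig$p[rows])]
        data.frame(locus_id = l, chrom = e$chrom[1],
                   start_bp = min(e$start_bp), end_bp = max(e$end_bp),
                   n_ind_sig = length(rows),
                   n_lead = sum(ind_sig$id[rows] %in%
                                ind_sig$id[lead_rows]),
                   lead_ids = paste(
                       intersect(ind_sig$id[lead_rows], ind_sig$id[rows]),
                       collapse = ","),
                   top_snp = ind_sig$id[top], top_p = ind_sig$p[top])
    })
    loci <- do.call(rbind, loci)
    rownames(loci) <- NULL
    list(loci = loci, members = members)
}

#' Nearest gene to a position
#'
#' Distance is 0 when the position falls inside a gene span, otherwise the
#' minimum gap to either boundary. Ties are broken by smaller gene start,
#' then lexicographic gene id. Returns label `"none"` when the chromosome
#' has no genes.
#'
#' @param chrom chromosome label.
#' @param pos 1-based position.
#' @param genes `GRanges` with mcol `gene_id`.
#' @return list with `gene` and `distance` (bp).
#' @export
nearestGene <- function(chrom, pos, genes) {
    same <- genes[as.character(GenomicRanges::seqnames(genes)) == chrom]
    if (!length(same)) return(list(gene = "none", distance = NA_real_))
    d <- pmax(GenomicRanges::start(same) - pos,
              pos - GenomicRanges::end(same), 0)
    best <- which(d == min(d))
    if (length(best) > 1) {
        st <- GenomicRanges::start(same)[best]
        best <- best[st == min(st)]
        if (length(best) > 1) {
            ids <- same$gene_id[best]
            best <- best[order(ids)][1]
        }
    }
    list(gene = same$gene_id[best[1]], distance = d[best[1]])
}

#' Annotate loci with their nearest gene
#'
#' Labels each locus by the nearest gene of its top SNP.
#'
#' @param loci the `loci` data.frame from [leadAndLoci()].
#' @param gwas the [GwasRun-class] (to locate top SNPs).
#' @param genes `GRanges` with mcol `gene_id`.
#' @return `loci` with columns `nearest_gene` and `gene_distance` appended.
#' @export
annotateLoci <- function(loci, gwas, genes) {
    if (!nrow(loci)) return(loci)
    rec <- assocRecords(gwas)
    pos <- rec$pos[match(loci$top_snp, rec$id)]
    ng <- lapply(seq_len(nrow(loci)), function(i)
        nearestGene(loci$chrom[i], pos[i], genes))
    loci$nearest_gene <- vapply(ng, `[[`, character(1), "gene")
    loci$gene_distance <- vapply(ng, `[[`, numeric(1), "distance")
    loci
}

#' Classify extremes-GWAS results against the base study
#'
#' For each variant reported by the base study, finds the lowest-p ok-status
#' extremes variant within `flank_kb` and labels the report `replicated`
#' (best p at or below `sig_p`), `not_tested` (the reported variant itself
#' failed QC, with its reason) or `not_replicated`. Extremes loci are
#' labelled `replicated` when their envelope touches a reported variant's
#' flank and `novel` otherwise; `novel_strict` lists novel loci with top p
#' at or below `strict_p`.
#'
#' @param gwas a [GwasRun-class].
#' @param reported data.frame with `chrom`, `pos`, `id` of base-study hits.
#' @param loci optional `loci` table from [leadAndLoci()].
#' @param flank_kb flank half-width around each reported variant.
#' @param sig_p genome-wide threshold for replication.
#' @param strict_p threshold for the strict novel list.
#' @return list: `reported`, `loci` (with `class` column), `novel_strict`.
#' @export
compareWithBase <- function(gwas, reported, loci = NULL, flank_kb = 500,
                            sig_p = 5e-8, strict_p = 1e-15) {
    rec <- assocRecords(gwas)
    if (!any(reported$chrom %in% rec$chrom))
        stop("no reported variant shares a chromosome with the GWAS; ",
             "likely a genome build mismatch")
    flank <- flank_kb * 1000
    rows <- lapply(seq_len(nrow(reported)), function(i) {
        ch <- reported$chrom[i]; po <- reported$pos[i]
        win <- which(rec$chrom == ch & abs(rec$pos - po) <= flank)
        okw <- win[rec$status[win] == "ok" & !is.na(rec$p[win])]
        best_id <- NA_character_; best_p <- NA_real_
        if (length(okw)) {
            b <- okw[which.min(rec$p[okw])]
            best_id <- rec$id[b]; best_p <- rec$p[b]
        }
        here <- win[rec$pos[win] == po]
        status <- if (!is.na(best_p) && best_p <= sig_p) "replicated"
            else if (length(here) &&
                     all(startsWith(rec$status[here], "filtered_")))
                paste0("not_tested(",
                       sub("filtered_", "", rec$status[here[1]]), ")")
            else "not_replicated"
        data.frame(id = reported$id[i], chrom = ch, pos = po,
                   best_id = best_id, best_p = best_p, status = status)
    })
    rep_tab <- do.call(rbind, rows)
    loci_tab <- NULL; novel <- NULL
    if (!is.null(loci) && nrow(loci)) {
        loci_tab <- loci
        loci_tab$class <- vapply(seq_len(nrow(loci)), function(i) {
            hit <- any(reported$chrom == loci$chrom[i] &
                       reported$pos >= loci$start_bp[i] - flank &
                       reported$pos <= loci$end_bp[i] + flank)
            if (hit) "replicated" else "novel"
        }, character(1))
        novel <- loci_tab[loci_tab$class == "novel" &
                          loci_tab$top_p <= strict_p, , drop = FALSE]
    }
    list(reported = rep_tab, loci = loci_tab, novel_strict = novel)
}
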