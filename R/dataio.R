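## Readers/writers for the standard formats the pipeline touches (VCF 4.2,
## dosage TSV, summary-stat TSV, BED, GMT, JSON manifest) and allele
## harmonization between summary statistics and cohort genotypes.
## Coordinates are 1-based inclusive everywhere except BED interchange,
## converted at the boundary by rtracklayer.

#' Read cohort genotypes from VCF or dosage TSV
#'
#' VCF (4.2) input uses the `DS` FORMAT field when present and otherwise
#' converts `GT` to a dosage of the ALT allele; the counted effect allele
#' `a1` is ALT and `a2` is REF. Dosage TSV input has columns
#' `chrom, pos, id, a1, a2` followed by one column per sample. Missing
#' genotypes become `NA` (never a sentinel inside \[0,2\]).
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @param keep_samples optional sample subset; every id must be present.
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_tsv"),
                          keep_samples = NULL) {
    format <- match.arg(format)
    stopifnot(file.exists(path))
    if (format == "vcf") {
        vcf <- VariantAnnotation::readVcf(path)
        gt <- VariantAnnotation::geno(vcf)$GT
        dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
        dos[gt %in% c("0/0", "0|0")] <- 0
        dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
        dos[gt %in% c("1/1", "1|1")] <- 2
        if ("DS" %in% names(VariantAnnotation::geno(vcf))) {
            ds <- VariantAnnotation::geno(vcf)$DS
            use <- !is.na(ds)
            dos[use] <- ds[use]  # DS takes precedence over GT
        }
        rr <- SummarizedExperiment::rowRanges(vcf)
        gr <- GenomicRanges::GRanges(
            as.character(GenomicRanges::seqnames(rr)),
            IRanges::IRanges(GenomicRanges::start(rr), width = 1),
            id = names(rr),
            a1 = as.character(unlist(rr$ALT)),
            a2 = as.character(rr$REF))
        samples <- colnames(gt)
    } else {
        tb <- data.table::fread(path, sep = "\t", header = TRUE,
                                data.table = FALSE)
        need <- c("chrom", "pos", "id", "a1", "a2")
        if (!all(need %in% colnames(tb)))
            stop("dosage TSV must have columns ", paste(need, collapse = ", "))
        bad <- which(is.na(tb$chrom) | tb$chrom == "")
        if (length(bad))
            stop("unknown chromosome token at line ", bad[1] + 1L)
        samples <- setdiff(colnames(tb), need)
        dos <- as.matrix(tb[, samples, drop = FALSE])
        gr <- GenomicRanges::GRanges(
            as.character(tb$chrom), IRanges::IRanges(tb$pos, width = 1),
            id = tb$id, a1 = tb$a1, a2 = tb$a2)
    }
    if (!is.null(keep_samples)) {
        missing <- setdiff(keep_samples, samples)
        if (length(missing))
            stop("samples in keep-list absent from file: ",
                 paste(missing, collapse = ", "))
        dos <- dos[, keep_samples, drop = FALSE]
        samples <- keep_samples
    }
    GenotypeMatrix(dos, gr, samples)
}

#' Write genotypes as VCF (GT + DS) or dosage TSV
#'
#' The VCF writer emits `GT` from rounded dosages and carries the exact
#' dosage in `DS`, so a write/read round trip is lossless up to numeric
#' formatting.
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(G, path, format = c("vcf", "dosage_tsv")) {
    format <- match.arg(format)
    gr <- variantInfo(G)
    mc <- S4Vectors::mcols(gr)
    D <- dosages(G)
    if (format == "vcf") {
        hdr <- c("##fileformat=VCFv4.2",
                 paste0("##source=extremescan (build ",
                        S4Vectors::metadata(G)$build, ")"),
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", sampleIDs(G)),
                       collapse = "\t"))
        gt_of <- function(d) {
            r <- round(d)
            out <- rep("./.", length(d))
            out[!is.na(r) & r == 0] <- "0/0"
            out[!is.na(r) & r == 1] <- "0/1"
            out[!is.na(r) & r >= 2] <- "1/1"
            out
        }
        body <- vapply(seq_len(nrow(D)), function(i) {
            d <- D[i, ]
            ds <- ifelse(is.na(d), ".", formatC(d, format = "g", digits = 8))
            paste(c(as.character(GenomicRanges::seqnames(gr))[i],
                    GenomicRanges::start(gr)[i], mc$id[i], mc$a2[i],
                    mc$a1[i], ".", "PASS", ".", "GT:DS",
                    paste0(gt_of(d), ":", ds)), collapse = "\t")
        }, character(1))
        writeLines(c(hdr, body), path)
    } else {
        tb <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         pos = GenomicRanges::start(gr),
                         id = mc$id, a1 = mc$a1, a2 = mc$a2,
                         check.names = FALSE)
        tb <- cbind(tb, as.data.frame(D))
        utils::write.table(tb, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read base-GWAS summary statistics from TSV
#'
#' Mandatory columns (possibly via `column_map`): chrom, pos, effect and
#' other allele, beta or OR, and p. An OR column is converted to
#' `beta = log(OR)`. Rows with unparseable mandatory numerics are dropped
#' with a message; `p = 0` is clamped to the smallest positive double and
#' flagged.
#'
#' @param path TSV file with a header.
#' @param column_map optional named character vector mapping standard names
#'   (`chrom`, `pos`, `id`, `effect_allele`, `other_allele`, `beta`, `or`,
#'   `se`, `p`, `freq`, `n`) to file column names.
#' @return A [SummaryStats-class].
#' @export
readSumstats <- function(path, column_map = NULL) {
    stopifnot(file.exists(path))
    tb <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
    pick <- function(std, candidates) {
        if (!is.null(column_map) && std %in% names(column_map))
            return(if (column_map[[std]] %in% colnames(tb))
                       column_map[[std]] else NA_character_)
        hit <- candidates[candidates %in% colnames(tb)]
        if (length(hit)) hit[1] else NA_character_
    }
    cols <- c(chrom = pick("chrom", c("chrom", "CHR", "chr")),
              pos = pick("pos", c("pos", "POS", "BP", "bp")),
              id = pick("id", c("id", "SNP", "rsid", "ID")),
              effect_allele = pick("effect_allele",
                                   c("effect_allele", "A1", "EA")),
              other_allele = pick("other_allele",
                                  c("other_allele", "A2", "OA")),
              beta = pick("beta", c("beta", "BETA", "b")),
              or = pick("or", c("or", "OR")),
              se = pick("se", c("se", "SE")),
              p = pick("p", c("p", "P", "pval", "p_value")),
              freq = pick("freq", c("freq", "FRQ", "EAF")),
              n = pick("n", c("n", "N")))
    mandatory <- c("chrom", "pos", "effect_allele", "other_allele", "p")
    if (any(is.na(cols[mandatory])))
        stop("cannot resolve mandatory columns: ",
             paste(mandatory[is.na(cols[mandatory])], collapse = ", "))
    if (is.na(cols["beta"]) && is.na(cols["or"]))
        stop("neither a beta nor an OR column could be resolved")
    num <- function(v) suppressWarnings(as.numeric(v))
    beta <- if (!is.na(cols["beta"])) num(tb[[cols["beta"]]])
            else log(num(tb[[cols["or"]]]))
    p <- num(tb[[cols["p"]]])
    pos <- num(tb[[cols["pos"]]])
    keep <- !is.na(beta) & !is.na(p) & !is.na(pos)
    if (any(!keep))
        message("readSumstats: dropped ", sum(!keep),
                " rows with unparseable numerics")
    clamped <- keep & p == 0
    if (any(clamped)) {
        message("readSumstats: clamped ", sum(clamped),
                " zero p-values to ", .Machine$double.xmin)
        p[clamped] <- .Machine$double.xmin
    }
    grab <- function(col, default = NA) {
        if (is.na(cols[col])) rep(default, nrow(tb)) else tb[[cols[col]]]
    }
    out <- data.frame(
        chrom = as.character(tb[[cols["chrom"]]]),
        pos = as.integer(pos),
        id = as.character(grab("id", NA_character_)),
        effect_allele = toupper(as.character(tb[[cols["effect_allele"]]])),
        other_allele = toupper(as.character(tb[[cols["other_allele"]]])),
        beta = beta, se = num(grab("se")), p = p,
        freq = num(grab("freq")), n = num(grab("n")),
        flagged = clamped)[keep, , drop = FALSE]
    if (all(is.na(out$id)))
        out$id <- paste0(out$chrom, ":", out$pos)
    SummaryStats(out)
}

#' Write summary statistics as TSV
#'
#' @param ss a [SummaryStats-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(ss, path) {
    utils::write.table(statsTable(ss), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.isAmbiguous <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize summary-statistic alleles to a genotype cohort
#'
#' Variants are matched on (chrom, pos) — never on rsid. When the
#' summary-stat effect/other alleles equal the cohort (a2, a1), the match is
#' kept with `sign_flip = TRUE` (the effect refers to the opposite allele);
#' allele mismatches are dropped, strand-ambiguous A/T and C/G pairs are
#' dropped by default, and duplicated positions are dropped on both sides.
#' No strand flipping is ever attempted.
#'
#' @param ss a [SummaryStats-class].
#' @param G a [GenotypeMatrix-class].
#' @param drop_ambiguous drop A/T and C/G pairs (default `TRUE`).
#' @return list of class `HarmonizedPair`: `ss_idx`, `g_idx`, `sign_flip`
#'   (parallel vectors) and `dropped` (data.frame ss_idx, id, reason with
#'   reason in allele_mismatch / ambiguous_strand / duplicate /
#'   missing_in_cohort).
#' @export
harmonizeAlleles <- function(ss, G, drop_ambiguous = TRUE) {
    tb <- statsTable(ss)
    stopifnot(nrow(tb) > 0, nVariants(G) > 0)
    gr <- variantInfo(G)
    mc <- S4Vectors::mcols(gr)
    key_ss <- paste0(tb$chrom, ":", tb$pos)
    key_g <- paste0(as.character(GenomicRanges::seqnames(gr)), ":",
                    GenomicRanges::start(gr))
    dup_ss <- key_ss %in% key_ss[duplicated(key_ss)]
    dup_g <- key_ss %in% key_g[duplicated(key_g)]
    gi <- match(key_ss, key_g)
    reason <- rep(NA_character_, nrow(tb))
    reason[is.na(gi)] <- "missing_in_cohort"
    reason[dup_ss | dup_g] <- "duplicate"
    cand <- which(is.na(reason))
    ea <- toupper(tb$effect_allele[cand]); oa <- toupper(tb$other_allele[cand])
    a1 <- toupper(mc$a1[gi[cand]]); a2 <- toupper(mc$a2[gi[cand]])
    straight <- ea == a1 & oa == a2
    flipped <- ea == a2 & oa == a1
    amb <- .isAmbiguous(ea, oa)
    r <- rep(NA_character_, length(cand))
    r[!(straight | flipped)] <- "allele_mismatch"
    if (drop_ambiguous) r[amb] <- "ambiguous_strand"
    reason[cand] <- r
    keep <- which(is.na(reason))
    if (!length(keep))
        stop("zero variants matched after harmonization; ",
             "likely a genome build mismatch")
    structure(list(
        ss_idx = keep,
        g_idx = gi[keep],
        sign_flip = (toupper(tb$effect_allele[keep]) ==
                     toupper(mc$a2[gi[keep]])),
        dropped = data.frame(ss_idx = which(!is.na(reason)),
                             id = tb$id[!is.na(reason)],
                             reason = reason[!is.na(reason)])),
        class = "HarmonizedPair")
}

#' Write stage outputs plus a JSON run manifest
#'
#' Every table becomes `<name>.tsv` in `out_dir`; `manifest.json` records the
#' configuration hash, seed, and per-table row counts. No timestamps are
#' written, so identical runs produce byte-identical output.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param overwrite allow clobbering existing files.
#' @param seed,config recorded in the manifest (config is hashed, not stored).
#' @return the manifest list, invisibly.
#' @export
writeResults <- function(tables, out_dir, overwrite = FALSE,
                         seed = NULL, config = NULL) {
    stopifnot(is.list(tables), !is.null(names(tables)))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, paste0(names(tables), ".tsv"))
    hit <- file.exists(paths)
    if (any(hit) && !overwrite)
        stop("output exists (use overwrite = TRUE): ",
             paste(basename(paths[hit]), collapse = ", "))
    for (i in seq_along(tables))
        utils::write.table(tables[[i]], paths[i], sep = "\t",
                           quote = FALSE, row.names = FALSE)
    tmp <- tempfile()
    saveRDS(config, tmp, version = 2)
    manifest <- list(
        config_hash = unname(tools::md5sum(tmp)),
        seed = seed,
        tables = stats::setNames(
            lapply(tables, function(t) list(rows = nrow(t))),
            names(tables)))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

#' Read / write gene annotations as BED
#'
#' BED is 0-based half-open on disk; in memory genes are 1-based inclusive
#' `GRanges` with an mcol `gene_id`. Conversion happens at the boundary
#' (rtracklayer).
#'
#' @param path BED file.
#' @return `readGeneBed`: a `GRanges` with mcol `gene_id`.
#' @export
readGeneBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(gr)),
        IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
        gene_id = gr$name)
    out
}

#' @rdname readGeneBed
#' @param genes `GRanges` with mcol `gene_id`.
#' @export
writeGeneBed <- function(genes, path) {
    out <- genes
    out$name <- genes$gene_id
    out$gene_id <- NULL
    rtracklayer::export(out, path, format = "BED")
    invisible(path)
}

#' Read / write gene-set catalogs as GMT
#'
#' @param path GMT file.
#' @return `readGmt`: named list of gene-id vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' @rdname readGmt
#' @param sets named list of gene-id vectors.
#' @export
writeGmt <- function(sets, path) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    writeLines(vapply(names(sets), function(nm)
        paste(c(nm, "na", sets[[nm]]), collapse = "\t"),
        character(1)), path)
    invisible(path)
}
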