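## End-to-end orchestration: harmonize -> PRS-stage QC -> clump -> score ->
## extremes -> GWAS-stage QC -> GWAS + lambda -> loci -> base comparison ->
## optional enrichment / LDSC / PheWAS, with the dual with/without-region
## design and a JSON run manifest.

#' Assemble and validate a pipeline configuration
#'
#' Either `simulate` describes a synthetic study (and all inputs are
#' generated under `seed`), or file paths supply the genotypes and base
#' summary statistics. The two QC parameter sets are deliberately separate:
#' score construction and the extremes GWAS use different filters.
#'
#' @param simulate optional list: `n_samples`, `n_blocks`, `block_size`,
#'   `rho`, `n_causal`, `h2`, `prevalence`, `n_base`, and optionally
#'   `trait_specs` (see [simulateTraitTable()]).
#' @param genotypes,genotype_format,sumstats,covariates,genes_bed,sets_gmt
#'   input file paths for non-simulate mode.
#' @param keep_samples optional pre-filtered sample keep-list.
#' @param clump a [clumpParams()].
#' @param qc_prs score-stage [qcParams()] (default [qcParamsPRS()]).
#' @param qc_gwas GWAS-stage [qcParams()].
#' @param tail_q extreme-tail fraction.
#' @param locus a [locusParams()].
#' @param apoe_mode `"include"`, `"exclude"` or `"both"`: whether scoring
#'   (and the phenome scan) is repeated with the dominant-locus region
#'   excluded.
#' @param exclude_region list(chrom, start, end) for the exclusion runs; in
#'   simulate mode it defaults to 1 Mb around the largest-effect causal
#'   variant.
#' @param do_enrich,do_ldsc,do_phewas stage toggles.
#' @param seed global seed, expanded per stage via [childSeed()].
#' @param out_dir output directory (optional; no files written when `NULL`).
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simulate = NULL, genotypes = NULL,
                           genotype_format = "vcf", sumstats = NULL,
                           covariates = NULL, genes_bed = NULL,
                           sets_gmt = NULL, keep_samples = NULL,
                           clump = clumpParams(), qc_prs = qcParamsPRS(),
                           qc_gwas = qcParams(), tail_q = 0.05,
                           locus = locusParams(),
                           apoe_mode = c("include", "exclude", "both"),
                           exclude_region = NULL,
                           do_enrich = TRUE, do_ldsc = TRUE,
                           do_phewas = TRUE, seed = 1L, out_dir = NULL) {
    apoe_mode <- match.arg(apoe_mode)
    if (is.null(simulate)) {
        for (f in c(genotypes, sumstats))
            if (!is.null(f) && !file.exists(f))
                stop("input file does not exist: ", f)
        if (is.null(genotypes) || is.null(sumstats))
            stop("non-simulate mode needs genotypes and sumstats paths")
    } else {
        defaults <- list(n_samples = 2000L, n_blocks = 100L,
                         block_size = 50L, rho = 0.8, n_causal = 50L,
                         h2 = 0.5, prevalence = 0.1, n_base = 100000L,
                         trait_specs = NULL)
        simulate <- utils::modifyList(defaults, simulate)
    }
    .assertAll(tail_q = tail_q > 0 && tail_q < 0.5)
    structure(list(simulate = simulate, genotypes = genotypes,
                   genotype_format = genotype_format, sumstats = sumstats,
                   covariates = covariates, genes_bed = genes_bed,
                   sets_gmt = sets_gmt, keep_samples = keep_samples,
                   clump = clump, qc_prs = qc_prs, qc_gwas = qc_gwas,
                   tail_q = tail_q, locus = locus, apoe_mode = apoe_mode,
                   exclude_region = exclude_region, do_enrich = do_enrich,
                   do_ldsc = do_ldsc, do_phewas = do_phewas,
                   seed = as.integer(seed), out_dir = out_dir),
              class = "PipelineConfig")
}

.stage <- function(name, counts, expr) {
    res <- tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    message("[", name, "] ",
            paste(names(counts), unlist(counts), sep = "=",
                  collapse = " "))
    res
}

#' Run the extremes design end to end
#'
#' Executes harmonize, score-stage QC, clumping, scoring, extreme
#' assignment, GWAS-stage QC, the extremes GWAS with genomic inflation,
#' locus definition, base comparison, and the optional enrichment, LDSC and
#' phenome-scan stages. With `apoe_mode = "both"`, scoring, assignment and
#' the phenome scan are repeated with the exclusion region removed and the
#' paired outputs are kept side by side. The manifest records every
#' parameter, per-stage counts, and the seed; with an `out_dir`, all tables
#' and the manifest are written via [writeResults()].
#'
#' @param config a [pipelineConfig()].
#' @return list with the stage outputs (`genotypes`, `sumstats`, `groups`,
#'   `gwas`, `loci`, `comparison`, `enrichment`, `ldsc`, `phewas`,
#'   `noregion` for the exclusion run) and `manifest`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    seed <- config$seed
    counts <- list()
    out <- list()

    if (!is.null(config$simulate)) {
        sm <- config$simulate
        blocks <- lapply(seq_len(sm$n_blocks), function(b)
            ldBlockSpec(sm$block_size, sm$rho, chrom = "1"))
        G <- .stage("simulate", list(), simulateLDGenotypes(
            blocks, sm$n_samples, childSeed(seed, "cohort")))
        arch <- architectureSpec(sm$n_causal, sm$h2, sm$prevalence,
                                 seed = childSeed(seed, "arch"))
        phen <- simulateLiabilityPhenotype(G, arch)
        ss <- simulateBaseSumstats(G, arch, sm$n_base,
                                   childSeed(seed, "base"))
        covariates <- phen$covariates
        genes_sets <- simulateAnnotation(
            "1", 1, max(GenomicRanges::start(variantInfo(G))) + 1e4,
            n_genes = max(20L, sm$n_blocks), n_sets = 25L,
            enriched_positions = {
                pos <- GenomicRanges::start(variantInfo(G))
                pos[phen$causal$idx]
            }, seed = childSeed(seed, "annotation"))
        genes <- genes_sets$genes; sets <- genes_sets$sets
        out$truth <- phen
    } else {
        G <- .stage("read_genotypes", list(), readGenotypes(
            config$genotypes, config$genotype_format,
            config$keep_samples))
        ss <- readSumstats(config$sumstats)
        covariates <- if (!is.null(config$covariates))
            data.table::fread(config$covariates, data.table = FALSE)
            else NULL
        genes <- if (!is.null(config$genes_bed))
            readGeneBed(config$genes_bed) else NULL
        sets <- if (!is.null(config$sets_gmt))
            readGmt(config$sets_gmt) else NULL
    }
    out$genotypes <- G; out$sumstats <- ss
    counts$n_samples <- nSamples(G); counts$n_variants <- nVariants(G)

    harm <- .stage("harmonize", list(matched = 0),
                   harmonizeAlleles(ss, G))
    counts$n_harmonized <- length(harm$ss_idx)

    prs_qc <- .stage("prs_qc", list(), qcFilter(G, params = config$qc_prs))
    pass_g <- prs_qc$idx[prs_qc$keep]
    harm_keep <- harm$g_idx %in% pass_g
    counts$n_prs_qc_pass <- sum(harm_keep)

    ss_cand <- ss[harm$ss_idx[harm_keep]]
    retained_cand <- .stage("clump", list(), clumpVariants(
        ss_cand, G, config$clump))
    ## back to original ss row indices
    retained <- harm$ss_idx[harm_keep][retained_cand]
    counts$n_clumped <- length(retained)

    weights <- prsWeights(harm, ss, retained)
    region <- config$exclude_region
    if (is.null(region) && !is.null(config$simulate)) {
        ## dominant locus: the LD block holding the largest causal effect
        top <- out$truth$causal$idx[which.max(abs(
            out$truth$causal$beta_std))]
        gr <- variantInfo(G)
        blk <- S4Vectors::mcols(gr)$block
        inblk <- which(blk == blk[top])
        region <- list(chrom = as.character(GenomicRanges::seqnames(
            gr))[top], start = min(GenomicRanges::start(gr)[inblk]),
            end = max(GenomicRanges::start(gr)[inblk]))
    }
    scoreAndAssign <- function(w) {
        prs <- scorePRS(G, w)
        list(prs = prs, groups = assignExtremes(prs, config$tail_q))
    }
    run_incl <- if (config$apoe_mode != "exclude") scoreAndAssign(weights)
                else NULL
    run_excl <- NULL
    if (config$apoe_mode != "include") {
        w2 <- excludeRegion(weights, region$chrom, region$start,
                            region$end)
        run_excl <- scoreAndAssign(w2)
    }
    main <- if (is.null(run_incl)) run_excl else run_incl
    out$prs <- main$prs; out$groups <- main$groups
    counts$k_per_tail <- tailCount(main$groups)
    .stage("extremes", list(k = counts$k_per_tail), TRUE)

    gwas <- .stage("gwas", list(), runGwas(G, main$groups, covariates,
                                           config$qc_gwas))
    out$gwas <- gwas
    rec <- assocRecords(gwas)
    counts$n_tested <- sum(rec$status == "ok")
    counts$lambda_gc <- round(lambdaGC(gwas), 4)

    ind_sig <- independentSignificant(gwas, G, config$locus)
    ll <- leadAndLoci(ind_sig, gwas, G, config$locus)
    if (!is.null(genes) && nrow(ll$loci))
        ll$loci <- annotateLoci(ll$loci, gwas, genes)
    out$loci <- ll
    counts$n_loci <- if (nrow(ll$loci)) nrow(ll$loci) else 0L
    .stage("loci", list(n = counts$n_loci), TRUE)

    base_tb <- statsTable(ss)
    base_sig <- base_tb[!is.na(base_tb$p) &
                        base_tb$p <= config$locus$sig_p, , drop = FALSE]
    if (nrow(base_sig))
        out$comparison <- .stage("compare", list(n = nrow(base_sig)),
            compareWithBase(gwas, base_sig, ll$loci,
                            sig_p = config$locus$sig_p))

    if (config$do_enrich && !is.null(genes) && !is.null(sets)) {
        sig_snps <- rec[rec$status == "ok" & !is.na(rec$p) &
                        rec$p <= config$locus$sig_p, c("chrom", "pos")]
        mapped <- mapGenesPositional(sig_snps, genes)
        if (length(mapped) >= 2)
            out$enrichment <- .stage("enrich", list(genes = length(mapped)),
                hypergeomEnrichment(mapped, sets, genes$gene_id))
    }

    if (config$do_ldsc) {
        ok <- rec$status == "ok"
        panel_idx <- .matchPanel(rec[ok, ], G)
        Gsub <- G[panel_idx, ]
        ld <- .stage("ld_scores", list(m = sum(ok)),
                     ldScores(Gsub, window_kb = 200))
        z_ex <- rec$beta[ok] / rec$se[ok]
        n_ex <- 2 * tailCount(main$groups)
        bsub <- base_tb[match(rec$id[ok], base_tb$id), , drop = FALSE]
        z_base <- bsub$beta / bsub$se
        n_base <- stats::median(bsub$n, na.rm = TRUE)
        out$ldsc <- .stage("ldsc", list(), list(
            h2_extremes = h2Regression(z_ex^2, n_ex, ld),
            rg_vs_base = rgRegression(z_ex, z_base, n_ex, n_base, ld)))
    }

    if (config$do_phewas) {
        traits <- if (!is.null(config$simulate)) {
            specs <- config$simulate$trait_specs
            if (is.null(specs))
                specs <- data.frame(
                    id = c("t_cont", "t_bin", "t_null"),
                    type = c("continuous", "binary", "continuous"),
                    effect = c(0.8, 1.0, 0))
            simulateTraitTable(main$groups, specs,
                               seed = childSeed(seed, "traits"))
        } else NULL
        if (!is.null(traits)) {
            out$phewas <- .stage("phewas", list(n = nrow(traitManifest(
                traits))), phewasScan(main$groups, traits, covariates,
                                      min_category = 50))
            if (!is.null(run_excl)) {
                tr2 <- simulateTraitTable(run_excl$groups,
                    traitManifest(traits),
                    seed = childSeed(seed, "traits"))
                out$phewas_noregion <- phewasScan(
                    run_excl$groups, tr2, covariates, min_category = 50)
            }
        }
    }
    if (!is.null(run_incl) && !is.null(run_excl)) {
        d <- length(union(setdiff(highSamples(run_incl$groups),
                                  highSamples(run_excl$groups)),
                          setdiff(highSamples(run_excl$groups),
                                  highSamples(run_incl$groups))))
        counts$high_group_symmdiff <- d
        out$groups_noregion <- run_excl$groups
    }

    manifest <- list(seed = seed, apoe_mode = config$apoe_mode,
                     tail_q = config$tail_q,
                     clump = unclass(config$clump),
                     qc_prs = unclass(config$qc_prs),
                     qc_gwas = unclass(config$qc_gwas),
                     locus = unclass(config$locus),
                     counts = counts)
    out$manifest <- manifest
    if (!is.null(config$out_dir)) {
        tabs <- list(gwas = rec)
        if (counts$n_loci > 0) tabs$loci <- ll$loci
        if (!is.null(out$phewas)) tabs$phewas <- out$phewas
        if (!is.null(out$enrichment))
            tabs$enrichment <- as.data.frame(out$enrichment)
        gl <- groupLabels(main$groups)
        tabs$groups <- data.frame(sample_id = names(gl),
                                  label = as.character(gl))
        writeResults(tabs, config$out_dir, overwrite = TRUE,
                     seed = seed, config = manifest)
    }
    out
}
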