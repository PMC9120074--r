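## Synthetic cohorts with known ground truth: block-LD genotypes via a
## latent-Gaussian AR(1) threshold model, liability-threshold disease status,
## analytically simulated external ("base") summary statistics, gene
## annotations/sets, and mixed-type trait tables.

#' Specify one LD block of the synthetic genome
#'
#' Haplotypes within a block are generated by thresholding a latent Gaussian
#' AR(1) process (correlation `rho^|i-j|` between variants i and j) at each
#' variant's allele-frequency quantile; blocks are mutually independent. This
#' latent model is used because the true haplotype correlation is available
#' in closed form for oracle tests.
#'
#' @param n_variants variants in the block (>= 1).
#' @param rho latent AR(1) correlation, in \[0, 1).
#' @param freq_range allele-frequency interval for the effect allele,
#'   within (0, 0.5].
#' @param spacing_bp base pairs between adjacent variants.
#' @param block_gap_bp gap to the previous block (layout mode).
#' @param chrom chromosome label.
#' @param start_bp 1-based start; `NA` lays blocks out consecutively.
#' @return list of class `LDBlockSpec`.
#' @export
ldBlockSpec <- function(n_variants, rho, freq_range = c(0.05, 0.5),
                        spacing_bp = 1000L, block_gap_bp = 10000L,
                        chrom = "1", start_bp = NA_integer_) {
    .assertAll(
        n_variants = n_variants >= 1,
        rho = rho >= 0 && rho < 1,
        freq_range = length(freq_range) == 2 && freq_range[1] > 0 &&
            freq_range[2] <= 0.5 && freq_range[1] <= freq_range[2],
        spacing_bp = spacing_bp >= 1)
    structure(list(n_variants = as.integer(n_variants), rho = rho,
                   freq_range = freq_range, spacing_bp = as.integer(spacing_bp),
                   block_gap_bp = as.integer(block_gap_bp),
                   chrom = as.character(chrom),
                   start_bp = as.integer(start_bp)),
              class = "LDBlockSpec")
}

#' Specify a polygenic liability-threshold architecture
#'
#' Disease status arises when a standard-normal liability — the sum of a
#' polygenic genetic component with variance `h2_liability` and an
#' independent Gaussian residual — exceeds the threshold matching the
#' population `prevalence`.
#'
#' @param n_causal number of causal variants.
#' @param h2_liability liability-scale heritability in \[0, 1\].
#' @param prevalence disease prevalence in (0, 1).
#' @param effect_dist_sd scale of the raw (pre-standardisation) causal
#'   effect distribution.
#' @param seed integer seed; expanded to per-stage child seeds via
#'   [childSeed()].
#' @return list of class `ArchitectureSpec`.
#' @export
architectureSpec <- function(n_causal, h2_liability, prevalence = 0.1,
                             effect_dist_sd = 1, seed = 1L) {
    .assertAll(
        n_causal = n_causal >= 0,
        h2_liability = h2_liability >= 0 && h2_liability <= 1,
        prevalence = prevalence > 0 && prevalence < 1)
    structure(list(n_causal = as.integer(n_causal),
                   h2_liability = h2_liability, prevalence = prevalence,
                   effect_dist_sd = effect_dist_sd, seed = as.integer(seed)),
              class = "ArchitectureSpec")
}

## non-strand-ambiguous allele pairs, cycled over variants
.ALLELE_PAIRS <- matrix(c("A","G", "A","C", "T","G", "T","C",
                          "G","A", "C","A", "G","T", "C","T"),
                        ncol = 2, byrow = TRUE)

#' Simulate block-LD dosage genotypes
#'
#' Two haplotypes per sample are drawn independently; within a block each
#' haplotype thresholds a latent AR(1) Gaussian at `qnorm(freq)`, so the
#' effect-allele frequency is exact in expectation and the latent LD decays
#' as `rho^|i-j|`.
#'
#' @param blocks a single [ldBlockSpec()] or a list of them.
#' @param n_samples number of diploid samples (>= 2).
#' @param seed integer seed (bit-reproducible output).
#' @return A [GenotypeMatrix-class]; `rowRanges()` mcols carry `true_freq`,
#'   `block` and `rho` ground truth.
#' @examples
#' G <- simulateLDGenotypes(ldBlockSpec(10, 0.8), n_samples = 50, seed = 1)
#' dim(dosages(G))
#' @export
simulateLDGenotypes <- function(blocks, n_samples, seed) {
    if (inherits(blocks, "LDBlockSpec")) blocks <- list(blocks)
    stopifnot(n_samples >= 2, length(blocks) >= 1)
    set.seed(childSeed(seed, "genotypes"))
    chrom <- character(0); pos <- integer(0)
    freq <- numeric(0); block_id <- integer(0); rho_all <- numeric(0)
    dos <- vector("list", length(blocks))
    last_pos <- list()  # per chromosome
    for (b in seq_along(blocks)) {
        bl <- blocks[[b]]
        m <- bl$n_variants
        f <- stats::runif(m, bl$freq_range[1], bl$freq_range[2])
        prev <- last_pos[[bl$chrom]]
        start <- if (!is.na(bl$start_bp)) bl$start_bp
                 else if (is.null(prev)) 1L
                 else prev + bl$block_gap_bp
        p <- start + (seq_len(m) - 1L) * bl$spacing_bp
        if (!is.null(prev) && p[1] <= prev)
            stop("configuration error: non-increasing positions on chromosome ",
                 bl$chrom, " at block ", b)
        last_pos[[bl$chrom]] <- p[m]
        ## two haplotypes, each latent AR(1) across variants
        d <- matrix(0L, n_samples, m)
        thr <- stats::qnorm(f)
        for (h in 1:2) {
            z <- stats::rnorm(n_samples)
            d[, 1] <- d[, 1] + (z < thr[1])
            if (m > 1) for (j in 2:m) {
                z <- bl$rho * z + sqrt(1 - bl$rho^2) * stats::rnorm(n_samples)
                d[, j] <- d[, j] + (z < thr[j])
            }
        }
        dos[[b]] <- t(d)
        chrom <- c(chrom, rep(bl$chrom, m)); pos <- c(pos, p)
        freq <- c(freq, f); block_id <- c(block_id, rep(b, m))
        rho_all <- c(rho_all, rep(bl$rho, m))
    }
    n_var <- length(pos)
    pair <- .ALLELE_PAIRS[(seq_len(n_var) - 1L) %% nrow(.ALLELE_PAIRS) + 1L, ,
                          drop = FALSE]
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(pos, width = 1),
        id = sprintf("snp_%s_%d", chrom, pos),
        a1 = pair[, 1], a2 = pair[, 2],
        true_freq = freq, block = block_id, rho = rho_all)
    GenotypeMatrix(do.call(rbind, dos), gr,
                   sprintf("sample_%06d", seq_len(n_samples)))
}

## Draw the causal set and standardized effects for an architecture, scaled so
## the realized genetic variance in G equals h2 exactly. Seeded only by the
## architecture seed, so panel and cohort built on matched variant grids share
## the same causal model.
.drawArchitecture <- function(G, arch) {
    stopifnot(inherits(arch, "ArchitectureSpec"),
              arch$n_causal <= nVariants(G))
    set.seed(childSeed(arch$seed, "architecture"))
    D <- dosages(G)
    poly <- which(apply(D, 1, stats::sd, na.rm = TRUE) > 0)
    if (arch$n_causal > length(poly))
        stop("fewer polymorphic variants than n_causal")
    idx <- sort(sample(poly, arch$n_causal))
    beta <- stats::rnorm(arch$n_causal, 0, arch$effect_dist_sd)
    g <- rep(0, nSamples(G))
    if (arch$n_causal > 0 && arch$h2_liability > 0) {
        Z <- scale(t(D[idx, , drop = FALSE]))
        g_raw <- as.vector(Z %*% beta)
        s <- stats::sd(g_raw)
        beta <- beta * sqrt(arch$h2_liability) / s
        g <- g_raw * sqrt(arch$h2_liability) / s
    } else beta <- beta * 0
    list(idx = idx, beta_std = beta, genetic = g)
}

#' Simulate a liability-threshold phenotype plus covariates
#'
#' Liability is the scaled genetic score of the causal set plus independent
#' Gaussian noise (total variance 1); status is liability above
#' `qnorm(1 - prevalence)`. Covariates mirror a biobank analysis: sex, year
#' of birth, a deprivation index, genotyping batch, and ten principal
#' components computed from the realized genotype matrix (so covariate
#' adjustment is meaningful, not decorative).
#'
#' @param G a [GenotypeMatrix-class] cohort.
#' @param arch an [architectureSpec()].
#' @return list with `phenotype` (sample_id, liability, status),
#'   `covariates` (sex, yob, townsend, batch, PC1..PC10) and `causal`
#'   (variant index, id, standardized beta) data.frames.
#' @export
simulateLiabilityPhenotype <- function(G, arch) {
    stopifnot(inherits(arch, "ArchitectureSpec"))
    drawn <- .drawArchitecture(G, arch)
    set.seed(childSeed(arch$seed, "phenotype"))
    n <- nSamples(G)
    liab <- drawn$genetic +
        stats::rnorm(n, 0, sqrt(1 - arch$h2_liability))
    status <- as.integer(liab > stats::qnorm(1 - arch$prevalence))
    pcs <- genotypePCs(G, n_pcs = 10)
    cov <- data.frame(
        sample_id = sampleIDs(G),
        sex = stats::rbinom(n, 1, 0.5),
        yob = sample(1938:1970, n, replace = TRUE),
        townsend = stats::rnorm(n),
        batch = factor(sample(paste0("b", 1:5), n, replace = TRUE)))
    cov <- cbind(cov, as.data.frame(pcs))
    ids <- S4Vectors::mcols(variantInfo(G))$id
    list(phenotype = data.frame(sample_id = sampleIDs(G),
                                liability = liab, status = status),
         covariates = cov,
         causal = data.frame(idx = drawn$idx, id = ids[drawn$idx],
                             beta_std = drawn$beta_std))
}

#' Principal components of a genotype matrix
#'
#' Top principal components of the standardized dosage matrix, computed from
#' an evenly spaced variant subset (eigendecomposition of the variant-side
#' covariance, cheap at cohort scale).
#'
#' @param G a [GenotypeMatrix-class].
#' @param n_pcs number of components.
#' @param max_variants variant subset size used for the decomposition.
#' @return numeric matrix n_samples x n_pcs, columns PC1..PCk.
#' @export
genotypePCs <- function(G, n_pcs = 10, max_variants = 500) {
    D <- dosages(G)
    keep <- which(apply(D, 1, stats::sd, na.rm = TRUE) > 0)
    sub <- keep[unique(round(seq(1, length(keep),
                                 length.out = min(max_variants,
                                                  length(keep)))))]
    Z <- scale(t(D[sub, , drop = FALSE]))
    Z[is.na(Z)] <- 0
    C <- crossprod(Z) / (nrow(Z) - 1)
    ev <- eigen(C, symmetric = TRUE)
    k <- min(n_pcs, ncol(Z))
    pcs <- Z %*% ev$vectors[, seq_len(k), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(k))
    rownames(pcs) <- colnames(D)
    pcs
}

#' Simulate base-study summary statistics analytically
#'
#' Emulates an external GWAS of size `n_base` on the same variant grid
#' without simulating its genotypes: each variant's true marginal effect is
#' the LD-weighted sum of causal effects (`sum_k r_jk beta_k`, correlations
#' taken from `G_panel` within LD blocks, which are independent by
#' construction), the reported estimate adds Gaussian noise with
#' `SE = 1/sqrt(n_base * 2 f (1-f))`, and p is the two-sided Wald test.
#' Cost is O(variants x block width) rather than O(n_base).
#'
#' @param G_panel LD/frequency reference panel ([GenotypeMatrix-class]).
#' @param arch the shared [architectureSpec()].
#' @param n_base external cohort size (>= 100).
#' @param seed noise seed.
#' @param noise set `FALSE` for the infinite-sample limit (no estimation
#'   noise; SE still reflects `n_base`).
#' @return A [SummaryStats-class]; monomorphic variants carry `NA`
#'   statistics and `flagged = TRUE`.
#' @export
simulateBaseSumstats <- function(G_panel, arch, n_base, seed,
                                 noise = TRUE) {
    stopifnot(n_base >= 100)
    drawn <- .drawArchitecture(G_panel, arch)
    set.seed(childSeed(seed, "base_sumstats"))
    D <- dosages(G_panel)
    gr <- variantInfo(G_panel)
    mc <- S4Vectors::mcols(gr)
    m <- nVariants(G_panel)
    f <- rowMeans(D, na.rm = TRUE) / 2
    mono <- f <= 0 | f >= 1 | apply(D, 1, stats::sd, na.rm = TRUE) == 0
    ## marginal standardized effects via within-block LD with the causal set
    marg <- rep(0, m)
    if (length(drawn$idx)) {
        blk <- mc$block
        if (is.null(blk)) blk <- rep(1L, m)
        causal_by_block <- split(seq_along(drawn$idx), blk[drawn$idx])
        for (b in names(causal_by_block)) {
            jb <- which(blk == as.integer(b) & !mono)
            ci <- causal_by_block[[b]]
            if (!length(jb) || !length(ci)) next
            R <- suppressWarnings(stats::cor(
                t(D[jb, , drop = FALSE]),
                t(D[drawn$idx[ci], , drop = FALSE]),
                use = "pairwise.complete.obs"))
            R[is.na(R)] <- 0
            marg[jb] <- as.vector(R %*% drawn$beta_std[ci])
        }
    }
    sdj <- sqrt(2 * f * (1 - f))
    se <- ifelse(mono, NA_real_, 1 / sqrt(n_base * 2 * f * (1 - f)))
    beta_true <- ifelse(mono, NA_real_, marg / sdj)
    beta_hat <- beta_true +
        if (noise) stats::rnorm(m) * se else 0
    z <- beta_hat / se
    p <- 2 * stats::pnorm(-abs(z))
    p[!is.na(p) & p == 0] <- .Machine$double.xmin
    SummaryStats(data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = GenomicRanges::start(gr), id = mc$id,
        effect_allele = mc$a1, other_allele = mc$a2,
        beta = beta_hat, se = se, p = p,
        freq = ifelse(mono, NA_real_, f), n = n_base,
        flagged = mono))
}

#' Simulate a mixed-type trait table against group membership
#'
#' Traits are generated for the assigned (low/high) samples only; declared
#' effects act on the high-vs-low indicator on each model's natural scale:
#' additive for continuous, log-odds for binary, proportional-odds latent
#' shift for ordered (4 levels), and log-odds of one level for unordered
#' (3 levels). Missingness is injected completely at random per trait.
#'
#' @param groups an [ExtremeGroups-class] assignment.
#' @param trait_specs data.frame with columns `id`, `type`
#'   (continuous/binary/ordered/unordered), `effect`, and optionally
#'   `missing` (per-trait missingness rate).
#' @param missingness default missingness rate for specs without their own.
#' @param seed integer seed.
#' @return A [TraitTable-class]; the manifest keeps the generating truth.
#' @export
simulateTraitTable <- function(groups, trait_specs, missingness = 0,
                               seed = 1L) {
    stopifnot(is.data.frame(trait_specs),
              all(c("id", "type", "effect") %in% colnames(trait_specs)))
    if (!all(trait_specs$type %in%
             c("continuous", "binary", "ordered", "unordered")))
        stop("unknown trait type in specs")
    keep <- groupLabels(groups) != "unassigned"
    if (!any(keep)) stop("no assigned samples in groups")
    ids <- groups@sample_id[keep]
    ind <- as.integer(groups@label[keep] == "high")
    n <- length(ids)
    if (is.null(trait_specs$missing)) trait_specs$missing <- missingness
    trait_specs$missing[is.na(trait_specs$missing)] <- missingness
    set.seed(childSeed(seed, "traits"))
    vals <- data.frame(sample_id = ids)
    for (i in seq_len(nrow(trait_specs))) {
        eff <- trait_specs$effect[i]
        y <- switch(trait_specs$type[i],
            continuous = eff * ind + stats::rnorm(n),
            binary = stats::rbinom(n, 1, stats::plogis(
                stats::qlogis(0.3) + eff * ind)),
            ordered = {
                lat <- eff * ind + stats::rlogis(n)
                cutp <- stats::qlogis(c(0.25, 0.5, 0.75))
                factor(paste0("L", findInterval(lat, cutp) + 1L),
                       levels = paste0("L", 1:4), ordered = TRUE)
            },
            unordered = {
                lo <- eff * ind
                pr <- cbind(1, exp(lo), 1)
                pr <- pr / rowSums(pr)
                lv <- c("A", "B", "C")
                factor(vapply(seq_len(n), function(s)
                    sample(lv, 1, prob = pr[s, ]), character(1)),
                    levels = lv)
            })
        mr <- trait_specs$missing[i]
        if (mr > 0) y[stats::runif(n) < mr] <- NA
        vals[[trait_specs$id[i]]] <- y
    }
    new("TraitTable", values = vals,
        manifest = trait_specs[, c("id", "type", "effect", "missing")])
}

#' Simulate a gene annotation and gene-set catalog
#'
#' Genes are tiled over the span with equal gaps (never overlapping); random
#' sets are drawn from them, and an optional designated "enriched" set is
#' seeded with the genes nearest the supplied positions (e.g. true causal
#' loci), so downstream enrichment has a known positive.
#'
#' @param chrom chromosome label.
#' @param span_start,span_end 1-based span to tile.
#' @param n_genes number of genes (>= 2).
#' @param n_sets number of random sets in the catalog.
#' @param enriched_positions optional vector of positions whose nearest genes
#'   seed the set named `"enriched"`.
#' @param seed integer seed.
#' @return list with `genes` (a `GRanges` with mcol `gene_id`) and `sets`
#'   (named list of gene-id vectors, GMT-writable).
#' @export
simulateAnnotation <- function(chrom, span_start, span_end, n_genes,
                               n_sets, enriched_positions = NULL,
                               seed = 1L) {
    stopifnot(n_genes >= 2, span_end > span_start)
    span <- span_end - span_start + 1
    len <- floor(span / (2 * n_genes))
    if (len < 100)
        stop("span too small for ", n_genes, " genes")
    starts <- span_start + (seq_len(n_genes) - 1L) * 2L * len
    genes <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(starts, width = len),
        gene_id = sprintf("gene_%04d", seq_len(n_genes)))
    set.seed(childSeed(seed, "annotation"))
    gid <- genes$gene_id
    sets <- lapply(seq_len(n_sets), function(s)
        sort(sample(gid, sample(3:max(3, n_genes %/% 4), 1))))
    names(sets) <- sprintf("set_%03d", seq_len(n_sets))
    if (!is.null(enriched_positions)) {
        hit <- vapply(enriched_positions, function(p) {
            d <- pmax(starts - p, p - (starts + len - 1), 0)
            gid[which.min(d)]
        }, character(1))
        sets$enriched <- sort(unique(hit))
    }
    list(genes = genes, sets = sets)
}
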