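## PHESANT-style phenome scan of extreme-group membership against a
## mixed-type trait table, with Bonferroni correction across performed tests.

#' Infer the statistical type of a trait
#'
#' Simplified typing rules: exactly 2 distinct non-missing values is binary;
#' numeric with more than `max_ordered` distinct values is continuous;
#' numeric with up to `max_ordered` distinct values is ordered categorical;
#' anything non-numeric is unordered categorical (an ordered factor input is
#' ordered by declaration). Declared manifest types always override
#' inference in [phewasScan()].
#'
#' @param values trait vector.
#' @param max_ordered distinct-value cutoff separating ordered categorical
#'   from continuous (default 20).
#' @return one of `"continuous"`, `"binary"`, `"ordered"`, `"unordered"`.
#' @export
inferTraitType <- function(values, max_ordered = 20) {
    v <- values[!is.na(values)]
    if (!length(v)) stop("all values missing")
    nd <- length(unique(v))
    if (nd < 2) stop("degenerate trait: fewer than 2 distinct values")
    if (nd == 2) return("binary")
    if (is.ordered(values)) return("ordered")
    if (is.numeric(v))
        return(if (nd > max_ordered) "continuous" else "ordered")
    "unordered"
}

## linear model with Wald t test on the first non-intercept column
.linearFit <- function(y, x, X) {
    des <- cbind(1, x, X)
    fit <- stats::lm.fit(des, y)
    n <- length(y); p <- ncol(des)
    s2 <- sum(fit$residuals^2) / (n - p)
    cov <- tryCatch(chol2inv(chol(crossprod(des))) * s2,
                    error = function(e) NULL)
    if (is.null(cov)) return(NULL)
    beta <- fit$coefficients[2]; se <- sqrt(diag(cov))[2]
    list(beta = beta, se = se,
         p = 2 * stats::pt(-abs(beta / se), df = n - p))
}

#' Phenome-wide scan of extreme-group membership
#'
#' Each trait is regressed on the high-vs-low indicator (the exposure,
#' PHESANT's direction) plus covariates, with the model chosen by trait
#' type: linear for continuous, logistic for binary, proportional odds for
#' ordered, and one-vs-rest logistic per level for unordered (the
#' minimum-p level is reported after its own within-trait Bonferroni
#' factor). Traits failing the missingness filter are excluded with reason
#' `missingness`; categorical levels smaller than `min_category` are
#' dropped, and traits left with fewer than two usable levels (or fewer
#' than `min_category` observations) are excluded with reason
#' `category_size`. The family-wise threshold is `alpha` divided by the
#' number of tests actually performed. Underflowing p-values are clamped to
#' 1e-150 in the signed `-log10` plotting column only.
#'
#' @param groups an [ExtremeGroups-class].
#' @param traits a [TraitTable-class].
#' @param covariates optional data.frame with `sample_id` plus columns.
#' @param min_category minimum answers per phenotype category (default 200).
#' @param max_missing maximum missing fraction (default 0.20).
#' @param alpha family-wise error target (default 0.05).
#' @return data.frame: trait, type, beta, se, ci_low, ci_high, p, n_used,
#'   status, pass_bonferroni, pass_magnitude (|beta| >= 0.5),
#'   signed_log10p. Attributes `n_tests` and `bonferroni_threshold`.
#' @export
phewasScan <- function(groups, traits, covariates = NULL,
                       min_category = 200, max_missing = 0.20,
                       alpha = 0.05) {
    lab <- groupLabels(groups)
    ids <- names(lab)[lab != "unassigned"]
    ind <- as.integer(lab[ids] == "high")
    if (length(unique(ind)) < 2) stop("group indicator is constant")
    vals <- traitValues(traits)
    stopifnot(all(ids %in% vals$sample_id))
    vals <- vals[match(ids, vals$sample_id), , drop = FALSE]
    man <- traitManifest(traits)
    X <- NULL
    if (!is.null(covariates)) {
        cv <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
        cv$sample_id <- NULL
        X <- stats::model.matrix(~ ., data = cv)[, -1, drop = FALSE]
    }
    scanOne <- function(tid) {
        y <- vals[[tid]]
        rec <- data.frame(trait = tid, type = NA_character_,
                          beta = NA_real_, se = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, n_used = 0L, status = "tested")
        if (mean(is.na(y)) > max_missing) {
            rec$status <- "excluded(missingness)"
            return(rec)
        }
        type <- man$type[match(tid, man$id)]
        if (is.na(type))
            type <- tryCatch(inferTraitType(y),
                             error = function(e) NA_character_)
        if (is.na(type)) {
            rec$status <- "excluded(degenerate)"
            return(rec)
        }
        if (type == "ordered" && !is.ordered(y) && !is.numeric(y))
            y <- factor(y, ordered = TRUE)
        rec$type <- type
        keep <- !is.na(y) & !is.na(ind)
        if (!is.null(X)) keep <- keep & !apply(is.na(X), 1, any)
        yv <- y[keep]; iv <- ind[keep]
        Xv <- if (is.null(X)) NULL else X[keep, , drop = FALSE]
        fit <- NULL
        if (type == "continuous") {
            if (length(yv) < min_category) {
                rec$status <- "excluded(category_size)"
                return(rec)
            }
            fit <- .linearFit(as.numeric(yv), iv, Xv)
        } else if (type == "binary") {
            yb <- as.integer(factor(yv)) - 1L
            if (min(table(yb)) < min_category) {
                rec$status <- "excluded(category_size)"
                return(rec)
            }
            r <- tryCatch(logisticAssoc(iv, yb, Xv),
                          error = function(e) NULL)
            if (!is.null(r) && r$status == "ok")
                fit <- list(beta = r$beta, se = r$se, p = r$p)
        } else {
            yf <- factor(yv)
            tab <- table(yf)
            small <- names(tab)[tab < min_category]
            if (length(small)) {
                drop <- yf %in% small
                yf <- droplevels(yf[!drop]); iv <- iv[!drop]
                if (!is.null(Xv)) Xv <- Xv[!drop, , drop = FALSE]
            }
            if (nlevels(yf) < 2 || length(unique(iv)) < 2) {
                rec$status <- "excluded(category_size)"
                return(rec)
            }
            if (type == "ordered" && nlevels(yf) > 2) {
                df <- data.frame(y = factor(yf, ordered = TRUE), ind = iv)
                if (!is.null(Xv)) df <- cbind(df, as.data.frame(Xv))
                pfit <- tryCatch(
                    MASS::polr(y ~ ., data = df, Hess = TRUE),
                    error = function(e) NULL)
                if (!is.null(pfit)) {
                    beta <- pfit$coefficients["ind"]
                    se <- tryCatch(sqrt(diag(stats::vcov(pfit))["ind"]),
                                   error = function(e) NA_real_)
                    if (is.finite(se))
                        fit <- list(beta = unname(beta), se = unname(se),
                                    p = 2 * stats::pnorm(
                                        -abs(beta / se)))
                }
            } else {
                ## unordered (or a 2-level leftover): one-vs-rest logistic,
                ## minimum p with a within-trait Bonferroni factor
                lv <- levels(yf)
                L <- if (nlevels(yf) == 2) 1L else nlevels(yf)
                cand <- lapply(lv[seq_len(max(L, 1))], function(l) {
                    r <- tryCatch(
                        logisticAssoc(iv, as.integer(yf == l), Xv),
                        error = function(e) NULL)
                    if (!is.null(r) && r$status == "ok") r else NULL
                })
                cand <- Filter(Negate(is.null), cand)
                if (length(cand)) {
                    ps <- vapply(cand, function(r) r$p, numeric(1))
                    b <- cand[[which.min(ps)]]
                    fit <- list(beta = b$beta, se = b$se,
                                p = min(1, min(ps) * L))
                }
            }
        }
        if (is.null(fit) || !is.finite(fit$p)) {
            rec$status <- "excluded(degenerate)"
            return(rec)
        }
        rec$beta <- fit$beta; rec$se <- fit$se
        rec$ci_low <- fit$beta - 1.96 * fit$se
        rec$ci_high <- fit$beta + 1.96 * fit$se
        rec$p <- fit$p
        rec$n_used <- length(yv)
        rec
    }
    res <- do.call(rbind, lapply(man$id, scanOne))
    n_tests <- sum(res$status == "tested")
    thr <- if (n_tests) bonferroniThreshold(alpha, n_tests) else NA_real_
    res$pass_bonferroni <- res$status == "tested" & !is.na(res$p) &
        res$p <= thr
    res$pass_magnitude <- !is.na(res$beta) & abs(res$beta) >= 0.5
    res$signed_log10p <- ifelse(is.na(res$p), NA_real_,
                                sign(ifelse(is.na(res$beta), 1, res$beta)) *
                                -log10(pmax(res$p, 1e-150)))
    attr(res, "n_tests") <- n_tests
    attr(res, "bonferroni_threshold") <- thr
    res
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error target.
#' @param n_tests number of tests actually performed (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroniThreshold(0.05, 1424)  # 3.511236e-05
#' @export
bonferroniThreshold <- function(alpha, n_tests) {
    if (any(n_tests < 1)) stop("n_tests must be >= 1")
    alpha / n_tests
}
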