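# Independent brute-force oracles. Each re-derives the expected result by a
# different route than the package implementation (recurrences vs closed
# forms, all-pairs scans vs windowed algorithms, full greedy transcriptions
# on explicit r2 matrices).

# HWE exact test via the Wigginton-style probability recurrence (the package
# uses the closed-form multinomial enumeration).
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if ((mid %% 2) != (rare %% 2)) mid <- mid + 1L
  hets <- seq(rare %% 2L, rare, by = 2L)
  prob <- numeric(length(hets))
  at <- function(h) (h - hets[1]) / 2 + 1
  prob[at(mid)] <- 1
  h <- mid
  while (h >= 2) {
    prob[at(h - 2)] <- prob[at(h)] * h * (h - 1) /
      ((rare - h + 2) * (2 * n - rare - h + 2))
    h <- h - 2
  }
  h <- mid
  while (h <= rare - 2) {
    prob[at(h + 2)] <- prob[at(h)] * (rare - h) * (2 * n - rare - h) /
      ((h + 2) * (h + 1))
    h <- h + 2
  }
  prob <- prob / sum(prob)
  obs <- prob[at(nAa)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# Greedy clumping transcribed directly onto an explicit r2 matrix.
oracle_clump <- function(p, chrom, pos, r2, p_threshold, clump_r2,
                         clump_kb, clump_p = 1) {
  cand <- which(!is.na(p) & p < clump_p)
  cand <- cand[order(p[cand], chrom[cand], pos[cand])]
  clumped <- rep(FALSE, length(p))
  kept <- integer(0)
  for (v in cand) {
    if (clumped[v]) next
    kept <- c(kept, v)
    for (u in cand) {
      if (u == v || clumped[u] || u %in% kept) next
      same <- chrom[u] == chrom[v] &&
        abs(pos[u] - pos[v]) <= clump_kb * 1000
      r2uv <- r2[u, v]
      if (is.na(r2uv)) r2uv <- 0
      if (same && r2uv >= clump_r2) clumped[u] <- TRUE
    }
  }
  sort(kept[p[kept] < p_threshold])
}

# FUMA-style locus construction on explicit r2: two greedy clump tiers,
# candidate envelopes (r2 >= r2_ind with any member, within 1 Mb), merge.
oracle_loci <- function(p, chrom, pos, r2, params) {
  sig <- which(!is.na(p) & p <= params$sig_p)
  ind <- oracle_clump(p, chrom, pos, r2, p_threshold = 1,
                      clump_r2 = params$r2_independent, clump_kb = Inf,
                      clump_p = 1)
  ind <- intersect(ind, sig)
  # restrict first clump to significant SNPs only
  psig <- ifelse(seq_along(p) %in% sig, p, NA)
  ind <- oracle_clump(psig, chrom, pos, r2, 1, params$r2_independent, Inf)
  if (!length(ind)) return(list(n_loci = 0L, membership = integer(0)))
  # second tier among independent significant SNPs
  pind <- ifelse(seq_along(p) %in% ind, p, NA)
  leads <- oracle_clump(pind, chrom, pos, r2, 1, params$r2_lead, Inf)
  # assign each ind-sig SNP to the lead that would clump it first
  lead_of <- sapply(ind, function(v) {
    if (v %in% leads) return(v)
    cands <- leads[chrom[leads] == chrom[v]]
    cands <- cands[sapply(cands, function(l) {
      r <- r2[l, v]; !is.na(r) && r >= params$r2_lead
    })]
    cands[order(p[cands])][1]
  })
  groups <- split(ind, lead_of)
  cand <- which(!is.na(p) & p <= params$cand_p)
  env <- t(sapply(groups, function(g) {
    members <- g
    lo <- min(pos[members]); hi <- max(pos[members])
    near <- cand[chrom[cand] == chrom[members[1]] &
                 pos[cand] >= lo - 1e6 & pos[cand] <= hi + 1e6]
    inb <- near[sapply(near, function(u)
      any(sapply(members, function(m) {
        r <- r2[u, m]; !is.na(r) && r >= params$r2_independent
      })))]
    if (length(inb)) c(min(lo, pos[inb]), max(hi, pos[inb]))
    else c(lo, hi)
  }))
  ch <- sapply(groups, function(g) chrom[g[1]])
  o <- order(ch, env[, 1])
  env <- env[o, , drop = FALSE]; ch <- ch[o]; groups <- groups[o]
  locus <- integer(nrow(env))
  cur <- 0; cur_end <- -Inf; cur_ch <- ""
  for (i in seq_len(nrow(env))) {
    if (ch[i] != cur_ch || env[i, 1] - cur_end > params$merge_kb * 1000) {
      cur <- cur + 1; cur_ch <- ch[i]; cur_end <- env[i, 2]
    } else cur_end <- max(cur_end, env[i, 2])
    locus[i] <- cur
  }
  membership <- integer(0)
  for (i in seq_along(groups))
    membership[as.character(groups[[i]])] <- locus[i]
  list(n_loci = max(locus), membership = membership)
}

# BH step-up by hand (the package delegates to p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Hypergeometric upper tail by explicit summation.
oracle_hyper <- function(ov, K, N, n) {
  ks <- ov:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Nearest gene by exhaustive scan with the stated tie rules.
oracle_nearest <- function(chrom, pos, gchrom, gstart, gend, gid) {
  same <- which(gchrom == chrom)
  if (!length(same)) return("none")
  d <- sapply(same, function(i) {
    if (pos >= gstart[i] && pos <= gend[i]) 0
    else min(abs(pos - gstart[i]), abs(pos - gend[i]))
  })
  best <- same[d == min(d)]
  best <- best[gstart[best] == min(gstart[best])]
  gid[best[order(gid[best])][1]]
}

# True dosage-scale LD of the latent-Gaussian AR(1) threshold model:
# P(both haplotypes carry) from the bivariate normal orthant, by 1-D
# numerical integration.
oracle_threshold_r2 <- function(f1, f2, rho_latent) {
  t1 <- qnorm(f1); t2 <- qnorm(f2)
  p11 <- integrate(function(z)
    pnorm((t2 - rho_latent * z) / sqrt(1 - rho_latent^2)) * dnorm(z),
    -Inf, t1, rel.tol = 1e-10)$value
  r_hap <- (p11 - f1 * f2) / sqrt(f1 * (1 - f1) * f2 * (1 - f2))
  r_hap^2  # dosage correlation equals haplotype correlation (sum of 2 iid)
}

# Pairwise r2 matrix of a GenotypeMatrix, straightforwardly.
full_r2 <- function(G) {
  r <- suppressWarnings(cor(t(dosages(G)), use = "pairwise.complete.obs"))
  r^2
}
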