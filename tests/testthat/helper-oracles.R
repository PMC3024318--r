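# Independent oracles used to cross-check the package's statistics.  These
# deliberately use different code paths (direct factorial enumeration,
# stats:: reference implementations, brute-force likelihood grids) from the
# implementations they verify.

# HWE exact test by direct enumeration: conditional probability of each
# feasible heterozygote count given the allele counts, from log-factorials.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  hets <- seq(na %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    haa <- (na - h) / 2
    hbb <- (nb - h) / 2
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Pearson chi-square via stats::chisq.test (no continuity correction)
oracle_chi2 <- function(tab) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# Woolf logit CI recomputed longhand
oracle_or_ci <- function(a, b, c, d) {
  or_ <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or_ = or_, ci = exp(log(or_) + c(-1, 1) * 1.959963984540054 * se))
}

# One-parameter likelihood grid for the 2-SNP EM: with both allele
# frequencies fixed at their genotype-count MLEs, profile the multinomial
# likelihood of the unphased two-locus table over the AB-haplotype frequency.
oracle_two_snp_hap_freq <- function(g1, g2, grid_n = 20001) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = grid_n)
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  ll <- vapply(grid, function(pAB) {
    f <- c(AB = pAB, Ab = pA - pAB, aB = pB - pAB,
           ab = 1 - pA - pB + pAB)
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 0)
    s <- 0
    for (gi in 0:2) for (gj in 0:2) {
      n <- tab[gi + 1, gj + 1]
      if (n == 0) next
      pr <- 0
      for (x1 in 0:1) for (y1 in 0:1) {
        x2 <- gi - x1; y2 <- gj - y1
        if (x2 < 0 || x2 > 1 || y2 < 0 || y2 > 1) next
        h <- function(x, y) if (x == 1 && y == 1) f["AB"] else
          if (x == 1) f["Ab"] else if (y == 1) f["aB"] else f["ab"]
        pr <- pr + h(x1, y1) * h(x2, y2)
      }
      s <- s + n * log(max(pr, 1e-300))
    }
    s
  }, 0)
  grid[which.max(ll)]
}

# small deterministic panel built directly from a genotype matrix
make_panel <- function(calls, pos = NULL, chrom = "6") {
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq(1e6, by = 1e4, length.out = m)
  snps <- data.frame(snp_id = sprintf("s%04d", seq_len(m)), chrom = chrom,
                     pos = pos, allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  genotype_panel(snps, calls)
}

make_phen <- function(panel, n_case) {
  ids <- rownames(panel$calls)
  n <- length(ids)
  phenotype_table(ids, rep(c("case", "control"), c(n_case, n - n_case)),
                  age = rep(50, n),
                  sex = rep(c("male", "female"), length.out = n))
}
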