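# --- internal EM machinery over an unphased multilocus window -------------
#
# Haplotypes over k biallelic SNPs are coded as integers 1..2^k; bit j set
# means the haplotype carries allele_a of the j-th window SNP.  Individuals
# with any missing call inside the window are dropped from that window's EM.

hap_strings <- function(panel, snp_ids) {
  k <- length(snp_ids)
  idx <- vapply(snp_ids, function(s) snp_index(panel, s), 0L)
  codes <- 0:(2^k - 1)
  sapply(codes, function(cd) {
    bits <- bitwAnd(bitwShiftR(cd, 0:(k - 1)), 1L)
    paste(ifelse(bits == 1L, panel$snps$allele_a[idx],
                 panel$snps$allele_b[idx]), collapse = "")
  })
}

# ordered diplotype expansions compatible with one genotype vector g in
# {0,1,2}^k -> two-column matrix of 1-based haplotype indices
compatible_pairs <- function(g) {
  k <- length(g)
  het <- which(g == 1L)
  base <- sum((g == 2L) * 2^(seq_len(k) - 1))
  if (!length(het)) return(cbind(base + 1L, base + 1L))
  combos <- as.matrix(expand.grid(rep(list(c(0L, 1L)), length(het))))
  h1 <- base + as.vector(combos %*% 2^(het - 1))
  h2 <- base + as.vector((1L - combos) %*% 2^(het - 1))
  cbind(h1 + 1L, h2 + 1L)
}

# Fit the EM on a window.  Returns haplotype frequencies, the log-likelihood
# trace, and per-individual expected haplotype counts (rows sum to 2).
window_em <- function(panel, snp_ids, max_iter = 1000, tol = 1e-6) {
  stopifnot(length(snp_ids) >= 2, length(snp_ids) <= 8)
  idx <- vapply(snp_ids, function(s) snp_index(panel, s), 0L)
  G <- panel$calls[, idx, drop = FALSE]
  keep <- !apply(is.na(G), 1, any)
  if (!any(keep)) stop("window has no complete genotypes")
  G <- G[keep, , drop = FALSE]
  key <- apply(G, 1, paste, collapse = "")
  pat <- !duplicated(key)
  pat_of <- match(key, key[pat])
  cnt <- tabulate(pat_of, nbins = sum(pat))
  pairs <- lapply(which(pat), function(i) compatible_pairs(G[i, ]))
  n_hap <- 2^length(snp_ids)
  used <- sort(unique(unlist(pairs)))
  f <- numeric(n_hap)
  f[used] <- 1 / length(used)
  n <- nrow(G)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    counts <- numeric(n_hap)
    ll <- 0
    post <- vector("list", length(pairs))
    for (t in seq_along(pairs)) {
      pr <- pairs[[t]]
      w <- f[pr[, 1]] * f[pr[, 2]]
      s <- sum(w)
      ll <- ll + cnt[t] * log(s)
      pw <- w / s
      post[[t]] <- pw
      inc <- cnt[t] * pw
      counts[pr[, 1]] <- counts[pr[, 1]] + inc
      counts[pr[, 2]] <- counts[pr[, 2]] + inc
    }
    f_new <- counts / (2 * n)
    ll_trace <- c(ll_trace, ll)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  # expected haplotype counts per individual at the converged frequencies
  D <- matrix(0, n, n_hap)
  for (t in seq_along(pairs)) {
    pr <- pairs[[t]]
    w <- f[pr[, 1]] * f[pr[, 2]]
    pw <- w / sum(w)
    rows <- which(pat_of == t)
    for (p in seq_len(nrow(pr))) {
      D[rows, pr[p, 1]] <- D[rows, pr[p, 1]] + pw[p]
      D[rows, pr[p, 2]] <- D[rows, pr[p, 2]] + pw[p]
    }
  }
  list(snp_ids = snp_ids, freq = f, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, dosage = D, keep = keep,
       n_used = n, converged = delta < tol)
}

#' EM haplotype-frequency estimation over an unphased SNP window
#'
#' Classical EM over multilocus genotypes: the E-step weights each compatible
#' diplotype by the product of current haplotype frequencies, the M-step
#' re-estimates frequencies from the expected haplotype counts.  The EM runs
#' on the pooled sample; case/control frequencies come from the posterior
#' diplotype weights within each stratum.  Initialisation is uniform over the
#' compatible haplotypes, which makes the fit deterministic for windows of up
#' to 8 SNPs; `seed` is accepted for interface uniformity but unused.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`, or `NULL` for pooled-only output
#' @param snp_ids ordered window of 2-8 SNP ids
#' @param max_iter iteration cap (default 1000)
#' @param tol convergence threshold on the max frequency change (default 1e-6)
#' @param seed unused; present so every stochastic-capable op shares one
#'   signature
#' @return object of class `haplotype_freqs`: `snp_ids`, `haplotypes` (allele
#'   strings), `freq_all`, `freq_cases`, `freq_controls`, `loglik`,
#'   `loglik_trace`, `n_used`
#' @export
em_haplotypes <- function(panel, phen = NULL, snp_ids, max_iter = 1000,
                          tol = 1e-6, seed = NULL) {
  fit <- window_em(panel, snp_ids, max_iter, tol)
  haps <- hap_strings(panel, snp_ids)
  keep_haps <- fit$freq > 0 | colSums(fit$dosage) > 0
  fc <- fn <- rep(NA_real_, length(haps))
  if (!is.null(phen)) {
    masks <- status_masks(panel, phen)
    ca <- masks$case[fit$keep]
    fc <- colSums(fit$dosage[ca, , drop = FALSE]) / (2 * sum(ca))
    fn <- colSums(fit$dosage[!ca, , drop = FALSE]) / (2 * sum(!ca))
  }
  structure(list(snp_ids = snp_ids, haplotypes = haps[keep_haps],
                 freq_all = fit$freq[keep_haps],
                 freq_cases = fc[keep_haps], freq_controls = fn[keep_haps],
                 loglik = fit$loglik, loglik_trace = fit$loglik_trace,
                 n_used = fit$n_used, converged = fit$converged),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, ...) {
  cat("haplotype_freqs over", paste(x$snp_ids, collapse = ","),
      "(n =", x$n_used, ")\n")
  ord <- order(-x$freq_all)
  for (i in ord[x$freq_all[ord] > 1e-4])
    cat(sprintf("  %s  %.4f\n", x$haplotypes[i], x$freq_all[i]))
  invisible(x)
}

# two-locus genotype log-likelihood given haplotype freqs c(pAB,pAb,paB,pab)
# on the 3x3 genotype count table (rows snp_i code, cols snp_j code)
two_locus_loglik <- function(tab9, hf) {
  ll <- 0
  for (gi in 0:2) for (gj in 0:2) {
    n <- tab9[gi + 1, gj + 1]
    if (n == 0) next
    # genotype prob = sum over compatible ordered hap pairs / includes both
    # phases of the double het
    p <- 0
    for (x1 in 0:1) for (y1 in 0:1) {
      x2 <- gi - x1; y2 <- gj - y1
      if (x2 < 0 || x2 > 1 || y2 < 0 || y2 > 1) next
      h1 <- 1 + x1 * 2 + y1  # order: ab,aB,Ab,AB with x high bit
      h2 <- 1 + x2 * 2 + y2
      p <- p + hf[h1] * hf[h2]
    }
    ll <- ll + n * log(max(p, 1e-300))
  }
  ll
}

hf_from_d <- function(pA, pB, D) {
  c(ab = (1 - pA) * (1 - pB) + D, aB = (1 - pA) * pB - D,
    Ab = pA * (1 - pB) - D, AB = pA * pB + D)
}

#' Pairwise linkage disequilibrium
#'
#' D', r-squared and a D' confidence interval for one SNP pair.  Two-locus
#' haplotype frequencies come from the window EM; the CI profiles the
#' unphased two-locus likelihood over a 101-point D' grid at the MLE allele
#' frequencies, normalises it to a distribution, and reports its 5th and 95th
#' percentiles (the confidence-bound construction used by
#' confidence-interval block-finding).
#'
#' @param panel a `genotype_panel`
#' @param snp_i,snp_j SNP ids; both must be polymorphic
#' @return one-row data.frame: `snp_i`, `snp_j`, `d_prime`, `r2`, `ci_low`,
#'   `ci_high`
#' @export
ld_pair <- function(panel, snp_i, snp_j) {
  for (s in c(snp_i, snp_j)) {
    g <- panel$calls[, snp_index(panel, s)]
    g <- g[!is.na(g)]
    if (!length(g) || all(g == 0L) || all(g == 2L))
      stop("LD undefined: ", s, " is monomorphic")
  }
  fit <- window_em(panel, c(snp_i, snp_j))
  # window hap coding: bit1 = snp_i allele_a, bit2 = snp_j allele_a
  f <- fit$freq
  pAB <- f[4]; pAb <- f[2]; paB <- f[3]
  pA <- pAB + pAb
  pB <- pAB + paB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("LD undefined: monomorphic haplotype frequencies")
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (dmax > 0) abs(D) / dmax else 0
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))

  idx <- c(snp_index(panel, snp_i), snp_index(panel, snp_j))
  G <- panel$calls[, idx, drop = FALSE]
  G <- G[stats::complete.cases(G), , drop = FALSE]
  tab9 <- matrix(0, 3, 3)
  for (r in seq_len(nrow(G))) tab9[G[r, 1] + 1, G[r, 2] + 1] <-
      tab9[G[r, 1] + 1, G[r, 2] + 1] + 1
  grid <- seq(0, 1, length.out = 101)
  sgn <- if (D >= 0) 1 else -1
  ll <- vapply(grid, function(dp) {
    Dg <- sgn * dp * dmax
    hf <- hf_from_d(pA, pB, Dg)
    if (any(hf < -1e-12)) return(-Inf)
    two_locus_loglik(tab9, pmax(hf, 0))
  }, 0)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cw <- cumsum(w)
  ci_low <- grid[which(cw >= 0.05)[1]]
  ci_high <- grid[which(cw >= 0.95)[1]]
  data.frame(snp_i = snp_i, snp_j = snp_j, d_prime = d_prime, r2 = r2,
             ci_low = ci_low, ci_high = ci_high, stringsAsFactors = FALSE)
}

#' Confidence-interval haplotype blocks
#'
#' Gabriel-style block finding: a pair is in "strong LD" when its D' CI is at
#' least (0.70, 0.98) and shows "strong recombination" when the upper bound
#' is below 0.90.  A contiguous span is a block when its outermost pair is in
#' strong LD and at least 95% of its informative pairs (strong LD or strong
#' recombination) are strong LD; a two-SNP span needs its single pair in
#' strong LD.  Candidate spans are accepted longest-first (bp), without
#' overlap.
#'
#' @param panel a `genotype_panel`
#' @param snp_ids ordered region SNPs (default: whole panel)
#' @param ci_strong_low,ci_strong_high,ci_recomb_high classification cut-offs
#' @param min_strong_frac informative-pair fraction (default 0.95)
#' @return data.frame of blocks: `start_snp`, `end_snp`, `n_snps`, `snp_ids`
#'   (comma-joined)
#' @export
gabriel_blocks <- function(panel, snp_ids = panel$snps$snp_id,
                           ci_strong_low = 0.70, ci_strong_high = 0.98,
                           ci_recomb_high = 0.90, min_strong_frac = 0.95) {
  m <- length(snp_ids)
  if (m < 2) return(empty_blocks())
  cls <- matrix(NA_character_, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    ld <- tryCatch(ld_pair(panel, snp_ids[i], snp_ids[j]),
                   error = function(e) NULL)
    cls[i, j] <- if (is.null(ld)) "uninformative"
    else if (ld$ci_low >= ci_strong_low && ld$ci_high >= ci_strong_high)
      "strong_ld"
    else if (ld$ci_high < ci_recomb_high) "strong_recomb"
    else "uninformative"
  }
  pos <- panel$snps$pos[match(snp_ids, panel$snps$snp_id)]
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (!identical(cls[i, j], "strong_ld")) next
    sub <- cls[i:j, i:j]
    vals <- sub[upper.tri(sub)]
    n_ld <- sum(vals == "strong_ld")
    n_inf <- n_ld + sum(vals == "strong_recomb")
    ok <- if (j - i == 1) TRUE else n_inf > 0 && n_ld / n_inf >= min_strong_frac
    if (ok) cand[[length(cand) + 1]] <- c(i, j, pos[j] - pos[i])
  }
  if (!length(cand)) return(empty_blocks())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3], cand[, 1]), , drop = FALSE]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (any(taken[i:j])) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1]] <-
      data.frame(start_snp = snp_ids[i], end_snp = snp_ids[j],
                 n_snps = j - i + 1,
                 snp_ids = paste(snp_ids[i:j], collapse = ","),
                 start_idx = i, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$start_idx), setdiff(names(out), "start_idx"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_blocks <- function() {
  data.frame(start_snp = character(0), end_snp = character(0),
             n_snps = integer(0), snp_ids = character(0),
             stringsAsFactors = FALSE)
}

# per-haplotype 2x2 chi-square from EM-expected haplotype counts; fractional
# counts are used as-is (rounded only at output, never in the statistic)
hap_chi2 <- function(d_case, d_ctrl, tot_case, tot_ctrl) {
  a <- d_case; b <- tot_case - d_case
  c <- d_ctrl; d <- tot_ctrl - d_ctrl
  n <- tot_case + tot_ctrl
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(den > 0, n * (a * d - b * c)^2 / den, 0)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

window_hap_test <- function(panel, phen, fit, haps, pool_below = 0.01) {
  masks <- status_masks(panel, phen)
  ca <- masks$case[fit$keep]
  tot_case <- 2 * sum(ca)
  tot_ctrl <- 2 * sum(!ca)
  d_case <- colSums(fit$dosage[ca, , drop = FALSE])
  d_ctrl <- colSums(fit$dosage[!ca, , drop = FALSE])
  present <- fit$freq > 1e-10
  frequent <- present & fit$freq >= pool_below
  rows <- list()
  ord <- which(frequent)[order(haps[frequent])]  # lexicographic tie-break
  for (h in ord) {
    ct <- hap_chi2(d_case[h], d_ctrl[h], tot_case, tot_ctrl)
    rows[[length(rows) + 1]] <- data.frame(
      haplotype = haps[h], freq_case = d_case[h] / tot_case,
      freq_ctrl = d_ctrl[h] / tot_ctrl, freq_all = fit$freq[h],
      chi2 = ct$chi2, p = ct$p, stringsAsFactors = FALSE)
  }
  rare <- present & !frequent
  if (any(rare)) {
    dc <- sum(d_case[rare]); dn <- sum(d_ctrl[rare])
    ct <- hap_chi2(dc, dn, tot_case, tot_ctrl)
    rows[[length(rows) + 1]] <- data.frame(
      haplotype = "rare_pooled", freq_case = dc / tot_case,
      freq_ctrl = dn / tot_ctrl, freq_all = sum(fit$freq[rare]),
      chi2 = ct$chi2, p = ct$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Sliding-window haplotype association
#'
#' For each window of `window_size` consecutive SNPs (shifting one SNP at a
#' time) the EM estimates haplotype frequencies on the pooled sample; each
#' haplotype with overall frequency at least 0.01 is tested haplotype-vs-all-
#' others against case status by a 2x2 chi-square on the EM-expected
#' haplotype counts, and rarer haplotypes are pooled into one `rare_pooled`
#' test.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param window_size SNPs per window, `>= 2` (default 3)
#' @param n_perm optional max-T permutation count (0 = skip)
#' @param seed RNG seed, required when `n_perm > 0`
#' @param pool_below pooling threshold on overall frequency (default 0.01)
#' @return data.frame: `window`, `snp_ids`, `haplotype`, `freq_case`,
#'   `freq_ctrl`, `chi2`, `p` and, with permutations, `p_perm`
#' @export
sliding_window_assoc <- function(panel, phen, window_size = 3, n_perm = 0,
                                 seed = NULL, pool_below = 0.01) {
  stopifnot(window_size >= 2)
  m <- n_snps(panel)
  if (m < window_size) stop("panel smaller than one window")
  windows <- lapply(seq_len(m - window_size + 1), function(i)
    panel$snps$snp_id[i:(i + window_size - 1)])
  fits <- lapply(windows, function(w) window_em(panel, w))
  out <- list()
  for (i in seq_along(windows)) {
    haps <- hap_strings(panel, windows[[i]])
    tt <- window_hap_test(panel, phen, fits[[i]], haps, pool_below)
    if (is.null(tt)) next
    tt <- cbind(data.frame(window = i,
                           snp_ids = paste(windows[[i]], collapse = ","),
                           stringsAsFactors = FALSE), tt)
    out[[length(out) + 1]] <- tt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (n_perm > 0) {
    if (is.null(seed)) stop("seed is required when permuting")
    res$p_perm <- hap_maxt(panel, phen, fits, res, n_perm, seed, pool_below)
  }
  res
}

#' Max-T permutation correction for haplotype tests
#'
#' Family-wise adjusted p-values over every (window, haplotype) test: labels
#' are shuffled `n_perm` times over the fixed per-individual EM haplotype
#' dosages and each observed chi-square is compared with the permutation
#' distribution of the maximum chi-square.
#'
#' @param panel,phen as in [sliding_window_assoc()]
#' @param windows list of SNP-id vectors
#' @param n_perm permutations (default 10000)
#' @param seed RNG seed (required)
#' @param pool_below pooling threshold (default 0.01)
#' @return data.frame as from [sliding_window_assoc()] plus `p_perm`
#' @export
haplotype_permutation <- function(panel, phen, windows, n_perm = 10000, seed,
                                  pool_below = 0.01) {
  if (missing(seed)) stop("seed is required")
  fits <- lapply(windows, function(w) window_em(panel, w))
  out <- list()
  for (i in seq_along(windows)) {
    haps <- hap_strings(panel, windows[[i]])
    tt <- window_hap_test(panel, phen, fits[[i]], haps, pool_below)
    tt <- cbind(data.frame(window = i,
                           snp_ids = paste(windows[[i]], collapse = ","),
                           stringsAsFactors = FALSE), tt)
    out[[i]] <- tt
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_perm <- hap_maxt(panel, phen, fits, res, n_perm, seed, pool_below)
  res
}

# shared max-T engine over per-window dosage matrices
hap_maxt <- function(panel, phen, fits, res, n_perm, seed, pool_below) {
  masks <- status_masks(panel, phen)
  ns <- n_samples(panel)
  n_case <- sum(masks$case)
  # pre-collapse each window's dosage to the tested haplotype columns
  mats <- list()
  for (i in seq_along(fits)) {
    fit <- fits[[i]]
    haps <- hap_strings(panel, fit$snp_ids)
    rws <- which(res$window == i)
    cols <- lapply(res$haplotype[rws], function(h) {
      if (h == "rare_pooled") which(fit$freq > 1e-10 & fit$freq < pool_below)
      else which(haps == h)
    })
    Dw <- sapply(cols, function(cc)
      rowSums(fit$dosage[, cc, drop = FALSE]))
    Dfull <- matrix(0, ns, length(rws))
    Dfull[fit$keep, ] <- Dw
    mats[[i]] <- list(D = Dfull, keep = fit$keep, rows = rws)
  }
  stat_for <- function(case_mask) {
    s <- numeric(nrow(res))
    for (mt in mats) {
      ca <- case_mask & mt$keep
      co <- !case_mask & mt$keep
      tc <- 2 * sum(ca); tn <- 2 * sum(co)
      dc <- colSums(mt$D[ca, , drop = FALSE])
      dn <- colSums(mt$D[co, , drop = FALSE])
      s[mt$rows] <- hap_chi2(dc, dn, tc, tn)$chi2
    }
    s
  }
  obs <- stat_for(masks$case)
  set.seed(seed)
  maxes <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- rep(FALSE, ns)
    perm[sample.int(ns, n_case)] <- TRUE
    maxes[b] <- max(stat_for(perm))
  }
  vapply(obs, function(s) (1 + sum(maxes >= s)) / (n_perm + 1), 0)
}
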