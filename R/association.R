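# Pearson chi-square on an r x c contingency table, no continuity correction.
# Degrees of freedom drop for empty rows/columns (PLINK-style).
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(chi2 = 0, df = 0L, p = 1))
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - exp)^2 / exp)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Allelic case-control association test
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table of
#' allele counts, treating each individual as two independent alleles.  The
#' odds ratio is `(case_a * ctrl_b) / (case_b * ctrl_a)` with a Woolf logit
#' 95% CI; when a cell is zero the Haldane-Anscombe 0.5 correction is applied
#' to the OR and CI and the result is flagged.
#'
#' @param case_a,case_b allele counts in cases (A = minor allele)
#' @param ctrl_a,ctrl_b allele counts in controls
#' @param snp_id optional identifier carried into the result
#' @return one-row data.frame: `snp_id`, `case_a`, `case_b`, `ctrl_a`,
#'   `ctrl_b`, `chi2`, `df`, `p`, `or_`, `ci_low`, `ci_high`, `zero_cell`
#' @export
allelic_test <- function(case_a, case_b, ctrl_a, ctrl_b, snp_id = NA) {
  tab <- matrix(c(case_a, ctrl_a, case_b, ctrl_b), 2, 2)
  if (sum(tab) <= 0) stop("empty allele table")
  ct <- pearson_chi2(tab)
  zero <- any(tab == 0)
  a <- case_a; b <- case_b; c <- ctrl_a; d <- ctrl_b
  if (zero) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or_ <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(or_) + c(-1, 1) * stats::qnorm(0.975) * se)
  data.frame(snp_id = snp_id, case_a = case_a, case_b = case_b,
             ctrl_a = ctrl_a, ctrl_b = ctrl_b, chi2 = ct$chi2, df = ct$df,
             p = ct$p, or_ = or_, ci_low = ci[1], ci_high = ci[2],
             zero_cell = zero, stringsAsFactors = FALSE)
}

#' Genotypic case-control association test
#'
#' Pearson chi-square on the 2x3 case/control-by-genotype table (df = 2;
#' reduced when a genotype column is empty).
#'
#' @param counts 2x3 matrix, rows case/control, columns hom_a/het/hom_b
#' @param snp_id optional identifier
#' @return one-row data.frame with `chi2`, `df`, `p`
#' @export
genotypic_test <- function(counts, snp_id = NA) {
  stopifnot(is.matrix(counts), nrow(counts) == 2, ncol(counts) == 3)
  if (sum(counts) <= 0) stop("empty genotype table")
  ct <- pearson_chi2(counts)
  data.frame(snp_id = snp_id, chi2 = ct$chi2, df = ct$df, p = ct$p,
             stringsAsFactors = FALSE)
}

# per-SNP case/control allele counts of (allele_a, allele_b)
allele_count_table <- function(panel, phen) {
  masks <- status_masks(panel, phen)
  count_grp <- function(mask) {
    g <- panel$calls[mask, , drop = FALSE]
    nm <- colSums(!is.na(g))
    a <- colSums(g, na.rm = TRUE)
    cbind(a = a, b = 2 * nm - a)
  }
  list(case = count_grp(masks$case), control = count_grp(masks$control))
}

#' Allelic association scan across a panel
#'
#' Runs [allelic_test()] for every SNP and appends the Bonferroni-adjusted
#' p-value (`m` = number of SNPs tested).
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @return data.frame, one row per SNP in panel order
#' @export
assoc_scan <- function(panel, phen) {
  ac <- allele_count_table(panel, phen)
  rows <- lapply(seq_len(n_snps(panel)), function(j)
    allelic_test(ac$case[j, "a"], ac$case[j, "b"],
                 ac$control[j, "a"], ac$control[j, "b"],
                 snp_id = panel$snps$snp_id[j]))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- vapply(out$p, bonferroni, 0, m = nrow(out))
  out
}

#' Covariate-adjusted logistic association for one SNP
#'
#' Maximum-likelihood logistic regression of case status on the additive
#' minor-allele dosage (0/1/2), optionally adjusted for age and sex.  Samples
#' with a missing genotype are dropped; missing covariates are an error.  The
#' Wald test on the dosage coefficient gives the p-value.  Complete
#' separation is reported through `converged = FALSE` rather than an error.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param snp_id SNP to test
#' @param covariates character subset of `c("age", "sex")`
#' @return one-row data.frame: `beta`, `se`, `p_wald`, `or_`, `ci_low`,
#'   `ci_high`, `converged`
#' @export
logistic_assoc <- function(panel, phen, snp_id, covariates = c("age", "sex")) {
  j <- snp_index(panel, snp_id)
  idx <- match(rownames(panel$calls), phen$sample_id)
  df <- data.frame(y = as.integer(phen$status[idx] == "case"),
                   g = panel$calls[, j],
                   age = phen$age[idx], sex = phen$sex[idx])
  df <- df[!is.na(df$g), , drop = FALSE]
  if (length(covariates))
    covariates <- match.arg(covariates, c("age", "sex"), several.ok = TRUE)
  else covariates <- character(0)
  if (length(covariates) && anyNA(df[covariates]))
    stop("incomplete covariates for logistic regression")
  form <- stats::reformulate(c("g", covariates), response = "y")
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- summary(fit)$coefficients["g", ]
  beta <- co[1]; se <- co[2]
  # Wald blows up under separation: huge SE relative to the coefficient scale
  converged <- fit$converged && is.finite(se) && se < 100
  ci <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
  data.frame(snp_id = snp_id, beta = beta, se = se, p_wald = co[4],
             or_ = exp(beta), ci_low = ci[1], ci_high = ci[2],
             converged = converged, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction
#' @param p raw p-value
#' @param m number of tests, `>= 1`
#' @return `min(1, m * p)`
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, p >= 0, p <= 1)
  min(1, m * p)
}

# allelic chi-square for every SNP given a case mask; vectorised so the
# permutation loop stays cheap.  Returns a numeric vector over SNPs.
allelic_chi2_vec <- function(calls, case_mask) {
  gc <- calls[case_mask, , drop = FALSE]
  gn <- calls[!case_mask, , drop = FALSE]
  ca <- colSums(gc, na.rm = TRUE)
  cb <- 2 * colSums(!is.na(gc)) - ca
  na <- colSums(gn, na.rm = TRUE)
  nb <- 2 * colSums(!is.na(gn)) - na
  n <- ca + cb + na + nb
  num <- n * (ca * nb - cb * na)^2
  den <- (ca + cb) * (na + nb) * (ca + na) * (cb + nb)
  chi2 <- ifelse(den > 0, num / den, 0)
  unname(chi2)
}

#' Max-T permutation correction
#'
#' Family-wise adjusted p-values from the permutation distribution of the
#' maximum per-SNP statistic.  Permutations shuffle case/control labels only;
#' for each SNP `p_adj = (1 + #{perm : max statistic >= observed}) /
#' (n_perm + 1)`, never below the observed-inclusive floor `1/(n_perm+1)`.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param statistic function `(calls, case_mask) -> numeric vector` of per-SNP
#'   statistics (larger = more extreme); default allelic chi-square
#' @param n_perm number of permutations
#' @param seed RNG seed (required: the op is stochastic)
#' @return data.frame `snp_id`, `stat`, `p_perm`
#' @export
max_t_permutation <- function(panel, phen, statistic = allelic_chi2_vec,
                              n_perm = 1000, seed) {
  stopifnot(n_perm >= 1)
  if (missing(seed)) stop("seed is required")
  masks <- status_masks(panel, phen)
  obs <- statistic(panel$calls, masks$case)
  n_case <- sum(masks$case)
  ns <- n_samples(panel)
  maxes <- numeric(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- rep(FALSE, ns)
    perm[sample.int(ns, n_case)] <- TRUE
    maxes[b] <- max(statistic(panel$calls, perm))
  }
  p_adj <- vapply(obs, function(s) (1 + sum(maxes >= s)) / (n_perm + 1), 0)
  data.frame(snp_id = panel$snps$snp_id, stat = obs, p_perm = p_adj,
             stringsAsFactors = FALSE)
}
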