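#' Per-SNP genotyping call rate
#'
#' @param panel a `genotype_panel`
#' @param snp_id SNP identifier
#' @return fraction of samples with a non-missing call
#' @export
snp_call_rate <- function(panel, snp_id) {
  g <- panel$calls[, snp_index(panel, snp_id)]
  mean(!is.na(g))
}

#' Minor allele frequency
#'
#' Frequency of the less common allele among non-missing alleles, optionally
#' restricted to a sample subset.  Always `<= 0.5` by definition, regardless
#' of which allele the panel labels `allele_a`.
#'
#' @param panel a `genotype_panel`
#' @param snp_id SNP identifier
#' @param subset optional logical sample mask
#' @return fraction in `[0, 0.5]`
#' @export
minor_allele_freq <- function(panel, snp_id, subset = NULL) {
  g <- panel$calls[, snp_index(panel, snp_id)]
  if (!is.null(subset)) g <- g[subset]
  g <- g[!is.na(g)]
  if (!length(g)) stop("minor_allele_freq undefined: all calls missing for ",
                       snp_id)
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: given the observed allele
#' counts, the two-sided p-value sums the probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count.  Exact at small counts, where the chi-square approximation fails.
#' Probabilities are built by the stable ratio recurrence
#' P(h+2)/P(h) = 4 n_aa n_bb / ((h+2)(h+1)) over heterozygote counts of the
#' correct parity.
#'
#' @param n_hom_a,n_het,n_hom_b genotype counts
#' @return two-sided exact p-value
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  counts <- c(n_hom_a, n_het, n_hom_b)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  if (sum(counts) == 0) stop("no genotypes")
  n <- sum(counts)
  na <- 2 * n_hom_a + n_het          # count of the rarer-or-not allele A
  if (na > n) return(hwe_exact_test(n_hom_b, n_het, n_hom_a))
  if (na == 0) return(1)             # monomorphic: single outcome
  hets <- seq(na %% 2, na, by = 2)   # feasible het counts share parity with na
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_a <- (na - h) / 2
    hom_b <- n - h - hom_a
    probs[k] <- probs[k - 1] * 4 * hom_a * hom_b / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) stop("het count ", n_het, " inconsistent with allele count")
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

hwe_p_for_snp <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  hwe_exact_test(sum(g == 2L), sum(g == 1L), sum(g == 0L))
}

#' Marker-level quality control
#'
#' Screens each SNP on call rate, minor allele frequency and exact HWE, and
#' drops failures.  Defaults mirror the analysis-stage screen of the study
#' design: markers missing in more than half the cohort are uninformative,
#' MAF must exceed 0.01, and the HWE p-value must exceed 0.001.  HWE is
#' computed in both strata but filtering uses controls only (cases may
#' deviate under true association); both values are reported.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param geno_max maximum missing-call fraction (default 0.5)
#' @param maf_min minimum MAF over all samples, exclusive (default 0.01)
#' @param hwe_min minimum control-group HWE p-value, exclusive (default 0.001)
#' @return `list(panel = filtered genotype_panel, report = data.frame)` where
#'   the report has one row per input SNP with `snp_id`, `call_rate`, `maf`,
#'   `hwe_p_cases`, `hwe_p_controls`, `passed`, `fail_reasons`.
#' @export
apply_qc <- function(panel, phen, geno_max = 0.5, maf_min = 0.01,
                     hwe_min = 0.001) {
  stopifnot(geno_max >= 0, geno_max <= 1, maf_min >= 0, maf_min <= 1,
            hwe_min >= 0, hwe_min <= 1)
  masks <- status_masks(panel, phen)
  ids <- panel$snps$snp_id
  rep_rows <- lapply(seq_along(ids), function(j) {
    g <- panel$calls[, j]
    cr <- mean(!is.na(g))
    maf <- if (any(!is.na(g))) minor_allele_freq(panel, ids[j]) else NA_real_
    pca <- hwe_p_for_snp(g[masks$case])
    pco <- hwe_p_for_snp(g[masks$control])
    reasons <- character(0)
    if (1 - cr > geno_max) reasons <- c(reasons, "missingness")
    if (is.na(maf) || !(maf > maf_min)) reasons <- c(reasons, "maf")
    if (!is.na(pco) && !(pco > hwe_min)) reasons <- c(reasons, "hwe")
    data.frame(snp_id = ids[j], call_rate = cr, maf = maf,
               hwe_p_cases = pca, hwe_p_controls = pco,
               passed = length(reasons) == 0L,
               fail_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rep_rows)
  keep <- report$snp_id[report$passed]
  list(panel = subset_panel(panel, snp_ids = keep), report = report)
}
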