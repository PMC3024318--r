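test_that("allelic test reproduces the closed-form chi-square, OR and CI", {
  r0 <- allelic_test(50, 50, 50, 50)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$or_, 1)
  r <- allelic_test(100, 60, 80, 80)
  expect_equal(r$chi2, 320 * (100 * 80 - 60 * 80)^2 /
                 (160 * 160 * 180 * 140))
  expect_equal(r$chi2, 5.079365, tolerance = 1e-6)
  expect_equal(r$or_, 100 * 80 / (60 * 80))
  o <- oracle_or_ci(100, 60, 80, 80)
  expect_equal(c(r$ci_low, r$ci_high), o$ci, tolerance = 1e-9)
  expect_equal(r$ci_low, 1.067, tolerance = 1e-3)
  expect_equal(r$ci_high, 2.602, tolerance = 1e-3)
  # scaling: OR invariant, chi2 scales with n
  r10 <- allelic_test(1000, 600, 800, 800)
  expect_equal(r10$or_, r$or_)
  expect_equal(r10$chi2, 10 * r$chi2)
  # zero cell: Haldane-Anscombe correction, flagged
  rz <- allelic_test(10, 0, 5, 5)
  expect_true(rz$zero_cell)
  expect_equal(rz$or_, (10.5 * 5.5) / (0.5 * 5.5))
})

test_that("genotypic test matches the reference Pearson statistic", {
  eq <- matrix(c(30, 30, 40, 40, 30, 30), 2, 3)
  expect_equal(genotypic_test(eq)$p, 1)
  # empty genotype column drops a degree of freedom
  onecol <- matrix(c(30, 20, 70, 80, 0, 0), 2, 3)
  expect_equal(genotypic_test(onecol)$df, 1L)
  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(stats::rpois(6, 30) + 1, 2, 3)
    got <- genotypic_test(tab)
    want <- oracle_chi2(tab)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
    expect_equal(got$df, as.integer(want$df))
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("allelic and genotypic tests agree under multiplicative risk", {
  # HWE within strata and multiplicative genotype risk put all information
  # in the allele frequencies; the two statistics then nearly coincide
  for (fr in list(c(0.35, 0.25), c(0.5, 0.4))) {
    n <- 4000
    g_case <- n * c(fr[1]^2, 2 * fr[1] * (1 - fr[1]), (1 - fr[1])^2)
    g_ctrl <- n * c(fr[2]^2, 2 * fr[2] * (1 - fr[2]), (1 - fr[2])^2)
    al <- allelic_test(2 * g_case[1] + g_case[2], 2 * g_case[3] + g_case[2],
                       2 * g_ctrl[1] + g_ctrl[2], 2 * g_ctrl[3] + g_ctrl[2])
    ge <- genotypic_test(rbind(g_case, g_ctrl))
    expect_equal(al$chi2, ge$chi2, tolerance = 0.05)
  }
})

test_that("logistic fit recovers known effect sizes and the null", {
  # null: no effect, covariates present
  nullz <- replicate(30, {
    sim <- simulate_panel(sim_config(n_cases = 120, n_controls = 120,
                                     n_snps = 1, missing_rate = 0,
                                     maf_range = c(0.3, 0.3),
                                     seed = sample.int(1e6, 1)))
    r <- logistic_assoc(sim$panel, sim$phen, "snp0001")
    r$beta / r$se
  })
  expect_gte(mean(abs(nullz) < 4), 0.99)
  expect_lt(abs(mean(nullz)), 0.5)
  # parameter recovery at the study design
  set.seed(77)
  ors <- replicate(40, {
    sim <- simulate_panel(sim_config(
      block_spec = list(list(n_snps = 1, freqs = c(A = 0.3, G = 0.7))),
      risk_spec = list(block = 1, hap = "A", or_ = 1.6),
      missing_rate = 0, seed = sample.int(1e6, 1)))
    logistic_assoc(sim$panel, sim$phen, "snp0001")$or_
  })
  expect_gte(stats::median(ors), 1.4)
  expect_lte(stats::median(ors), 1.8)
})

test_that("unadjusted logistic Wald p agrees with the allelic test", {
  sim <- simulate_panel(sim_config(
    n_cases = 500, n_controls = 500,
    block_spec = list(list(n_snps = 1, freqs = c(A = 0.3, G = 0.7))),
    risk_spec = list(block = 1, hap = "A", or_ = 1.4),
    missing_rate = 0, seed = 13))
  lw <- logistic_assoc(sim$panel, sim$phen, "snp0001",
                       covariates = character(0))
  al <- assoc_scan(sim$panel, sim$phen)
  ratio <- -log10(lw$p_wald) / -log10(al$p[1])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("separation is flagged rather than fatal", {
  calls <- matrix(c(rep(2L, 20), rep(0L, 20)), 40, 1)
  p <- make_panel(calls)
  phen <- make_phen(p, 20)
  r <- logistic_assoc(p, phen, "s0001", covariates = character(0))
  expect_false(r$converged)
})

test_that("Bonferroni correction is textbook min(1, m p)", {
  expect_equal(bonferroni(0.001, 100), 0.1)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(3.36e-5, 231), 231 * 3.36e-5)
  expect_equal(bonferroni(3.36e-5, 231), 7.7616e-3, tolerance = 1e-9)
})

test_that("max-T permutation honours the floor, dominance and order invariance", {
  sim <- simulate_panel(sim_config(
    n_cases = 60, n_controls = 60,
    block_spec = c(list(list(n_snps = 1, freqs = c(A = 0.4, G = 0.6),
                             freqs_case = c(A = 0.75, G = 0.25),
                             freqs_ctrl = c(A = 0.25, G = 0.75))),
                   lapply(1:5, function(i)
                     list(n_snps = 1, freqs = c(A = 0.3, G = 0.7)))),
    missing_rate = 0, seed = 19))
  pp <- max_t_permutation(sim$panel, sim$phen, n_perm = 999, seed = 4)
  a <- assoc_scan(sim$panel, sim$phen)
  # implanted SNP beats every permuted max -> exact floor
  expect_equal(pp$p_perm[1], 1 / 1000)
  expect_true(all(pp$p_perm + 1e-12 >= a$p))
  # invariance to SNP ordering: reverse the coordinate map so the same
  # markers occupy reversed columns, then rerun with the same seed
  snps2 <- sim$panel$snps
  snps2$pos <- rev(snps2$pos)
  shuf <- genotype_panel(snps2, sim$panel$calls)
  pp2 <- max_t_permutation(shuf, sim$phen, n_perm = 999, seed = 4)
  expect_equal(pp2$p_perm[match(pp$snp_id, pp2$snp_id)], pp$p_perm)
})

test_that("max-T minimum adjusted p is approximately uniform under the null", {
  set.seed(8)
  minp <- replicate(60, {
    sim <- simulate_panel(sim_config(n_cases = 40, n_controls = 40,
                                     n_snps = 8, missing_rate = 0,
                                     seed = sample.int(1e6, 1)))
    min(max_t_permutation(sim$panel, sim$phen, n_perm = 99,
                          seed = sample.int(1e6, 1))$p_perm)
  })
  ks <- suppressWarnings(stats::ks.test(minp, "punif"))
  expect_gt(ks$p.value, 0.01)
})
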