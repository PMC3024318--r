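test_that("EM resolves unambiguous phase exactly", {
  # doubly homozygous individuals: no phase ambiguity at all
  calls <- rbind(matrix(2L, 5, 2), matrix(0L, 5, 2))
  p <- make_panel(calls)
  em <- em_haplotypes(p, NULL, c("s0001", "s0002"))
  f <- stats::setNames(em$freq_all, em$haplotypes)
  expect_equal(unname(f["AA"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(f["GG"]), 0.5, tolerance = 1e-9)
  expect_equal(sum(em$freq_all), 1, tolerance = 1e-6)
})

test_that("EM equals phase counting when no double heterozygotes exist", {
  # every individual has at most one het site -> haplotypes are countable
  calls <- rbind(c(2L, 2L), c(2L, 1L), c(1L, 2L), c(2L, 0L), c(0L, 0L),
                 c(0L, 1L))
  p <- make_panel(calls)
  em <- em_haplotypes(p, NULL, c("s0001", "s0002"))
  f <- stats::setNames(em$freq_all, em$haplotypes)
  # direct count: AA from rows 1(x2),2,3,4; AG from 2,4? enumerate per row:
  # (2,2)->AA,AA (2,1)->AA,AG (1,2)->AA,GA (2,0)->AG,AG (0,0)->GG,GG
  # (0,1)->GA,GG ; hap order string = (snp1 allele, snp2 allele)
  direct <- c(AA = 4, AG = 3, GA = 2, GG = 3) / 12
  expect_equal(unname(f[names(direct)]), unname(direct), tolerance = 1e-6)
})

test_that("two-SNP EM matches a brute-force likelihood grid", {
  for (seed in c(2, 3)) {
    sim <- simulate_panel(sim_config(
      n_cases = 150, n_controls = 150,
      block_spec = list(list(n_snps = 2, freqs = c(AA = 0.45, AG = 0.15,
                                                   GA = 0.1, GG = 0.3))),
      missing_rate = 0, seed = seed))
    em <- em_haplotypes(sim$panel, NULL, c("snp0001", "snp0002"))
    f <- stats::setNames(em$freq_all, em$haplotypes)
    g1 <- sim$panel$calls[, 1]; g2 <- sim$panel$calls[, 2]
    expect_equal(unname(f["AA"]), oracle_two_snp_hap_freq(g1, g2),
                 tolerance = 1e-4)
  }
})

test_that("EM recovers a known 3-SNP haplotype pool and is monotone", {
  pool <- c(AAA = 0.5, AGA = 0.3, GGA = 0.15, GGG = 0.05)
  sim <- simulate_panel(sim_config(
    n_cases = 1000, n_controls = 1000,
    block_spec = list(list(n_snps = 3, freqs = pool)),
    missing_rate = 0, seed = 101))
  em <- em_haplotypes(sim$panel, sim$phen, sim$panel$snps$snp_id)
  f <- stats::setNames(em$freq_all, em$haplotypes)
  for (h in names(pool))
    expect_lt(abs(f[[h]] - pool[[h]]), 0.02)
  expect_true(all(diff(em$loglik_trace) >= -1e-9))
  expect_equal(sum(em$freq_all), 1, tolerance = 1e-6)
  expect_equal(sum(em$freq_cases), 1, tolerance = 1e-6)
  expect_equal(sum(em$freq_controls), 1, tolerance = 1e-6)
})

test_that("pairwise LD reports coupling, equilibrium and symmetry", {
  sim <- simulate_panel(sim_config(
    n_cases = 1000, n_controls = 1000,
    block_spec = list(list(n_snps = 2, freqs = c(AA = 0.5, GG = 0.5))),
    missing_rate = 0, seed = 55))
  ld <- ld_pair(sim$panel, "snp0001", "snp0002")
  expect_equal(ld$d_prime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  expect_lte(ld$ci_low, ld$ci_high)
  # independent SNPs
  sim2 <- simulate_panel(sim_config(n_cases = 1000, n_controls = 1000,
                                    n_snps = 2, missing_rate = 0,
                                    seed = 56))
  ld2 <- ld_pair(sim2$panel, "snp0001", "snp0002")
  expect_lt(ld2$r2, 0.01)
  # r2 invariant to allele relabelling of one SNP
  flip <- sim2$panel$calls
  flip[, 2] <- 2L - flip[, 2]
  p3 <- genotype_panel(sim2$panel$snps, flip)
  ld3 <- ld_pair(p3, "snp0001", "snp0002")
  expect_equal(ld3$r2, ld2$r2, tolerance = 1e-9)
  # monomorphic SNP is an error
  mono <- sim2$panel$calls; mono[, 1] <- 2L
  p4 <- genotype_panel(sim2$panel$snps, mono)
  expect_error(ld_pair(p4, "snp0001", "snp0002"), "monomorphic")
})

test_that("confidence-interval blocks find LD structure and partition", {
  strong <- simulate_panel(sim_config(
    n_cases = 1000, n_controls = 1000,
    block_spec = list(list(n_snps = 3, freqs = c(AAA = 0.6, GGG = 0.4))),
    missing_rate = 0, seed = 61))
  bl <- gabriel_blocks(strong$panel)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$n_snps, 3)
  indep <- simulate_panel(sim_config(n_cases = 1000, n_controls = 1000,
                                     n_snps = 3, missing_rate = 0,
                                     seed = 62))
  expect_equal(nrow(gabriel_blocks(indep$panel)), 0)
  # two separated blocks with an independent spacer never overlap
  mixed <- simulate_panel(sim_config(
    n_cases = 800, n_controls = 800,
    block_spec = list(list(n_snps = 2, freqs = c(AA = 0.55, GG = 0.45)),
                      list(n_snps = 1, freqs = c(A = 0.5, G = 0.5)),
                      list(n_snps = 2, freqs = c(AA = 0.5, GG = 0.5))),
    missing_rate = 0, seed = 63))
  bl2 <- gabriel_blocks(mixed$panel)
  expect_gte(nrow(bl2), 1)
  spans <- mapply(function(s, e) {
    i <- match(s, mixed$panel$snps$snp_id)
    j <- match(e, mixed$panel$snps$snp_id)
    i:j
  }, bl2$start_snp, bl2$end_snp, SIMPLIFY = FALSE)
  expect_equal(anyDuplicated(unlist(spans)), 0)
})

test_that("a complete-LD window reduces to the single-SNP allelic test", {
  sim <- simulate_panel(sim_config(
    n_cases = 300, n_controls = 300,
    block_spec = list(list(n_snps = 3, freqs = c(AAA = 0.7, GGG = 0.3),
                           freqs_case = c(AAA = 0.78, GGG = 0.22),
                           freqs_ctrl = c(AAA = 0.66, GGG = 0.34))),
    missing_rate = 0, seed = 71))
  hw <- sliding_window_assoc(sim$panel, sim$phen, window_size = 3)
  al <- assoc_scan(sim$panel, sim$phen)
  aaa <- hw[hw$haplotype == "AAA", ]
  expect_equal(aaa$p, al$p[1], tolerance = 1e-6)
  expect_equal(aaa$chi2, al$chi2[1], tolerance = 1e-4)
})

test_that("an implanted risk haplotype is detected with honest frequencies", {
  sim <- simulate_panel(sim_config(
    block_spec = c(list(list(n_snps = 3, freqs = c(AAA = 0.78, GGG = 0.22),
                             freqs_case = c(AAA = 0.822, GGG = 0.178),
                             freqs_ctrl = c(AAA = 0.733, GGG = 0.267))),
                   list(list(n_snps = 2, freqs = c(AA = 0.3, AG = 0.2,
                                                   GG = 0.5)))),
    missing_rate = 0, seed = 81))
  hw <- sliding_window_assoc(sim$panel, sim$phen, window_size = 3)
  aaa <- hw[hw$window == 1 & hw$haplotype == "AAA", ]
  expect_lt(aaa$p, 0.01)
  expect_equal(aaa$freq_case, 0.822, tolerance = 0.04)
  expect_equal(aaa$freq_ctrl, 0.733, tolerance = 0.04)
})

test_that("haplotype permutation p dominates the raw p and has a floor", {
  sim <- simulate_panel(sim_config(
    n_cases = 80, n_controls = 80,
    block_spec = c(list(list(n_snps = 3, freqs = c(AAA = 0.6, GGG = 0.4),
                             freqs_case = c(AAA = 0.85, GGG = 0.15),
                             freqs_ctrl = c(AAA = 0.35, GGG = 0.65))),
                   list(list(n_snps = 1, freqs = c(A = 0.3, G = 0.7)))),
    missing_rate = 0, seed = 91))
  windows <- list(sim$panel$snps$snp_id[1:3], sim$panel$snps$snp_id[2:4])
  hp <- haplotype_permutation(sim$panel, sim$phen, windows, n_perm = 199,
                              seed = 6)
  expect_true(all(hp$p_perm + 1e-12 >= hp$p))
  expect_true(all(hp$p_perm >= 1 / 200))
  top <- hp[which.min(hp$p), ]
  expect_equal(top$p_perm, 1 / 200)  # implant beats every permuted max
})
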