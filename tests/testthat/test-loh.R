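test_that("homozygosity frequency counts non-missing genotypes", {
  calls <- matrix(c(rep(1L, 10),                       # cases: all het
                    c(rep(2L, 4), rep(0L, 2), rep(1L, 3), NA)), 20, 1)
  p <- make_panel(calls)
  phen <- make_phen(p, 10)
  expect_equal(homozygosity_freq(p, phen, "s0001", "case"), 0)
  expect_equal(homozygosity_freq(p, phen, "s0001", "control"), 6 / 9)
  allhom <- make_panel(matrix(2L, 10, 1))
  expect_equal(homozygosity_freq(allhom, make_phen(allhom, 5), "s0001",
                                 "case"), 1)
  missing_case <- make_panel(matrix(c(NA_integer_, 1L), 2, 1))
  expect_error(homozygosity_freq(missing_case, make_phen(missing_case, 1),
                                 "s0001", "case"), "no non-missing")
})

test_that("T/N ratio is simple division with guarded domain", {
  expect_equal(tn_ratio(0.608, 0.5), 1.216)
  expect_equal(tn_ratio(0.5, 0.5), 1)
  expect_error(tn_ratio(0.5, 0), "undefined")
  expect_error(tn_ratio(1.2, 0.5))
  # the packaged table's reference magnitude
  fx <- load_loh_fixture()
  expect_equal(fx$tn_ratio[fx$snp_id == "rs2076483"], 1.2159952)
})

test_that("homozygosity test matches the 2x2 oracle and flag conjunction", {
  # 60% vs 50% homozygous at n = 360 each: counts 216/144 vs 180/180
  calls <- matrix(c(rep(c(2L, 0L), 108), rep(1L, 144),
                    rep(c(2L, 0L), 90), rep(1L, 180)), ncol = 1)
  p <- make_panel(calls)
  phen <- make_phen(p, 360)
  r <- homozygosity_test(p, phen, "s0001")
  want <- oracle_chi2(matrix(c(216, 180, 144, 180), 2, 2))
  expect_equal(r$chi2, want$chi2, tolerance = 1e-9)
  expect_equal(r$p, want$p, tolerance = 1e-9)
  expect_equal(r$chi2, 7.2727, tolerance = 1e-4)
  expect_equal(r$p, 0.007, tolerance = 0.01)
  expect_equal(r$tn_ratio, 1.2)
  expect_true(r$is_frequent_loh)
  # identical groups: ratio exactly 1 is NOT frequent LOH (strict >)
  same <- make_panel(matrix(rep(c(2L, 1L), 50), ncol = 1))
  r2 <- homozygosity_test(same, make_phen(same, 50), "s0001")
  expect_equal(r2$tn_ratio, 1)
  expect_false(r2$is_frequent_loh)
  # elevated ratio but weak evidence fails the conjunction
  weak <- make_panel(matrix(c(rep(2L, 11), rep(1L, 9),
                              rep(2L, 9), rep(1L, 11)), ncol = 1))
  r3 <- homozygosity_test(weak, make_phen(weak, 20), "s0001")
  expect_gt(r3$tn_ratio, 1)
  expect_gt(r3$p, 0.05)
  expect_false(r3$is_frequent_loh)
})

test_that("frequent-LOH filtering retains the published 19 loci", {
  fx <- load_loh_fixture()
  kept <- call_frequent_loh(fx)
  expect_equal(nrow(kept), 19)
  expect_equal(kept$snp_id, fx$snp_id)   # order preserved
  expect_equal(nrow(call_frequent_loh(fx[0, ])), 0)
  # boundary: p exactly at alpha is excluded
  edge <- data.frame(snp_id = "x", tn_ratio = 1.2, p_value = 0.05)
  expect_equal(nrow(call_frequent_loh(edge)), 0)
  edge$p_value <- 0.049
  expect_equal(nrow(call_frequent_loh(edge)), 1)
  edge$tn_ratio <- 1
  expect_equal(nrow(call_frequent_loh(edge)), 0)
})

test_that("micro-deletion regions are maximal runs of adjacent loci", {
  fx <- load_loh_fixture()
  rg <- call_microdeletions(fx$snp_id, fx$snp_id[fx$in_microdeletion])
  expect_equal(nrow(rg), 3)
  expect_equal(rg$snp_ids,
               c("rs504083,rs1318748,rs11759513",
                 "rs2267633,rs2076483,rs29230",
                 "rs9260734,rs3869062,rs5009448"))
  ids <- sprintf("m%02d", 1:10)
  rg2 <- call_microdeletions(ids, ids[c(1, 2, 4, 5, 6)])
  expect_equal(nrow(rg2), 1)
  expect_equal(rg2$snp_ids, "m04,m05,m06")
  rg3 <- call_microdeletions(ids, ids)
  expect_equal(nrow(rg3), 1)
  expect_equal(rg3$n_snps, 10)
  expect_equal(nrow(call_microdeletions(ids, character(0))), 0)
  expect_error(call_microdeletions(ids, "zz"), "absent")
})

test_that("regions from a panel are disjoint, position-sorted and annotated", {
  sim <- simulate_panel(sim_config(n_cases = 150, n_controls = 150,
                                   n_snps = 20,
                                   deletion_spec = list(
                                     snp_range = c(4, 9),
                                     carrier_freq_cases = 0.6,
                                     carrier_freq_controls = 0.05),
                                   missing_rate = 0, seed = 17))
  l <- loh_scan(sim$panel, sim$phen)
  fl <- call_frequent_loh(l)
  rg <- call_microdeletions(sim$panel$snps$snp_id, fl$snp_id, 3, sim$panel)
  expect_gte(nrow(rg), 1)
  expect_true(all(diff(rg$start_pos) > 0))
  expect_true(all(rg$end_pos >= rg$start_pos))
  expect_true(any(mapply(function(s, e) s <= 9 && e >= 4,
                         match(rg$start_snp, sim$panel$snps$snp_id),
                         match(rg$end_snp, sim$panel$snps$snp_id))))
})

test_that("T/N ratio is invariant to group-size scaling", {
  base <- c(rep(2L, 12), rep(1L, 8))   # 60% homozygous
  ctrl <- c(rep(2L, 10), rep(1L, 10))  # 50%
  small <- make_panel(matrix(c(base, ctrl), ncol = 1))
  big <- make_panel(matrix(c(rep(base, 5), rep(ctrl, 5)), ncol = 1))
  r1 <- homozygosity_test(small, make_phen(small, 20), "s0001")
  r2 <- homozygosity_test(big, make_phen(big, 100), "s0001")
  expect_equal(r1$tn_ratio, r2$tn_ratio)
})
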