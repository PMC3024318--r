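test_that("PED/MAP parsing assigns genotype codes and conventions", {
  td <- withr::local_tempdir()
  ped <- file.path(td, "x.ped"); map <- file.path(td, "x.map")
  writeLines(c("F1 S1 0 0 1 2 A A",
               "F2 S2 0 0 2 1 A G",
               "F3 S3 0 0 1 1 0 0",
               "F4 S4 0 0 2 1 G G"), ped)
  writeLines("6\trs1\t0\t1000", map)
  d <- read_ped_map(ped, map)
  # minor allele among controls (S2 het, S3 missing, S4 GG) is A
  expect_equal(d$panel$snps$allele_a, "A")
  expect_equal(unname(d$panel$calls[, "rs1"]), c(2L, 1L, NA_integer_, 0L))
  expect_equal(as.character(d$phen$status), c("case", "control", "control",
                                              "control"))
  expect_equal(as.character(d$phen$sex), c("male", "female", "male",
                                           "female"))
})

test_that("malformed PED inputs fail with location information", {
  td <- withr::local_tempdir()
  ped <- file.path(td, "x.ped"); map <- file.path(td, "x.map")
  writeLines(c("F1 S1 0 0 1 2 A A", "F2 S2 0 0 1 1 A"), ped)
  writeLines("6\trs1\t0\t1000", map)
  expect_error(read_ped_map(ped, map), "line 2")
  writeLines(c("F1 S1 0 0 0 2 A A"), ped)
  expect_error(read_ped_map(ped, map), "sex")
  writeLines(c("F1 S1 0 0 1 9 A A"), ped)
  expect_error(read_ped_map(ped, map), "phenotype")
  writeLines(c("F1 S1 0 0 1 2 A A G G"), ped)
  writeLines(c("6\trs1\t0\t1000", "6\trs1\t0\t2000"), map)
  expect_error(read_ped_map(ped, map), "duplicate")
})

test_that("PED/MAP round trip is byte-identical and preserves every call", {
  sim <- simulate_panel(sim_config(n_cases = 10, n_controls = 10,
                                   n_snps = 50, missing_rate = 0.05,
                                   seed = 7))
  td <- withr::local_tempdir()
  a <- file.path(td, c("a.ped", "a.map"))
  b <- file.path(td, c("b.ped", "b.map"))
  write_ped_map(sim$panel, sim$phen, a[1], a[2])
  d <- read_ped_map(a[1], a[2])
  write_ped_map(d$panel, d$phen, b[1], b[2])
  expect_identical(readLines(a[1]), readLines(b[1]))
  expect_identical(readLines(a[2]), readLines(b[2]))
  # calls identical up to the deterministic minor-allele relabelling
  flip <- d$panel$snps$allele_a != sim$panel$snps$allele_a
  expect_calls <- sim$panel$calls
  expect_calls[, flip] <- 2L - expect_calls[, flip]
  expect_identical(unname(d$panel$calls), unname(expect_calls))
})

test_that("empty and missing-call panels are written in PLINK conventions", {
  p <- make_panel(matrix(c(2L, NA_integer_), 1, 2,
                         dimnames = list("S001", NULL)))
  phen <- make_phen(p, 1)
  td <- withr::local_tempdir()
  write_ped_map(p, phen, file.path(td, "m.ped"), file.path(td, "m.map"))
  line <- readLines(file.path(td, "m.ped"))
  expect_match(line, "A A 0 0$")
  empty <- subset_panel(p, snp_ids = character(0), samples = character(0))
  ph0 <- phenotype_table(character(0), character(0), numeric(0),
                         character(0))
  write_ped_map(empty, ph0, file.path(td, "e.ped"), file.path(td, "e.map"))
  expect_length(readLines(file.path(td, "e.ped")), 0)
  expect_length(readLines(file.path(td, "e.map")), 0)
})

test_that("panel construction sorts by position and sorting is idempotent", {
  calls <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 2, 3)
  snps <- data.frame(snp_id = c("c", "a", "b"), chrom = "6",
                     pos = c(300L, 100L, 200L), allele_a = "A",
                     allele_b = "G", stringsAsFactors = FALSE)
  p <- genotype_panel(snps, calls)
  expect_equal(p$snps$snp_id, c("a", "b", "c"))
  expect_equal(unname(p$calls[1, ]), c(2L, 0L, 0L))
  p2 <- genotype_panel(p$snps, p$calls)
  expect_identical(p2$snps, p$snps)
  expect_identical(p2$calls, p$calls)
  expect_error(genotype_panel(rbind(snps, snps[1, ]),
                              cbind(calls, calls[, 1])), "duplicate")
})

test_that("the packaged frequent-LOH table matches its published values", {
  fx <- load_loh_fixture()
  expect_equal(nrow(fx), 19L)
  expect_equal(fx$tn_ratio[fx$snp_id == "rs2143083"], 1.3092179)
  expect_equal(fx$p_value[fx$snp_id == "rs2143083"], 0.0001)
  expect_equal(fx$tn_ratio[fx$snp_id == "rs2076483"], 1.2159952)
  expect_equal(sum(fx$in_microdeletion), 9L)
  expect_true(all(c("rs504083", "rs1318748", "rs11759513", "rs2267633",
                    "rs2076483", "rs29230", "rs9260734", "rs3869062",
                    "rs5009448") %in% fx$snp_id[fx$in_microdeletion]))
  # integrity guard on row count
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.csv")
  utils::write.csv(fx[1:18, ], bad, row.names = FALSE, quote = FALSE)
  expect_error(load_loh_fixture(bad), "19")
})
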