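#' Simulation configuration
#'
#' Defaults emulate the study design this pipeline targets: 360 cases and 360
#' controls typed at 233 biallelic tag SNPs evenly spaced over chromosome 6p
#' (6,095,364-30,048,467 bp), control genotypes in HWE, and ~2% missing
#' calls.  Haplotype structure comes from `block_spec`; risk haplotypes,
#' hemizygous micro-deletions and autozygous (ROH) tracts are optional
#' implants recorded in the truth record.
#'
#' @param n_cases,n_controls sample sizes per stratum
#' @param n_snps panel size when `block_spec` is `NULL` (independent SNPs
#'   with MAF drawn uniformly from `maf_range`)
#' @param region `list(chrom, start_bp, end_bp)`
#' @param block_spec list of blocks; each block is
#'   `list(n_snps =, freqs = c(hap = prob, ...))` with haplotypes written
#'   over `A` (= allele_a) and `G` (= allele_b), plus optional `freqs_case` /
#'   `freqs_ctrl` to draw strata at stated frequencies directly
#' @param risk_spec optional `list(block =, hap =, or_ =)`: disease status
#'   assigned by a logistic model additive in copies of the risk haplotype,
#'   intercept set for ~50% case probability at the mean haplotype dose, and
#'   fixed stratum sizes filled by rejection
#' @param deletion_spec optional `list(snp_range = c(from, to),
#'   carrier_freq_cases =, carrier_freq_controls =)`; carriers lose one
#'   haplotype over the span and are typed homozygous for the surviving
#'   allele (never missing)
#' @param roh_spec optional `list(n_samples =, tract_length_kb =)` implanting
#'   autozygous tracts
#' @param missing_rate uniform missing-call rate (default 0.02)
#' @param maf_range MAF range for default independent SNPs
#' @param seed mandatory integer seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_cases = 360, n_controls = 360, n_snps = 233,
                       region = list(chrom = "6", start_bp = 6095364,
                                     end_bp = 30048467),
                       block_spec = NULL, risk_spec = NULL,
                       deletion_spec = NULL, roh_spec = NULL,
                       missing_rate = 0.02, maf_range = c(0.05, 0.5),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.null(block_spec)) {
    for (b in block_spec) {
      for (f in Filter(Negate(is.null),
                       b[c("freqs", "freqs_case", "freqs_ctrl")])) {
        if (abs(sum(f) - 1) > 1e-8) stop("block frequencies must sum to 1")
        if (any(f < 0)) stop("block frequencies must be non-negative")
        if (any(nchar(names(f)) != b$n_snps))
          stop("haplotype strings must have length n_snps")
      }
    }
    n_snps <- sum(vapply(block_spec, function(b) b$n_snps, 0))
  }
  if (!is.null(deletion_spec) &&
      (deletion_spec$snp_range[1] < 1 || deletion_spec$snp_range[2] > n_snps))
    stop("deletion span outside panel")
  structure(list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
                 region = region, block_spec = block_spec,
                 risk_spec = risk_spec, deletion_spec = deletion_spec,
                 roh_spec = roh_spec, missing_rate = missing_rate,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

# haplotype pool as 0/1 matrix (1 = allele_a) from names(freqs)
hap_matrix <- function(freqs) {
  k <- nchar(names(freqs)[1])
  v <- vapply(strsplit(names(freqs), ""), function(s) as.integer(s == "A"),
              integer(k))
  if (k == 1) matrix(v, ncol = 1) else t(v)
}

# draw haplotype-pair matrices for nb individuals; status optional (used for
# per-stratum block frequencies).  Returns H1, H2 (0/1 allele_a indicators)
# and the risk-haplotype dose when a risk_spec points into these blocks.
draw_individuals <- function(nb, blocks, status = NULL, risk_spec = NULL) {
  m <- sum(vapply(blocks, function(b) b$n_snps, 0))
  H1 <- matrix(0L, nb, m)
  H2 <- matrix(0L, nb, m)
  dose <- numeric(nb)
  col0 <- 0
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    cols <- col0 + seq_len(b$n_snps)
    pick <- function(fr, k) sample.int(length(fr), k, replace = TRUE,
                                       prob = fr)
    if (!is.null(status) &&
        (!is.null(b$freqs_case) || !is.null(b$freqs_ctrl))) {
      fc <- if (is.null(b$freqs_case)) b$freqs else b$freqs_case
      fn <- if (is.null(b$freqs_ctrl)) b$freqs else b$freqs_ctrl
      hm <- hap_matrix(fc)
      ca <- status == "case"
      i1 <- integer(nb); i2 <- integer(nb)
      i1[ca] <- pick(fc, sum(ca));  i2[ca] <- pick(fc, sum(ca))
      i1[!ca] <- pick(fn, sum(!ca)); i2[!ca] <- pick(fn, sum(!ca))
    } else {
      hm <- hap_matrix(b$freqs)
      i1 <- pick(b$freqs, nb)
      i2 <- pick(b$freqs, nb)
    }
    H1[, cols] <- hm[i1, , drop = FALSE]
    H2[, cols] <- hm[i2, , drop = FALSE]
    if (!is.null(risk_spec) && risk_spec$block == bi) {
      r <- match(risk_spec$hap, names(b$freqs))
      if (is.na(r)) stop("risk haplotype not in block pool")
      dose <- (i1 == r) + (i2 == r)
    }
    col0 <- col0 + b$n_snps
  }
  list(H1 = H1, H2 = H2, dose = dose)
}

#' Simulate a case-control genotype panel
#'
#' Individuals are two haplotypes per block drawn from the configured pools;
#' positions are evenly spaced over the region; genotype codes count copies
#' of allele_a.  With a `risk_spec`, status comes from a logistic model on
#' risk-haplotype dose and the two strata are filled by rejection; with
#' per-stratum block frequencies, haplotypes are drawn per stratum directly;
#' otherwise strata differ only by sampling noise.  Deletion and ROH
#' implants and the per-sample carrier lists go into the truth record.
#'
#' @param config a [sim_config()]
#' @return `list(panel = genotype_panel, phen = phenotype_table,
#'   truth = list)`
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_snps
  n <- config$n_cases + config$n_controls
  blocks <- config$block_spec
  if (is.null(blocks)) {
    mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    blocks <- lapply(mafs, function(f)
      list(n_snps = 1, freqs = stats::setNames(c(f, 1 - f), c("A", "G"))))
  }
  per_stratum <- any(vapply(blocks, function(b)
    !is.null(b$freqs_case) || !is.null(b$freqs_ctrl), TRUE))
  status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

  if (!is.null(config$risk_spec) && !per_stratum) {
    # logistic disease model with ~50% case probability at the mean dose;
    # rejection sampling fills the two fixed strata
    rb <- blocks[[config$risk_spec$block]]
    risk_freq <- rb$freqs[match(config$risk_spec$hap, names(rb$freqs))]
    beta <- log(config$risk_spec$or_)
    b0 <- -beta * 2 * risk_freq
    need <- c(case = config$n_cases, control = config$n_controls)
    H1 <- matrix(0L, 0, m); H2 <- matrix(0L, 0, m)
    got_status <- character(0)
    while (any(need > 0)) {
      nb <- max(2L * sum(need), 100L)
      d <- draw_individuals(nb, blocks, risk_spec = config$risk_spec)
      st <- ifelse(stats::runif(nb) <
                     stats::plogis(b0 + beta * d$dose), "case", "control")
      for (g in c("case", "control")) {
        take <- which(st == g)
        take <- take[seq_len(min(length(take), need[[g]]))]
        if (!length(take)) next
        H1 <- rbind(H1, d$H1[take, , drop = FALSE])
        H2 <- rbind(H2, d$H2[take, , drop = FALSE])
        got_status <- c(got_status, rep(g, length(take)))
        need[[g]] <- need[[g]] - length(take)
      }
    }
    ord <- order(factor(got_status, levels = c("case", "control")))
    H1 <- H1[ord, , drop = FALSE]
    H2 <- H2[ord, , drop = FALSE]
  } else {
    d <- draw_individuals(n, blocks, status = status,
                          risk_spec = config$risk_spec)
    H1 <- d$H1; H2 <- d$H2
  }

  calls <- H1 + H2
  truth <- list(seed = config$seed)
  if (!is.null(config$deletion_spec)) {
    ds <- config$deletion_spec
    span <- ds$snp_range[1]:ds$snp_range[2]
    carrier <- stats::runif(n) < ifelse(status == "case",
                                        ds$carrier_freq_cases,
                                        ds$carrier_freq_controls)
    # surviving haplotype is H1; hemizygous span typed homozygous for it
    calls[carrier, span] <- 2L * H1[carrier, span, drop = FALSE]
    truth$deletion <- list(span = span, carriers = which(carrier),
                           n_case_carriers = sum(carrier & status == "case"),
                           n_ctrl_carriers = sum(carrier &
                                                   status == "control"))
  }
  pos <- round(seq(config$region$start_bp, config$region$end_bp,
                   length.out = m))
  if (!is.null(config$roh_spec)) {
    rs <- config$roh_spec
    tract_samples <- sample.int(n, rs$n_samples)
    tract <- list()
    len_bp <- rs$tract_length_kb * 1000
    fits <- max(1, sum(pos <= pos[m] - len_bp))  # full tract inside panel
    for (s in tract_samples) {
      start <- sample.int(fits, 1)
      span <- which(pos >= pos[start] & pos <= pos[start] + len_bp)
      calls[s, span] <- 2L * H1[s, span]
      tract[[length(tract) + 1]] <- list(sample = s, span = span)
    }
    truth$roh <- tract
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    calls[drop] <- NA_integer_
  }
  sample_id <- sprintf("%s%03d", ifelse(status == "case", "CA", "CO"),
                       stats::ave(seq_len(n), status, FUN = seq_along))
  rownames(calls) <- sample_id
  snps <- data.frame(snp_id = sprintf("snp%04d", seq_len(m)),
                     chrom = config$region$chrom, pos = pos,
                     band = NA_character_, allele_a = "A", allele_b = "G",
                     stringsAsFactors = FALSE)
  panel <- genotype_panel(snps, calls)
  # covariates emulate the cohort description: cases older and mostly male
  is_case <- status == "case"
  age <- round(ifelse(is_case, stats::rnorm(n, 46.4, 11.2),
                      stats::rnorm(n, 41.4, 8.9)))
  age <- pmin(pmax(age, 14), 75)
  sex <- ifelse(stats::runif(n) < ifelse(is_case, 0.718, 0.344),
                "male", "female")
  phen <- phenotype_table(sample_id, status, age, sex)
  list(panel = panel, phen = phen, truth = truth)
}

#' Simulate a paired tumor/normal Ct table
#'
#' One target and one endogenous-control gene per specimen, `n_replicates`
#' replicate wells each with normal measurement noise; the tumor target is
#' shifted by a per-pair true ddCt drawn `N(delta_delta_ct_mean, sd)`.
#'
#' @param n_pairs number of tumor/normal pairs
#' @param delta_delta_ct_mean mean true ddCt (positive = lower tumor
#'   expression)
#' @param sd between-pair SD of the true ddCt
#' @param n_replicates replicate wells per (specimen, gene) (default 2)
#' @param seed RNG seed
#' @param replicate_sd well-to-well Ct noise (default 0.15 cycles)
#' @return data.frame: `sample_id`, `tissue`, `gene`, `role`, `replicate`,
#'   `ct`; attribute `true_ddct` carries the per-pair truth
#' @export
simulate_ct_table <- function(n_pairs, delta_delta_ct_mean, sd,
                              n_replicates = 2, seed, replicate_sd = 0.15) {
  stopifnot(n_pairs >= 1)
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  true_ddct <- stats::rnorm(n_pairs, delta_delta_ct_mean, sd)
  rows <- list()
  for (i in seq_len(n_pairs)) {
    base_target <- stats::rnorm(1, 24, 1)   # pair-level target abundance
    base_ctrl <- stats::rnorm(1, 12, 0.5)   # endogenous control
    for (tissue in c("normal", "tumor")) {
      shift <- if (tissue == "tumor") true_ddct[i] else 0
      for (rep_i in seq_len(n_replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("P%02d", i), tissue = tissue,
          gene = c("TARGET", "CTRL18S"),
          role = c("target", "endogenous_control"),
          replicate = rep_i,
          ct = c(base_target + shift + stats::rnorm(1, 0, replicate_sd),
                 base_ctrl + stats::rnorm(1, 0, replicate_sd)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_ddct") <- true_ddct
  out
}

#' Write the canonical synthetic fixture suite
#'
#' Generates and writes the panels and tables the pipeline stages consume: a
#' null panel at the study design, a risk-haplotype panel, a micro-deletion
#' panel, a dense ROH panel with implanted tracts, a paired Ct table, the
#' packaged frequent-LOH summary CSV, and a JSON manifest recording every
#' seed.
#'
#' @param out_dir output directory (created if needed)
#' @param seed master seed; per-fixture seeds derive from it by fixed offsets
#' @return invisibly, the manifest list
#' @export
write_fixture_suite <- function(out_dir, seed = 1) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", out_dir)
  seeds <- list(null = seed + 101, risk = seed + 202, deletion = seed + 303,
                roh = seed + 404, ct = seed + 505)
  wr <- function(sim, tag) {
    write_ped_map(sim$panel, sim$phen,
                  file.path(out_dir, paste0(tag, ".ped")),
                  file.path(out_dir, paste0(tag, ".map")),
                  file.path(out_dir, paste0(tag, "_covar.tsv")))
  }
  wr(simulate_panel(sim_config(seed = seeds$null)), "null")
  risk_blocks <- c(list(list(n_snps = 3,
                             freqs = c(AAA = 0.78, GGG = 0.22),
                             freqs_case = c(AAA = 0.822, GGG = 0.178),
                             freqs_ctrl = c(AAA = 0.733, GGG = 0.267))),
                   lapply(1:7, function(i)
                     list(n_snps = 1, freqs = c(A = 0.3, G = 0.7))))
  wr(simulate_panel(sim_config(block_spec = risk_blocks,
                               seed = seeds$risk)), "risk")
  wr(simulate_panel(sim_config(n_snps = 12,
                               deletion_spec = list(
                                 snp_range = c(5, 8),
                                 carrier_freq_cases = 0.20,
                                 carrier_freq_controls = 0.05),
                               seed = seeds$deletion)), "deletion")
  wr(simulate_panel(sim_config(n_cases = 20, n_controls = 20, n_snps = 300,
                               region = list(chrom = "6", start_bp = 6e6,
                                             end_bp = 6e6 + 299 * 10000),
                               roh_spec = list(n_samples = 5,
                                               tract_length_kb = 2000),
                               seed = seeds$roh)), "roh")
  ct <- simulate_ct_table(11, 1.5, 1, seed = seeds$ct)
  write_tsv(ct, file.path(out_dir, "ct_pairs.tsv"))
  file.copy(system.file("extdata", "loh_table1.csv", package = "loh6p"),
            file.path(out_dir, "loh_table1.csv"), overwrite = TRUE)
  manifest <- list(master_seed = seed, seeds = seeds,
                   files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
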