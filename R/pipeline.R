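#' Pipeline configuration
#'
#' Collects the input paths, stage options and the master seed for one
#' end-to-end run.  Stages communicate through files under `out_dir`, so
#' each stage is independently re-runnable and a rerun with the same config
#' is bitwise-identical.
#'
#' @param ped,map PLINK-text genotype input paths
#' @param covar optional `sample_id  age` TSV
#' @param ct_table optional Ct TSV (`sample_id`, `tissue`, `gene`, `role`,
#'   `replicate`, `ct`) for the qPCR stage
#' @param loh_fixture path to a frequent-LOH summary CSV (defaults to the
#'   packaged table)
#' @param out_dir output directory
#' @param seed master seed; required whenever permutations are requested
#' @param geno_max,maf_min,hwe_min QC thresholds (see [apply_qc()])
#' @param assoc_perm,haplo_perm permutation counts (0 = skip)
#' @param haplo_window sliding-window size
#' @param blocks_around number of flanking SNPs on each side of the top
#'   association for the LD-block stage; `NULL` skips block finding
#' @param loh_alpha,loh_min_run frequent-LOH / region-calling parameters
#' @param roh a [roh_params()] list
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(ped, map, covar = NULL, ct_table = NULL,
                            loh_fixture = system.file("extdata",
                                                      "loh_table1.csv",
                                                      package = "loh6p"),
                            out_dir, seed = NULL, geno_max = 0.5,
                            maf_min = 0.01, hwe_min = 0.001,
                            assoc_perm = 0, haplo_perm = 0,
                            haplo_window = 3, blocks_around = 3,
                            loh_alpha = 0.05, loh_min_run = 3,
                            roh = roh_params()) {
  if ((assoc_perm > 0 || haplo_perm > 0) && is.null(seed))
    stop("seed is mandatory when any permutation is requested")
  structure(list(ped = ped, map = map, covar = covar, ct_table = ct_table,
                 loh_fixture = loh_fixture, out_dir = out_dir, seed = seed,
                 geno_max = geno_max, maf_min = maf_min, hwe_min = hwe_min,
                 assoc_perm = assoc_perm, haplo_perm = haplo_perm,
                 haplo_window = haplo_window, blocks_around = blocks_around,
                 loh_alpha = loh_alpha, loh_min_run = loh_min_run,
                 roh = roh), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes QC, single-SNP association, sliding-window haplotype analysis
#' (with LD blocks around the top association), the homozygosity-ratio LOH /
#' micro-deletion stage, the ROH screen and, when a Ct table is supplied,
#' the paired 2^-ddCt expression stage.  Every stage writes a TSV under
#' `out_dir`; a JSON manifest records package version, seed, parameters and
#' per-file row counts.  Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()]
#' @return the manifest, invisibly (also written to `manifest.json`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c(config$ped, config$map, config$covar, config$ct_table)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- list(package = "loh6p",
                   version = as.character(utils::packageVersion("loh6p")),
                   seed = config$seed, stages = list())
  note <- function(stage, files, params = NULL) {
    counts <- vapply(files, function(f)
      length(readLines(out(f))) - 1L, 0L)
    manifest$stages[[stage]] <<- list(files = as.list(files),
                                      rows = as.list(counts),
                                      params = params)
    message("[", stage, "] wrote ", paste(files, collapse = ", "))
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dat <- stage("load", function()
    read_ped_map(config$ped, config$map, config$covar))
  panel <- dat$panel; phen <- dat$phen

  qc <- stage("qc", function() {
    r <- apply_qc(panel, phen, config$geno_max, config$maf_min,
                  config$hwe_min)
    write_tsv(r$report, out("qc_report.tsv"))
    r
  })
  note("qc", "qc_report.tsv",
       list(geno_max = config$geno_max, maf_min = config$maf_min,
            hwe_min = config$hwe_min))
  panel <- qc$panel

  assoc <- stage("assoc", function() {
    a <- assoc_scan(panel, phen)
    if (config$assoc_perm > 0) {
      pp <- max_t_permutation(panel, phen, n_perm = config$assoc_perm,
                              seed = config$seed)
      a$p_perm <- pp$p_perm[match(a$snp_id, pp$snp_id)]
    }
    write_tsv(a, out("assoc.tsv"))
    a
  })
  note("assoc", "assoc.tsv", list(n_perm = config$assoc_perm))

  stage("haplo", function() {
    h <- sliding_window_assoc(panel, phen, config$haplo_window,
                              n_perm = config$haplo_perm,
                              seed = if (config$haplo_perm > 0)
                                config$seed + 1 else NULL)
    write_tsv(h, out("haplotype.tsv"))
    if (!is.null(config$blocks_around)) {
      top <- which.min(assoc$p)
      lo <- max(1, top - config$blocks_around)
      hi <- min(n_snps(panel), top + config$blocks_around)
      bl <- gabriel_blocks(panel, panel$snps$snp_id[lo:hi])
      write_tsv(bl, out("blocks.tsv"))
    }
  })
  note("haplo", c("haplotype.tsv",
                  if (!is.null(config$blocks_around)) "blocks.tsv"),
       list(window = config$haplo_window, n_perm = config$haplo_perm))

  stage("loh", function() {
    l <- loh_scan(panel, phen, config$loh_alpha)
    write_tsv(l, out("loh.tsv"))
    fl <- call_frequent_loh(l, config$loh_alpha)
    write_tsv(fl, out("frequent_loh.tsv"))
    rg <- call_microdeletions(panel$snps$snp_id, fl$snp_id,
                              config$loh_min_run, panel)
    write_tsv(rg, out("regions.tsv"))
  })
  note("loh", c("loh.tsv", "frequent_loh.tsv", "regions.tsv"),
       list(alpha = config$loh_alpha, min_run = config$loh_min_run))

  stage("roh", function() {
    r <- roh_summary(panel, phen, config$roh)
    write_tsv(r$segments, out("roh_segments.tsv"))
    write_tsv(r$per_sample, out("roh_per_sample.tsv"))
  })
  note("roh", c("roh_segments.tsv", "roh_per_sample.tsv"),
       unclass(config$roh))

  if (!is.null(config$ct_table)) {
    stage("qpcr", function() {
      ct <- utils::read.table(config$ct_table, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      fc <- qpcr_paired_analysis(ct)
      write_tsv(fc$per_pair, out("qpcr.tsv"))
      write_tsv(fc$tests, out("qpcr_tests.tsv"))
    })
    note("qpcr", c("qpcr.tsv", "qpcr_tests.tsv"))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Paired tumor/normal 2^-ddCt analysis of a long Ct table
#'
#' For every pair id the tumor specimen's fold change is computed against its
#' own normal tissue, then the pairs are tested with [paired_tests()].
#'
#' @param ct data.frame: `sample_id`, `tissue` (`tumor`/`normal`), `gene`,
#'   `role`, `replicate`, `ct`
#' @return list: `per_pair` (fold change per pair) and `tests`
#' @export
qpcr_paired_analysis <- function(ct) {
  ids <- unique(ct$sample_id)
  grab <- function(id, tissue, role) {
    ct$ct[ct$sample_id == id & ct$tissue == tissue & ct$role == role]
  }
  rows <- list()
  for (id in ids) {
    fc <- delta_delta_ct(grab(id, "tumor", "target"),
                         grab(id, "tumor", "endogenous_control"),
                         grab(id, "normal", "target"),
                         grab(id, "normal", "endogenous_control"))
    rows[[length(rows) + 1]] <- cbind(
      data.frame(sample_id = id, stringsAsFactors = FALSE), fc)
  }
  per_pair <- do.call(rbind, rows)
  tests <- paired_tests(per_pair$delta_ct_sample, per_pair$delta_ct_ref)
  list(per_pair = per_pair, tests = tests)
}

#' Human-readable run report
#'
#' Summarises a completed run: top SNPs and haplotypes, called micro-deletion
#' regions, the ROH screen and the expression verdicts, with a pointer to
#' every file the run wrote.
#'
#' @param out_dir the pipeline output directory (must contain
#'   `manifest.json`)
#' @param top_n how many top associations to list (default 5)
#' @return character vector of Markdown lines (also written to `report.md`)
#' @export
report_summary <- function(out_dir, top_n = 5) {
  mf_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("incomplete run: no manifest in ", out_dir)
  mf <- jsonlite::read_json(mf_path)
  rd <- function(name) utils::read.table(file.path(out_dir, name),
                                         header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE)
  lines <- c("# Pipeline run report", "")
  a <- rd("assoc.tsv")
  a <- a[order(a$p), ]
  lines <- c(lines, "## Top single-SNP associations", "")
  for (i in seq_len(min(top_n, nrow(a))))
    lines <- c(lines, sprintf("- %s: OR %.3f (%.3f-%.3f), p = %.3g",
                              a$snp_id[i], a$or_[i], a$ci_low[i],
                              a$ci_high[i], a$p[i]))
  h <- rd("haplotype.tsv")
  h <- h[order(h$p), ]
  lines <- c(lines, "", "## Top haplotypes", "")
  for (i in seq_len(min(top_n, nrow(h))))
    lines <- c(lines, sprintf("- window %s [%s]: f_case %.3f f_ctrl %.3f p = %.3g",
                              h$snp_ids[i], h$haplotype[i], h$freq_case[i],
                              h$freq_ctrl[i], h$p[i]))
  rg <- rd("regions.tsv")
  lines <- c(lines, "", "## Micro-deletion regions", "")
  if (!nrow(rg)) lines <- c(lines, "- no micro-deletions called")
  else for (i in seq_len(nrow(rg)))
    lines <- c(lines, sprintf("- %s..%s (%d SNPs)", rg$start_snp[i],
                              rg$end_snp[i], rg$n_snps[i]))
  rs <- rd("roh_per_sample.tsv")
  lines <- c(lines, "", "## Runs of homozygosity", "",
             sprintf("- %d of %d samples carry at least one ROH segment",
                     sum(rs$n_segments > 0), nrow(rs)))
  if ("qpcr" %in% names(mf$stages)) {
    qt <- rd("qpcr_tests.tsv")
    lines <- c(lines, "", "## Expression follow-up", "",
               sprintf("- %d/%d pairs down-regulated; paired t p = %.3g, Wilcoxon p = %.3g",
                       qt$n_down, qt$n_total, qt$t_p, qt$wilcoxon_p))
  }
  files <- unlist(lapply(mf$stages, function(s) unlist(s$files)))
  lines <- c(lines, "", "## Files", "",
             paste0("- ", unname(files)))
  writeLines(lines, file.path(out_dir, "report.md"))
  lines
}
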