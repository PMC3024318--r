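#' Homozygous genotype frequency in one stratum
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param snp_id SNP identifier
#' @param group `"case"` or `"control"`
#' @return (hom_a + hom_b count) / (non-missing count)
#' @export
homozygosity_freq <- function(panel, phen, snp_id, group = c("case",
                                                             "control")) {
  group <- match.arg(group)
  masks <- status_masks(panel, phen)
  g <- panel$calls[masks[[group]], snp_index(panel, snp_id)]
  g <- g[!is.na(g)]
  if (!length(g)) stop("no non-missing calls in ", group, " group for ",
                       snp_id)
  mean(g != 1L)
}

#' T/N homozygosity ratio
#'
#' The case-to-control ratio of per-SNP homozygous genotype frequency.  A
#' hemizygous micro-deletion makes carriers look homozygous for the surviving
#' allele, so an excess ratio above 1 marks candidate allelic-imbalance loci.
#'
#' @param f_case homozygous frequency in cases
#' @param f_ctrl homozygous frequency in controls; must be positive
#' @return `f_case / f_ctrl`
#' @export
tn_ratio <- function(f_case, f_ctrl) {
  stopifnot(f_case >= 0, f_case <= 1, f_ctrl >= 0, f_ctrl <= 1)
  if (f_ctrl == 0) stop("T/N ratio undefined: control homozygosity is zero")
  f_case / f_ctrl
}

#' Homozygous-vs-heterozygous case-control test at one SNP
#'
#' Pearson chi-square (df = 1, no correction) on the 2x2 table of
#' case/control by homozygous/heterozygous, plus the T/N ratio.  A locus is a
#' frequent-LOH candidate when the T/N ratio strictly exceeds 1 and the
#' p-value is strictly below `alpha`.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param snp_id SNP identifier
#' @param alpha significance threshold used for the flag (default 0.05)
#' @return one-row data.frame: `snp_id`, `f_hom_case`, `f_hom_ctrl`,
#'   `tn_ratio`, `chi2`, `p`, `is_frequent_loh`, `degenerate`
#' @export
homozygosity_test <- function(panel, phen, snp_id, alpha = 0.05) {
  masks <- status_masks(panel, phen)
  j <- snp_index(panel, snp_id)
  gc <- panel$calls[masks$case, j]; gc <- gc[!is.na(gc)]
  gn <- panel$calls[masks$control, j]; gn <- gn[!is.na(gn)]
  if (!length(gc) || !length(gn)) stop("empty stratum at ", snp_id)
  tab <- matrix(c(sum(gc != 1L), sum(gn != 1L),
                  sum(gc == 1L), sum(gn == 1L)), 2, 2)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  ct <- pearson_chi2(tab)
  f_case <- mean(gc != 1L)
  f_ctrl <- mean(gn != 1L)
  tn <- if (f_ctrl > 0) f_case / f_ctrl else NA_real_
  data.frame(snp_id = snp_id, f_hom_case = f_case, f_hom_ctrl = f_ctrl,
             tn_ratio = tn, chi2 = ct$chi2, p = ct$p,
             is_frequent_loh = !is.na(tn) && tn > 1 && ct$p < alpha,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Homozygosity scan across a panel
#'
#' [homozygosity_test()] applied to every SNP, in panel order.
#'
#' @inheritParams homozygosity_test
#' @return data.frame, one row per SNP
#' @export
loh_scan <- function(panel, phen, alpha = 0.05) {
  rows <- lapply(panel$snps$snp_id, function(s)
    homozygosity_test(panel, phen, s, alpha))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter loci to frequent-LOH candidates
#'
#' Keeps loci with `tn_ratio > 1` and `p < alpha` (both strict), preserving
#' input order.
#'
#' @param loci data.frame with columns `tn_ratio` and either `p` or `p_value`
#' @param alpha significance threshold (default 0.05)
#' @return the filtered data.frame
#' @export
call_frequent_loh <- function(loci, alpha = 0.05) {
  p <- if ("p" %in% names(loci)) loci$p else loci$p_value
  loci[!is.na(loci$tn_ratio) & loci$tn_ratio > 1 & p < alpha, , drop = FALSE]
}

#' Call micro-deletion regions from adjacent frequent-LOH loci
#'
#' A region is a maximal run of at least `min_run` consecutive panel SNPs
#' that are all frequent-LOH.  Adjacency means consecutive position in the
#' full ordered panel supplied here (typically the QC-passed marker set), not
#' adjacency among significant loci only.
#'
#' @param panel_order character vector of SNP ids in panel (position) order
#' @param frequent_loh_ids ids flagged frequent-LOH; must be a subset of
#'   `panel_order`
#' @param min_run minimum run length (default 3)
#' @param panel optional `genotype_panel` used to annotate chrom/start/end
#' @return data.frame of regions, position-sorted and disjoint: `start_snp`,
#'   `end_snp`, `n_snps`, `snp_ids` plus `chrom`, `start_pos`, `end_pos` when
#'   a panel is given
#' @export
call_microdeletions <- function(panel_order, frequent_loh_ids, min_run = 3,
                                panel = NULL) {
  unknown <- setdiff(frequent_loh_ids, panel_order)
  if (length(unknown))
    stop("frequent-LOH ids absent from panel: ",
         paste(unknown, collapse = ", "))
  flag <- panel_order %in% frequent_loh_ids
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(empty_regions(!is.null(panel)))
  rows <- lapply(which(keep), function(k) {
    ids <- panel_order[starts[k]:ends[k]]
    out <- data.frame(start_snp = ids[1], end_snp = ids[length(ids)],
                      n_snps = length(ids),
                      snp_ids = paste(ids, collapse = ","),
                      stringsAsFactors = FALSE)
    if (!is.null(panel)) {
      i1 <- snp_index(panel, ids[1]); i2 <- snp_index(panel, ids[length(ids)])
      out$chrom <- panel$snps$chrom[i1]
      out$start_pos <- panel$snps$pos[i1]
      out$end_pos <- panel$snps$pos[i2]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_regions <- function(with_pos) {
  out <- data.frame(start_snp = character(0), end_snp = character(0),
                    n_snps = integer(0), snp_ids = character(0),
                    stringsAsFactors = FALSE)
  if (with_pos) {
    out$chrom <- character(0); out$start_pos <- integer(0)
    out$end_pos <- integer(0)
  }
  out
}
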