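#' Runs-of-homozygosity parameters
#'
#' Scanning-window internals default to the common PLINK settings (50-SNP
#' window, at most 1 heterozygote and 5 missing calls per homozygous window,
#' 5% hit threshold); segment-level criteria default to 1,000 kb minimum
#' length, 100 SNPs, 50 kb/SNP maximum density and a 1,000 kb maximum gap.
#'
#' @param window_snps scanning window size in SNPs
#' @param window_het_max maximum heterozygous calls for a window to count as
#'   homozygous
#' @param window_missing_max maximum missing calls per homozygous window
#' @param hit_threshold minimum fraction of overlapping homozygous windows
#'   for a SNP to be in-run, in (0, 1]
#' @param seg_min_length_kb minimum segment length (kb)
#' @param seg_min_snps minimum SNPs per segment
#' @param seg_max_density_kb_per_snp maximum kb per SNP within a segment
#' @param seg_max_gap_kb largest allowed gap between consecutive in-run SNPs;
#'   larger gaps split the run before the segment criteria apply
#' @return list of class `roh_params`
#' @export
roh_params <- function(window_snps = 50, window_het_max = 1,
                       window_missing_max = 5, hit_threshold = 0.05,
                       seg_min_length_kb = 1000, seg_min_snps = 100,
                       seg_max_density_kb_per_snp = 50,
                       seg_max_gap_kb = 1000) {
  p <- list(window_snps = window_snps, window_het_max = window_het_max,
            window_missing_max = window_missing_max,
            hit_threshold = hit_threshold,
            seg_min_length_kb = seg_min_length_kb,
            seg_min_snps = seg_min_snps,
            seg_max_density_kb_per_snp = seg_max_density_kb_per_snp,
            seg_max_gap_kb = seg_max_gap_kb)
  stopifnot(all(unlist(p) > 0), hit_threshold <= 1)
  class(p) <- "roh_params"
  p
}

# in-run flags for one sample on one position-sorted chromosome
roh_in_run <- function(g, params) {
  m <- length(g)
  W <- params$window_snps
  if (W > m) return(rep(FALSE, m))
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  csh <- c(0, cumsum(het))
  csm <- c(0, cumsum(mis))
  nw <- m - W + 1
  i <- seq_len(nw)
  win_hom <- as.integer(csh[i + W] - csh[i] <= params$window_het_max &
                          csm[i + W] - csm[i] <= params$window_missing_max)
  cwh <- c(0, cumsum(win_hom))
  j <- seq_len(m)
  lo <- pmax(1L, j - W + 1L)
  hi <- pmin(j, nw)
  n_over <- hi - lo + 1L
  n_hom <- cwh[hi + 1] - cwh[lo]
  frac <- n_hom / n_over
  frac >= params$hit_threshold
}

#' Detect runs of homozygosity for one sample
#'
#' Slides a window of `window_snps` SNPs across each chromosome one SNP at a
#' time, marks windows homozygous when they carry few enough heterozygous and
#' missing calls, computes per SNP the fraction of overlapping windows that
#' are homozygous (edge SNPs use the reduced number of overlapping windows),
#' and flags the SNP in-run when the fraction reaches `hit_threshold`.
#' Maximal in-run stretches are split at inter-SNP gaps above
#' `seg_max_gap_kb`, then reported as segments when they meet the minimum
#' length, SNP count and density criteria.
#'
#' @param panel a `genotype_panel` (SNPs position-sorted)
#' @param sample_id sample to scan
#' @param params a [roh_params()] list
#' @return data.frame of segments: `sample_id`, `chrom`, `start_pos`,
#'   `end_pos`, `n_snps`, `length_kb`; zero rows (with a warning) when the
#'   window exceeds the panel
#' @export
detect_roh <- function(panel, sample_id, params = roh_params()) {
  row <- match(sample_id, rownames(panel$calls))
  if (is.na(row)) stop("unknown sample: ", sample_id)
  segs <- list()
  for (ch in unique(panel$snps$chrom)) {
    sel <- which(panel$snps$chrom == ch)
    g <- panel$calls[row, sel]
    pos <- panel$snps$pos[sel]
    if (params$window_snps > length(sel)) {
      warning("window_snps (", params$window_snps,
              ") exceeds panel size on chrom ", ch)
      next
    }
    flag <- roh_in_run(g, params)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      # the gap rule splits the run before segment criteria are applied
      gaps <- diff(pos[idx]) / 1000
      cut_after <- which(gaps > params$seg_max_gap_kb)
      piece_start <- c(1, cut_after + 1)
      piece_end <- c(cut_after, length(idx))
      for (pc in seq_along(piece_start)) {
        pidx <- idx[piece_start[pc]:piece_end[pc]]
        n <- length(pidx)
        len_kb <- (pos[pidx[n]] - pos[pidx[1]]) / 1000
        if (n >= params$seg_min_snps &&
            len_kb >= params$seg_min_length_kb &&
            len_kb / n <= params$seg_max_density_kb_per_snp) {
          segs[[length(segs) + 1]] <- data.frame(
            sample_id = sample_id, chrom = ch,
            start_pos = pos[pidx[1]], end_pos = pos[pidx[n]],
            n_snps = n, length_kb = len_kb, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_snps = integer(0), length_kb = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Cohort-level ROH summary
#'
#' Runs [detect_roh()] on every sample and tabulates segments per sample and,
#' per SNP, how many samples' segments cover it.
#'
#' @param panel a `genotype_panel`
#' @param phen matching `phenotype_table`
#' @param params a [roh_params()] list
#' @return list: `segments` (all segments), `per_sample` (`sample_id`,
#'   `status`, `n_segments`), `per_snp` (`snp_id`, `n_samples_covered`)
#' @export
roh_summary <- function(panel, phen, params = roh_params()) {
  ids <- rownames(panel$calls)
  all_segs <- lapply(ids, function(s) suppressWarnings(
    detect_roh(panel, s, params)))
  segments <- do.call(rbind, all_segs)
  n_seg <- vapply(all_segs, nrow, 0L)
  idx <- match(ids, phen$sample_id)
  per_sample <- data.frame(sample_id = ids,
                           status = as.character(phen$status[idx]),
                           n_segments = n_seg, stringsAsFactors = FALSE)
  cov <- integer(n_snps(panel))
  if (nrow(segments)) {
    for (r in seq_len(nrow(segments))) {
      hit <- panel$snps$chrom == segments$chrom[r] &
        panel$snps$pos >= segments$start_pos[r] &
        panel$snps$pos <= segments$end_pos[r]
      cov <- cov + hit
    }
  }
  per_snp <- data.frame(snp_id = panel$snps$snp_id,
                        n_samples_covered = cov, stringsAsFactors = FALSE)
  list(segments = segments, per_sample = per_sample, per_snp = per_snp)
}
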