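#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are averaged (arithmetic mean), then
#' `dCt = Ct_target - Ct_endogenous` within each specimen,
#' `ddCt = dCt_sample - dCt_reference`, and the fold change is `2^-ddCt`
#' (amplification efficiency 2 assumed, as the method requires).
#'
#' @param ct_target_sample,ct_control_sample numeric Ct replicates for the
#'   target and endogenous-control gene in the specimen of interest
#' @param ct_target_ref,ct_control_ref the same in the reference specimen
#' @param unchanged_below |log2 fold| below which `direction` is reported as
#'   `"unchanged"` (reporting only; default 0.1)
#' @return one-row data.frame: `delta_ct_sample`, `delta_ct_ref`,
#'   `delta_delta_ct`, `fold_change`, `direction`
#' @export
delta_delta_ct <- function(ct_target_sample, ct_control_sample,
                           ct_target_ref, ct_control_ref,
                           unchanged_below = 0.1) {
  vals <- list(ct_target_sample, ct_control_sample, ct_target_ref,
               ct_control_ref)
  if (any(vapply(vals, function(v) !length(v) || anyNA(v), TRUE)))
    stop("missing Ct values (endogenous control required for every specimen)")
  if (any(unlist(vals) <= 0)) stop("Ct values must be positive")
  dct_s <- mean(ct_target_sample) - mean(ct_control_sample)
  dct_r <- mean(ct_target_ref) - mean(ct_control_ref)
  ddct <- dct_s - dct_r
  fold <- 2^(-ddct)
  direction <- if (abs(ddct) < unchanged_below) "unchanged"
  else if (ddct < 0) "up" else "down"
  data.frame(delta_ct_sample = dct_s, delta_ct_ref = dct_r,
             delta_delta_ct = ddct, fold_change = fold,
             direction = direction, stringsAsFactors = FALSE)
}

#' Paired tumor/normal tests on ddCt values
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test on the per-pair
#' dCt differences (tumor minus normal, log2 scale), as used for paired
#' biopsy follow-up.  The Wilcoxon test is exact for n <= 25 (no ties).
#' `n_down` counts pairs whose tumor fold change is below 1 (positive ddCt).
#'
#' @param delta_ct_tumor,delta_ct_normal numeric vectors of per-pair dCt
#'   values (same order)
#' @return one-row data.frame: `t_stat`, `t_df`, `t_p`, `wilcoxon_p`,
#'   `n_down`, `n_total`, `degenerate`
#' @export
paired_tests <- function(delta_ct_tumor, delta_ct_normal) {
  stopifnot(length(delta_ct_tumor) == length(delta_ct_normal))
  n <- length(delta_ct_tumor)
  if (n < 2) stop("need at least 2 pairs")
  d <- delta_ct_tumor - delta_ct_normal   # ddCt per pair
  if (all(d == 0) || stats::sd(d) == 0) {
    return(data.frame(t_stat = NA_real_, t_df = n - 1, t_p = 1,
                      wilcoxon_p = 1, n_down = sum(d > 0), n_total = n,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  tt <- stats::t.test(delta_ct_tumor, delta_ct_normal, paired = TRUE)
  wx <- suppressWarnings(
    stats::wilcox.test(d, exact = n <= 25 && !any(d == 0) &&
                         !anyDuplicated(abs(d))))
  data.frame(t_stat = unname(tt$statistic), t_df = unname(tt$parameter),
             t_p = tt$p.value, wilcoxon_p = wx$p.value,
             n_down = sum(d > 0), n_total = n, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Fold changes of cell lines against a reference line
#'
#' 2^-ddCt per line and gene relative to the reference cell line, from a long
#' Ct table.
#'
#' @param ct_table data.frame with columns `sample_id`, `gene`, `role`
#'   (`target` / `endogenous_control`) and `ct` (one row per replicate)
#' @param reference_line `sample_id` of the reference line
#' @return data.frame: `sample_id`, `gene`, `delta_delta_ct`, `fold_change`,
#'   `direction`
#' @export
cell_line_profile <- function(ct_table, reference_line) {
  stopifnot(all(c("sample_id", "gene", "role", "ct") %in% names(ct_table)))
  if (!reference_line %in% ct_table$sample_id)
    stop("unknown reference line: ", reference_line)
  genes <- unique(ct_table$gene[ct_table$role == "target"])
  lines <- unique(ct_table$sample_id)
  grab <- function(line, gene, role) {
    ct_table$ct[ct_table$sample_id == line &
                  (if (role == "target") ct_table$gene == gene else
                     ct_table$role == "endogenous_control")]
  }
  rows <- list()
  for (gene in genes) for (line in lines) {
    fc <- delta_delta_ct(grab(line, gene, "target"),
                         grab(line, gene, "control"),
                         grab(reference_line, gene, "target"),
                         grab(reference_line, gene, "control"))
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = line, gene = gene, delta_delta_ct = fc$delta_delta_ct,
      fold_change = fc$fold_change, direction = fc$direction,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
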