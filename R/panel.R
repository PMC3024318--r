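#' Construct a genotype panel
#'
#' A `genotype_panel` bundles ordered SNP metadata with a sample-by-SNP matrix
#' of biallelic genotype codes.  Codes count copies of `allele_a`: 2 = hom_a,
#' 1 = het, 0 = hom_b, `NA` = missing.  SNPs are stored sorted by
#' `(chrom, pos)`; positions are 1-based as in MAP files.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b` and optionally `band`.
#' @param calls integer matrix, samples in rows and SNPs in columns, values in
#'   `{0, 1, 2, NA}`.  Row names are sample ids; column names must match
#'   `snps$snp_id` after sorting.
#' @return An object of class `genotype_panel` with elements `snps` and
#'   `calls`.
#' @export
genotype_panel <- function(snps, calls) {
  stopifnot(is.data.frame(snps),
            all(c("snp_id", "chrom", "pos", "allele_a", "allele_b") %in%
                  names(snps)))
  if (!"band" %in% names(snps)) snps$band <- NA_character_
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in panel: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (any(snps$pos <= 0)) stop("SNP positions must be positive")
  if (any(snps$allele_a == snps$allele_b))
    stop("allele_a must differ from allele_b")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(snps))
    stop("calls has ", ncol(calls), " columns but panel has ",
         nrow(snps), " SNPs")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  calls <- calls[, ord, drop = FALSE]
  colnames(calls) <- snps$snp_id
  if (is.null(rownames(calls)) && nrow(calls) > 0)
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  structure(list(snps = snps, calls = calls), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", nrow(x$calls), " samples x ", nrow(x$snps),
      " SNPs (", sprintf("%.2f", 100 * mean(is.na(x$calls))),
      "% missing)\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a `genotype_panel`
#' @return integer count
#' @export
n_samples <- function(panel) nrow(panel$calls)

#' @rdname n_samples
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' Construct a phenotype table
#'
#' Per-sample case/control status and the covariates used by the logistic
#' association model.  Status and sex must be known for every sample (PLINK
#' 0/-9 encodings are rejected at parse time); age may be `NA` here but the
#' covariate-adjusted logistic fit refuses incomplete covariates.
#'
#' @param sample_id character vector of unique sample ids.
#' @param status factor or character, values `case`/`control`.
#' @param age numeric, years.
#' @param sex factor or character, values `male`/`female`.
#' @return data.frame of class `phenotype_table`.
#' @export
phenotype_table <- function(sample_id, status, age, sex) {
  status <- as.character(status)
  sex <- as.character(sex)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  if (!all(status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  out <- data.frame(sample_id = as.character(sample_id),
                    status = factor(status, levels = c("control", "case")),
                    age = as.numeric(age),
                    sex = factor(sex, levels = c("male", "female")),
                    stringsAsFactors = FALSE)
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Check that a phenotype table covers every panel sample
#' @param panel a `genotype_panel`
#' @param phen a `phenotype_table`
#' @return invisibly `TRUE`; stops otherwise.
#' @export
check_panel_phenotypes <- function(panel, phen) {
  missing <- setdiff(rownames(panel$calls), phen$sample_id)
  if (length(missing))
    stop("samples without phenotype rows: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

# logical masks for the two strata, in panel row order
status_masks <- function(panel, phen) {
  idx <- match(rownames(panel$calls), phen$sample_id)
  if (anyNA(idx)) check_panel_phenotypes(panel, phen)
  st <- phen$status[idx]
  list(case = st == "case", control = st == "control")
}

#' Subset a panel by SNP ids or sample mask
#'
#' @param panel a `genotype_panel`
#' @param snp_ids character vector of SNP ids to keep (panel order preserved);
#'   `NULL` keeps all.
#' @param samples logical mask or character ids of samples to keep; `NULL`
#'   keeps all.
#' @return the subsetted `genotype_panel`
#' @export
subset_panel <- function(panel, snp_ids = NULL, samples = NULL) {
  keep <- if (is.null(snp_ids)) seq_len(n_snps(panel)) else {
    unknown <- setdiff(snp_ids, panel$snps$snp_id)
    if (length(unknown)) stop("unknown snp_id: ", paste(unknown, collapse = ", "))
    which(panel$snps$snp_id %in% snp_ids)
  }
  rows <- if (is.null(samples)) seq_len(n_samples(panel)) else if (is.logical(samples)) which(samples) else match(samples, rownames(panel$calls))
  genotype_panel(panel$snps[keep, , drop = FALSE],
                 panel$calls[rows, keep, drop = FALSE])
}

snp_index <- function(panel, snp_id) {
  i <- match(snp_id, panel$snps$snp_id)
  if (is.na(i)) stop("unknown snp_id: ", snp_id)
  i
}
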