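#' Read a PLINK-text PED/MAP pair
#'
#' Parses a whitespace-delimited PED file (FID, IID, PAT, MAT, SEX, PHENO then
#' two allele columns per SNP; `0` = missing allele) and its MAP companion
#' (chrom, snp_id, cM, pos).  Sex is 1 = male / 2 = female and phenotype
#' 1 = control / 2 = case; any other encoding is an error because downstream
#' stages need complete status and sex.  After parsing, SNPs are sorted by
#' `(chrom, pos)` and `allele_a` is re-labelled to the minor allele among
#' controls (ties and monomorphic sites fall back to the whole cohort, then to
#' first-observed order), so odds-ratio direction is deterministic across
#' files.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param covar_path optional TSV with header `sample_id<TAB>age` supplying the
#'   age covariate (PED carries no age); samples absent from it get `NA` age.
#' @return `list(panel = genotype_panel, phen = phenotype_table)`.
#' @export
read_ped_map <- function(ped_path, map_path, covar_path = NULL) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"),
                           colClasses = c("character", "character", "numeric",
                                          "integer"))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in MAP: ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  want <- 6L + 2L * m
  sample_id <- character(n)
  sex <- character(n)
  status <- character(n)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != want)
      stop("PED line ", i, " has ", length(f), " fields, expected ", want)
    sample_id[i] <- f[2]
    sex[i] <- switch(f[5], "1" = "male", "2" = "female",
                     stop("PED line ", i, ": unknown sex code '", f[5], "'"))
    status[i] <- switch(f[6], "1" = "control", "2" = "case",
                        stop("PED line ", i, ": unknown phenotype code '",
                             f[6], "'"))
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1L, 2L * m, 2L)]
    a2[i, ] <- g[seq(2L, 2L * m, 2L)]
  }
  age <- rep(NA_real_, n)
  if (!is.null(covar_path)) {
    cv <- utils::read.table(covar_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    age <- cv$age[match(sample_id, cv$sample_id)]
  }
  phen <- phenotype_table(sample_id, status, age, sex)

  calls <- matrix(NA_integer_, n, m)
  allele_a <- character(m)
  allele_b <- character(m)
  ctrl <- status == "control"
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    if (any(x1 == "0" & x2 != "0") || any(x1 != "0" & x2 == "0"))
      stop("half-missing genotype at ", map$snp_id[j])
    obs <- c(x1[!miss], x2[!miss])
    al <- unique(obs)
    if (length(al) > 2)
      stop(map$snp_id[j], " has >2 alleles: ", paste(al, collapse = ","))
    if (length(al) == 0) al <- c("0", "0")  # all-missing; placeholder
    if (length(al) == 1) al <- c(al, setdiff(c("A", "C", "G", "T", "B"), al)[1])
    # minor allele in controls, falling back to all samples, then file order
    cnt <- function(mask) {
      v <- c(x1[mask & !miss], x2[mask & !miss])
      c(sum(v == al[1]), sum(v == al[2]))
    }
    cc <- cnt(ctrl)
    if (cc[1] == cc[2]) cc <- cnt(rep(TRUE, n))
    if (cc[1] > cc[2]) al <- al[2:1]
    allele_a[j] <- al[1]; allele_b[j] <- al[2]
    g <- (x1 == al[1]) + (x2 == al[1])
    g[miss] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  rownames(calls) <- sample_id
  snps <- data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                     band = NA_character_, allele_a = allele_a,
                     allele_b = allele_b, stringsAsFactors = FALSE)
  list(panel = genotype_panel(snps, calls), phen = phen)
}

#' Write a PLINK-text PED/MAP pair
#'
#' Inverse of [read_ped_map()]: missing calls become `0 0`, sex/phenotype use
#' the 1/2 encodings.  An empty panel yields files with zero data rows.
#'
#' @param panel a `genotype_panel`.
#' @param phen matching `phenotype_table`.
#' @param ped_path,map_path output paths.
#' @param covar_path optional path for a `sample_id  age` TSV.
#' @return invisibly, `c(ped_path, map_path)`.
#' @export
write_ped_map <- function(panel, phen, ped_path, map_path, covar_path = NULL) {
  check_panel_phenotypes(panel, phen)
  s <- panel$snps
  map <- sprintf("%s\t%s\t0\t%d", s$chrom, s$snp_id, s$pos)
  writeLines(map, map_path)
  idx <- match(rownames(panel$calls), phen$sample_id)
  sex_code <- ifelse(phen$sex[idx] == "male", "1", "2")
  phe_code <- ifelse(phen$status[idx] == "case", "2", "1")
  # heterozygotes are written with alleles in lexicographic order so that
  # writing is invariant to which allele the panel labels allele_a (round
  # trips are byte-identical even after minor-allele relabelling)
  het1 <- pmin(s$allele_a, s$allele_b)
  het2 <- pmax(s$allele_a, s$allele_b)
  out <- character(n_samples(panel))
  for (i in seq_len(n_samples(panel))) {
    g <- panel$calls[i, ]
    x1 <- ifelse(is.na(g), "0",
                 ifelse(g == 2L, s$allele_a,
                        ifelse(g == 1L, het1, s$allele_b)))
    x2 <- ifelse(is.na(g), "0",
                 ifelse(g == 2L, s$allele_a,
                        ifelse(g == 1L, het2, s$allele_b)))
    id <- rownames(panel$calls)[i]
    out[i] <- paste(c(id, id, "0", "0", sex_code[i], phe_code[i],
                      rbind(x1, x2)), collapse = " ")
  }
  writeLines(out, ped_path)
  if (!is.null(covar_path)) {
    utils::write.table(
      data.frame(sample_id = phen$sample_id, age = phen$age),
      covar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(ped_path, map_path))
}

#' Load the packaged frequent-LOH summary table
#'
#' Reads the 19-row CSV transcription of the published frequent-LOH summary
#' (SNP id, cytogenetic band, T/N homozygosity ratio, p-value, gene, and a
#' flag marking rows inside called micro-deletion regions) and checks its
#' integrity.
#'
#' @param csv_path path to the fixture; defaults to the copy installed with
#'   the package.
#' @return data.frame with columns `snp_id`, `band`, `tn_ratio`, `p_value`,
#'   `gene`, `in_microdeletion`.
#' @export
load_loh_fixture <- function(csv_path = system.file("extdata",
                                                    "loh_table1.csv",
                                                    package = "loh6p")) {
  x <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("snp_id", "band", "tn_ratio", "p_value", "gene",
            "in_microdeletion")
  if (!identical(names(x), need))
    stop("fixture columns must be ", paste(need, collapse = ","))
  if (nrow(x) != 19L)
    stop("fixture integrity error: expected 19 rows, got ", nrow(x))
  if (any(x$tn_ratio <= 0) || any(x$p_value < 0) || any(x$p_value > 1))
    stop("fixture integrity error: tn_ratio/p out of range")
  x$in_microdeletion <- as.logical(x$in_microdeletion)
  x
}

#' Write a data.frame as a TSV with header
#' @param x data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
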