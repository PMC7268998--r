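#' Construct a dosage matrix
#'
#' The plaintext container for genotype dosages: an `n x m` numeric matrix
#' with individuals in rows and SNPs in columns, entries in `[0, 2]` counting
#' alternate alleles (fractional for imputed genotypes). Missing data are
#' rejected: the encryption scheme requires fully imputed input, so
#' imputation is an upstream responsibility.
#'
#' @param values numeric matrix, `n x m`, entries in `[0, 2]`, no `NA`.
#' @param snp_ids character vector of `m` SNP identifiers; defaults to the
#'   column names of `values` or `snp1..snpm`.
#' @param sample_ids character vector of `n` sample identifiers (plaintext
#'   only; stripped at encryption).
#' @param allele_freqs optional numeric vector of `m` alternate-allele
#'   frequencies in `(0, 1)`, used by population-frequency standardization.
#' @return an object of class `hegp_dosage`.
#' @export
dosage_matrix <- function(values, snp_ids = NULL, sample_ids = NULL,
                          allele_freqs = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); m <- ncol(values)
  if (n < 2L || m < 1L)
    stop("dosage matrix needs at least 2 individuals and 1 SNP", call. = FALSE)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "missing dosage at individual %d, SNP %d: HEGP requires complete data; impute genotypes upstream",
      idx[1L], idx[2L]), call. = FALSE)
  }
  if (min(values) < -1e-8 || max(values) > 2 + 1e-8)
    stop("dosages must lie in [0, 2]", call. = FALSE)
  if (is.null(snp_ids)) snp_ids <- colnames(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(n))
  stopifnot(length(snp_ids) == m, length(sample_ids) == n)
  if (!is.null(allele_freqs)) {
    stopifnot(length(allele_freqs) == m)
    if (any(allele_freqs <= 0 | allele_freqs >= 1))
      stop("allele_freqs must lie strictly in (0, 1)", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(
    list(values = values, snp_ids = as.character(snp_ids),
         sample_ids = as.character(sample_ids), allele_freqs = allele_freqs),
    class = "hegp_dosage")
}

#' @export
print.hegp_dosage <- function(x, ...) {
  cat(sprintf("<hegp_dosage> %d individuals x %d SNPs%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$allele_freqs)) "" else ", allele frequencies attached"))
  invisible(x)
}

#' @export
dim.hegp_dosage <- function(x) dim(x$values)

# columns with zero variance; names the first offender
.check_polymorphic <- function(values, snp_ids) {
  v <- apply(values, 2L, var)
  bad <- which(v <= .Machine$double.eps * 4)
  if (length(bad))
    stop(sprintf("monomorphic SNP (zero variance): %s%s",
                 snp_ids[bad[1L]],
                 if (length(bad) > 1L) sprintf(" (and %d more)", length(bad) - 1L) else ""),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a delimited dosage matrix
#'
#' Expects a header row of SNP ids and a first column of sample ids; remaining
#' cells are dosages in `[0, 2]`.
#'
#' @param path file path.
#' @param sep field separator, default tab (`fread` auto-detects if `"auto"`).
#' @return `hegp_dosage`.
#' @export
read_dosage_table <- function(path, sep = "auto") {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  sample_ids <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  dosage_matrix(vals, snp_ids = colnames(vals), sample_ids = sample_ids)
}

#' Read a PLINK-raw-style dosage table
#'
#' Whitespace-delimited with one row per individual. If the standard
#' `FID IID PAT MAT SEX PHENOTYPE` leading columns are present they are
#' dropped and `IID` used as the sample id; otherwise the first column is
#' taken as the sample id.
#'
#' @param path file path.
#' @return `hegp_dosage`.
#' @export
read_dosage_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(lead %in% colnames(dt))) {
    sample_ids <- as.character(dt[["IID"]])
    dt <- dt[, setdiff(colnames(dt), lead), drop = FALSE]
  } else {
    sample_ids <- as.character(dt[[1L]])
    dt <- dt[, -1L, drop = FALSE]
  }
  dosage_matrix(as.matrix(dt), snp_ids = colnames(dt), sample_ids = sample_ids)
}

#' Read dosages from a VCF
#'
#' Takes per-genotype dosages from the `DS` FORMAT field when present,
#' falling back to counting alternate alleles in `GT`. Coordinates and strand
#' are not interpreted; SNP ids are opaque strings (the VCF `ID`, or
#' `CHROM:POS` when missing).
#'
#' @param path VCF path (plain or bgzipped).
#' @return `hegp_dosage` (individuals in rows).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- unique(unlist(strsplit(unname(v@gt[, "FORMAT"]), ":")))
  if ("DS" %in% fmt) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    if (anyNA(gt))
      stop("missing genotypes in VCF: HEGP requires complete data; impute first",
           call. = FALSE)
    ds <- apply(gt, c(1L, 2L), function(g)
      sum(strsplit(g, "[/|]")[[1L]] != "0"))
  }
  ids <- vcfR::getID(v)
  miss <- is.na(ids) | ids == "."
  if (any(miss))
    ids[miss] <- paste0(vcfR::getCHROM(v)[miss], ":", vcfR::getPOS(v)[miss])
  # vcfR returns variants x samples; transpose to individuals x SNPs
  dosage_matrix(t(ds), snp_ids = ids, sample_ids = colnames(ds))
}

#' Write a standardized matrix as delimited text (debugging aid)
#'
#' @param sd a `hegp_standardized` object.
#' @param path output path.
#' @param digits significant digits retained.
#' @export
write_standardized <- function(sd, path, digits = 10) {
  stopifnot(inherits(sd, "hegp_standardized"))
  out <- data.frame(sample = if (is.null(sd$sample_ids))
    paste0("row", seq_len(nrow(sd$H))) else sd$sample_ids,
    signif(sd$H, digits), check.names = FALSE)
  colnames(out) <- c("sample", sd$snp_ids)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
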