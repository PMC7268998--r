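#' Standardize genotype dosages
#'
#' Turns raw dosages `G` into the standardized matrix `H` used throughout.
#' In `"population_freq"` mode column `j` becomes
#' `(G[i,j] - 2*pi_j) / sqrt(2*pi_j*(1 - pi_j))`, with `pi_j` the stored
#' alternate-allele frequency; in `"empirical"` mode each column is centred on
#' its sample mean and scaled by its sample SD (denominator `n - 1`).
#'
#' @param G a [dosage_matrix()].
#' @param mode `"population_freq"` or `"empirical"`.
#' @return numeric matrix `H` with SNP ids as column names.
#' @export
standardize_genotypes <- function(G, mode = c("empirical", "population_freq")) {
  stopifnot(inherits(G, "hegp_dosage"))
  mode <- match.arg(mode)
  vals <- G$values
  .check_polymorphic(vals, G$snp_ids)
  if (mode == "population_freq") {
    if (is.null(G$allele_freqs))
      stop("population_freq standardization needs allele_freqs on the dosage matrix",
           call. = FALSE)
    p <- G$allele_freqs
    H <- sweep(vals, 2L, 2 * p, "-")
    H <- sweep(H, 2L, sqrt(2 * p * (1 - p)), "/")
  } else {
    H <- scale(vals)  # sample SD, n - 1 denominator
    attr(H, "scaled:center") <- NULL
    attr(H, "scaled:scale") <- NULL
  }
  colnames(H) <- G$snp_ids
  rownames(H) <- G$sample_ids
  H
}

#' Standardize a numeric vector to mean 0, sample variance 1
#'
#' @param v numeric vector, length at least 2, nonconstant.
#' @return standardized vector.
#' @export
standardize_vector <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 2L)
  if (anyNA(v)) stop("missing values: impute before standardizing", call. = FALSE)
  s <- sd(v)
  if (s <= .Machine$double.eps * 4)
    stop("constant vector cannot be standardized", call. = FALSE)
  as.numeric((v - mean(v)) / s)
}

#' Bundle standardized genotypes, phenotype and covariates
#'
#' Produces the plaintext triple `{y, X, H}` that the encryptor consumes.
#' The phenotype and every covariate column are standardized to mean 0,
#' sample variance 1; genotypes per [standardize_genotypes()].
#'
#' @inheritParams standardize_genotypes
#' @param y numeric phenotype vector of length `n`.
#' @param X optional numeric covariate matrix (`n x p`); columns are
#'   standardized. `NULL` for none.
#' @return an object of class `hegp_standardized` with elements `H`, `y`,
#'   `X`, `snp_ids`, `covariate_names`, `sample_ids`.
#' @export
standardize_data <- function(G, y, X = NULL,
                             mode = c("empirical", "population_freq")) {
  H <- standardize_genotypes(G, mode)
  stopifnot(length(y) == nrow(H))
  y <- standardize_vector(y)
  covariate_names <- character(0)
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == nrow(H))
    covariate_names <- colnames(X)
    if (is.null(covariate_names)) covariate_names <- paste0("cov", seq_len(ncol(X)))
    X <- apply(X, 2L, standardize_vector)
    colnames(X) <- covariate_names
  } else {
    X <- matrix(0, nrow(H), 0L)
  }
  structure(
    list(H = H, y = y, X = X, snp_ids = colnames(H),
         covariate_names = covariate_names, sample_ids = rownames(H)),
    class = "hegp_standardized")
}

#' @export
print.hegp_standardized <- function(x, ...) {
  cat(sprintf("<hegp_standardized> n = %d, m = %d SNPs, p = %d covariates\n",
              nrow(x$H), ncol(x$H), ncol(x$X)))
  invisible(x)
}

#' Dominance indicator matrix
#'
#' `T[i,j]` is 0 where the dosage is (numerically) zero and 1 otherwise,
#' coding a dominance deviation alongside the additive dosage. For imputed,
#' fractional dosages a small threshold decides "zero".
#'
#' @param G a [dosage_matrix()].
#' @param zero_tol dosages at or below this count as homozygous reference;
#'   default 0.05.
#' @return integer 0/1 matrix, same shape and dimnames as the dosages.
#' @export
dominance_matrix <- function(G, zero_tol = 0.05) {
  stopifnot(inherits(G, "hegp_dosage"))
  T_ <- (G$values > zero_tol) * 1L
  dimnames(T_) <- dimnames(G$values)
  T_
}

#' Genomic relationship matrix
#'
#' `K = H %*% t(H) / m` from a standardized genotype matrix: the average
#' cross-product of standardized dosages, modelling phenotypic covariance
#' between individuals.
#'
#' @param H standardized genotype matrix (`n x m`).
#' @return object of class `hegp_grm`: list with `K` (`n x n`, symmetric) and
#'   `n_snps`.
#' @export
grm <- function(H) {
  H <- as.matrix(H)
  m <- ncol(H)
  if (m == 0L) stop("GRM needs at least one SNP", call. = FALSE)
  K <- tcrossprod(H) / m
  K <- (K + t(K)) / 2
  structure(list(K = K, n_snps = m), class = "hegp_grm")
}

#' @export
print.hegp_grm <- function(x, ...) {
  cat(sprintf("<hegp_grm> %d x %d from %d SNPs; mean diag %.4f\n",
              nrow(x$K), ncol(x$K), x$n_snps, mean(diag(x$K))))
  invisible(x)
}

#' SNP correlation (linkage disequilibrium) matrix
#'
#' `L = t(H) %*% H / n`: pairwise similarity between SNP dosage vectors.
#' Under empirical (sample-SD) standardization the diagonal is `(n-1)/n`
#' rather than exactly 1 — the `1/n` scaling is kept as-is rather than
#' rescaled, and the diagonal records the column variance convention in use.
#'
#' @param H standardized genotype matrix (`n x m`).
#' @return `m x m` symmetric matrix.
#' @export
snp_corr <- function(H) {
  H <- as.matrix(H)
  L <- crossprod(H) / nrow(H)
  (L + t(L)) / 2
}
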