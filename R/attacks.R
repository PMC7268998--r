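#' L1 decryption score
#'
#' The mean absolute elementwise difference between a candidate decryption
#' and the true standardized genotypes; a candidate scoring below the
#' threshold (default 0.4) is "good" — visually close to the plaintext.
#' Requires the plaintext, so it is an evaluation harness for key quality,
#' not an attack an adversary could run.
#'
#' @param H_true,H_candidate equal-shape numeric matrices.
#' @param threshold score below which the candidate counts as good.
#' @return object of class `hegp_attack_score`: list with `l1`, `good`,
#'   `threshold`.
#' @export
l1_score <- function(H_true, H_candidate, threshold = 0.4) {
  H_true <- as.matrix(H_true); H_candidate <- as.matrix(H_candidate)
  if (!identical(dim(H_true), dim(H_candidate)))
    stop("matrices must have equal shape", call. = FALSE)
  l1 <- mean(abs(H_true - H_candidate))
  structure(list(l1 = l1, good = l1 < threshold, threshold = threshold),
            class = "hegp_attack_score")
}

#' @export
print.hegp_attack_score <- function(x, ...) {
  cat(sprintf("<hegp_attack_score> L1 = %.5f (%s at threshold %.2f)\n",
              x$l1, if (x$good) "good" else "poor", x$threshold))
  invisible(x)
}

#' Brute-force key search
#'
#' Samples random Stiefel candidate keys, decrypts `F` with each transpose
#' and scores against the known plaintext. The good-key rate falls roughly
#' as one in `10^(n-1)`, so the search is guarded to small `n` — even at
#' `n = 8` a key regenerating the plaintext is effectively never found.
#'
#' @param F_ encrypted genotype matrix (`n x m`).
#' @param H_true plaintext standardized genotypes.
#' @param n_trials number of candidate keys.
#' @param seed integer seed.
#' @param threshold good-key L1 threshold.
#' @param max_n guard on the key dimension (default 16); raise explicitly to
#'   override.
#' @return list with `best_score`, `score_distribution`, `good_fraction`,
#'   `n_trials`.
#' @export
brute_force_attack <- function(F_, H_true, n_trials, seed = NULL,
                               threshold = 0.4, max_n = 16L) {
  F_ <- as.matrix(F_); H_true <- as.matrix(H_true)
  n <- nrow(F_)
  if (n > max_n)
    stop(sprintf("n = %d exceeds the brute-force guard (max_n = %d); raise max_n to override",
                 n, max_n), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scores <- vapply(seq_len(n_trials), function(i) {
    P <- sample_stiefel(n)$P
    mean(abs(crossprod(P, F_) - H_true))
  }, numeric(1L))
  list(best_score = min(scores), score_distribution = scores,
       good_fraction = mean(scores < threshold), n_trials = n_trials)
}

#' Standardized dosage modes under Hardy-Weinberg equilibrium
#'
#' For a SNP with alternate-allele frequency `pi`, the standardized dosages
#' concentrate on three modes `d_g = (g - 2 pi) / sqrt(2 pi (1 - pi))` for
#' `g = 0, 1, 2` — equally spaced, with HWE-weighted mean 0 and variance 1.
#'
#' @param pi allele frequency strictly in `(0, 1)`.
#' @return numeric vector `c(d0, d1, d2)`.
#' @export
hwe_modes <- function(pi) {
  if (!is.numeric(pi) || pi <= 0 || pi >= 1)
    stop("pi must lie strictly in (0, 1)", call. = FALSE)
  (c(0, 1, 2) - 2 * pi) / sqrt(2 * pi * (1 - pi))
}

# HWE genotype-class weights (for dosages 0, 1, 2 of the ALT allele)
.hwe_weights <- function(pi) c((1 - pi)^2, 2 * pi * (1 - pi), pi^2)

#' Hardy-Weinberg kernel density for standardized dosages
#'
#' A three-component normal mixture centred at the HWE modes with kernel SD
#' `tau` and HWE genotype-class weights — the model of what a correctly
#' decrypted dosage column should look like.
#'
#' @param x evaluation points.
#' @param pi allele frequency in `(0, 1)`.
#' @param tau kernel SD, `> 0`; small values concentrate mass at the modes.
#' @return density values at `x`.
#' @export
hwe_density <- function(x, pi, tau) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  d <- hwe_modes(pi)
  w <- .hwe_weights(pi)
  (w[1L] * dnorm((x - d[1L]) / tau) +
   w[2L] * dnorm((x - d[2L]) / tau) +
   w[3L] * dnorm((x - d[3L]) / tau)) / tau
}

#' Hardy-Weinberg log objective of a candidate decryption
#'
#' The log of the product over all entries of the HWE kernel density
#' evaluated at the candidate decryption `Phi %*% F`: the objective a
#' non-Gaussianity attack would try to maximize over orthogonal `Phi`. The
#' true `t(P)` concentrates every column at its modes and scores highly;
#' note row-permutations of the truth score identically, so the maximizer is
#' not unique. Only the objective is provided — the nonconvex optimization
#' over the orthogonal group is out of scope.
#'
#' @param Phi candidate orthogonal matrix (`n x n`).
#' @param F_ encrypted genotypes (`n x m`).
#' @param freqs per-SNP allele frequencies, length `m`.
#' @param tau kernel SD (default 0.1: positive, but small enough to
#'   concentrate mass at the modes).
#' @return scalar log objective.
#' @export
hwe_objective <- function(Phi, F_, freqs, tau = 0.1) {
  Phi <- as.matrix(Phi); F_ <- as.matrix(F_)
  .assert_orthogonal(Phi)
  stopifnot(ncol(Phi) == nrow(F_), length(freqs) == ncol(F_))
  D <- Phi %*% F_
  total <- 0
  for (j in seq_len(ncol(D)))
    total <- total + sum(log(pmax(hwe_density(D[, j], freqs[j], tau),
                                  .Machine$double.xmin)))
  total
}

#' Recover a key column from a private variant
#'
#' A variant carried by exactly one individual standardizes (sample-SD
#' convention) to `sqrt(n) e_i - 1/sqrt(n)`, so its encrypted column is
#' `sqrt(n) P_i - p / sqrt(n)` with `p` the row sums of the key. Knowing
#' `p`, the carrier's key column is recovered as
#' `P_i = (F_j + p / sqrt(n)) / sqrt(n)` — the clear-cut weakness of
#' orthogonal encryption.
#'
#' The inversion itself cannot fail: for any standardized column the
#' recovered vector has unit norm exactly (`t(P) p = 1` and columns of `H`
#' sum to zero), so a non-private column yields a well-formed but useless
#' estimate. Detection of that misuse is distributional: when per-SNP
#' `freqs` are supplied, the candidate decodes the carrier's whole genotype
#' row as `t(est) %*% F_`, whose entries must cluster at the Hardy-Weinberg
#' standardized modes; a decoded row far from the modes raises an error.
#'
#' @param F_ encrypted genotype matrix.
#' @param snp_index column of `F_` suspected to be a private variant.
#' @param n cohort size (rows of `F_`).
#' @param rowsums_p row sums of the key matrix `P` (assumed guessed/known).
#' @param freqs optional per-SNP allele frequencies (length `ncol(F_)`)
#'   enabling the mode-clustering consistency check.
#' @param mode_tol maximum mean distance of decoded-row entries to their
#'   nearest HWE mode before the column is declared non-private.
#' @return numeric length-`n` estimate of the carrier's key column.
#' @export
private_variant_attack <- function(F_, snp_index, n = nrow(F_), rowsums_p,
                                   freqs = NULL, mode_tol = 0.1) {
  F_ <- as.matrix(F_)
  stopifnot(n == nrow(F_), length(rowsums_p) == n)
  fj <- F_[, snp_index]
  est <- (fj + rowsums_p / sqrt(n)) / sqrt(n)
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == ncol(F_))
    decoded <- drop(crossprod(est, F_))
    others <- setdiff(seq_len(ncol(F_)), snp_index)
    dist <- vapply(others, function(k)
      min(abs(decoded[k] - hwe_modes(freqs[k]))), numeric(1L))
    if (mean(dist) > mode_tol)
      stop(sprintf(
        "column %d is inconsistent with a private variant (decoded genotype row has mean distance %.3f to the HWE modes)",
        snp_index, mean(dist)), call. = FALSE)
  }
  est
}
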