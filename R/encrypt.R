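new_ciphertext <- function(z, W, F_, snp_ids, covariate_names,
                           flags = list(), provenance = NULL) {
  n <- length(z)
  if (is.null(provenance))
    provenance <- list(list(tag = "local", rows = c(1L, n)))
  # no sample identifiers may survive into the ciphertext
  z <- unname(as.numeric(z))
  W <- as.matrix(W)
  dimnames(W) <- list(NULL, as.character(covariate_names))
  F_ <- as.matrix(F_)
  dimnames(F_) <- list(NULL, as.character(snp_ids))
  # fill flag defaults without dropping NULL-valued entries
  all_flags <- list(quantile_normalized = FALSE, rounded_digits = NULL,
                    mixed_transform = FALSE)
  for (nm in names(flags)) all_flags[nm] <- list(flags[[nm]])
  structure(
    list(z = z, W = W, F = F_,
         snp_ids = as.character(snp_ids),
         covariate_names = as.character(covariate_names),
         n = n, m = ncol(F_), p = ncol(W),
         flags = all_flags,
         provenance = provenance),
    class = "hegp_ciphertext")
}

#' @export
print.hegp_ciphertext <- function(x, ...) {
  extra <- c(if (isTRUE(x$flags$quantile_normalized)) "quantile-normalized",
             if (!is.null(x$flags$rounded_digits))
               sprintf("rounded to %d significant digits", x$flags$rounded_digits),
             if (isTRUE(x$flags$mixed_transform)) "mixed-model transform")
  cat(sprintf("<hegp_ciphertext> n = %d, m = %d SNPs, p = %d covariates, %d block(s)%s\n",
              x$n, x$m, x$p, length(x$provenance),
              if (length(extra)) paste0(" [", paste(extra, collapse = ", "), "]") else ""))
  invisible(x)
}

.check_standardized <- function(data) {
  stopifnot(inherits(data, "hegp_standardized"))
  bad_h <- max(abs(colMeans(data$H)))
  bad_y <- abs(mean(data$y))
  bad_x <- if (ncol(data$X)) max(abs(colMeans(data$X))) else 0
  worst <- max(bad_h, bad_y, bad_x)
  if (worst > .hegp_mean_tol)
    stop(sprintf(
      "input is not standardized (column mean %.3g exceeds tolerance %.1g); run standardize_data() first",
      worst, .hegp_mean_tol), call. = FALSE)
  invisible(TRUE)
}

#' Encrypt standardized data with an orthogonal key
#'
#' Left-multiplies phenotype, covariates and genotypes by the key:
#' `z = P y`, `W = P X`, `F = P H`. Rows of the ciphertext no longer
#' correspond to individuals (each is a weighted mix of all of them), so
#' sample ids are stripped. SNP ids travel in the clear — they are needed to
#' interpret any association hits.
#'
#' @param key `hegp_key` of dimension `n`.
#' @param data `hegp_standardized` with `n` rows.
#' @return `hegp_ciphertext` holding `{z, W, F}`.
#' @export
encrypt <- function(key, data) {
  stopifnot(inherits(key, "hegp_key"))
  .check_standardized(data)
  if (key$n != nrow(data$H))
    stop(sprintf("dimension mismatch: key is %d x %d, data has %d rows",
                 key$n, key$n, nrow(data$H)), call. = FALSE)
  new_ciphertext(z = key$P %*% data$y,
                 W = key$P %*% data$X,
                 F_ = key$P %*% data$H,
                 snp_ids = data$snp_ids,
                 covariate_names = data$covariate_names)
}

#' Decrypt a ciphertext with the matching key
#'
#' The key holder's inverse: applies `t(P)`. Quantile-normalized ciphertexts
#' decrypt only approximately (the normalization is a lossy nonlinear
#' perturbation); a warning is raised and the lossy plaintext returned.
#'
#' @param key the `hegp_key` (or `hegp_block_key`) used to encrypt.
#' @param ct `hegp_ciphertext`.
#' @return `hegp_standardized` (without sample ids).
#' @export
decrypt <- function(key, ct) {
  stopifnot(inherits(ct, "hegp_ciphertext"))
  if (isTRUE(ct$flags$mixed_transform))
    stop("mixed-transform ciphertexts are not invertible with an orthogonal key",
         call. = FALSE)
  if (isTRUE(ct$flags$quantile_normalized))
    warning("ciphertext was quantile normalized: decryption is lossy")
  if (inherits(key, "hegp_block_key")) {
    if (key$n != ct$n) stop("dimension mismatch between block key and ciphertext", call. = FALSE)
    H <- .block_unapply(key, ct$F)
    y <- drop(.block_unapply(key, matrix(ct$z)))
    X <- .block_unapply(key, ct$W)
  } else {
    stopifnot(inherits(key, "hegp_key"))
    if (key$n != ct$n) stop("dimension mismatch between key and ciphertext", call. = FALSE)
    H <- crossprod(key$P, ct$F)
    y <- drop(crossprod(key$P, ct$z))
    X <- crossprod(key$P, ct$W)
  }
  colnames(H) <- ct$snp_ids
  colnames(X) <- ct$covariate_names
  structure(list(H = H, y = y, X = X, snp_ids = ct$snp_ids,
                 covariate_names = ct$covariate_names, sample_ids = NULL),
            class = "hegp_standardized")
}

#' Encrypt with a permuted block-diagonal key
#'
#' Equivalent to [encrypt()] with the dense orthogonal matrix the block key
#' implies, but never forms it: rows are permuted, then each block is rotated
#' by its own key.
#'
#' @param bk `hegp_block_key`.
#' @param data `hegp_standardized`.
#' @return `hegp_ciphertext`.
#' @export
encrypt_blocks <- function(bk, data) {
  stopifnot(inherits(bk, "hegp_block_key"))
  .check_standardized(data)
  if (bk$n != nrow(data$H))
    stop("dimension mismatch between block key and data", call. = FALSE)
  ends <- cumsum(bk$block_sizes)
  prov <- lapply(seq_along(ends), function(k)
    list(tag = sprintf("block%d", k),
         rows = c(if (k == 1L) 1L else ends[k - 1L] + 1L, ends[k])))
  new_ciphertext(z = drop(.block_apply(bk, matrix(data$y))),
                 W = .block_apply(bk, data$X),
                 F_ = .block_apply(bk, data$H),
                 snp_ids = data$snp_ids,
                 covariate_names = data$covariate_names,
                 provenance = prov)
}

#' Stack independently encrypted cohorts into one ciphertext
#'
#' Federated mega-analysis: each party encrypts its own cohort with a private
#' key; the shared ciphertexts are stacked row-wise. The result is exactly
#' what a single block-diagonal key applied to the pooled plaintext would
#' give, so it can be analyzed as one study. All parties must have imputed to
#' the same SNPs in the same order, with identically defined covariates and
#' identical hardening flags.
#'
#' @param cts list of `hegp_ciphertext`.
#' @return combined `hegp_ciphertext` with per-party provenance blocks.
#' @export
federate <- function(cts) {
  stopifnot(is.list(cts), length(cts) >= 1L,
            all(vapply(cts, inherits, logical(1L), "hegp_ciphertext")))
  ref <- cts[[1L]]
  for (i in seq_along(cts)[-1L]) {
    ct <- cts[[i]]
    if (!identical(ct$snp_ids, ref$snp_ids)) {
      d <- which(ct$snp_ids != ref$snp_ids)[1L]
      stop(sprintf("party %d SNP ids differ from party 1 (first mismatch at position %d: '%s' vs '%s')",
                   i, d, ct$snp_ids[d], ref$snp_ids[d]), call. = FALSE)
    }
    if (!identical(ct$covariate_names, ref$covariate_names))
      stop(sprintf("party %d covariates differ from party 1", i), call. = FALSE)
    if (!identical(ct$flags, ref$flags))
      stop(sprintf("party %d hardening flags differ from party 1", i), call. = FALSE)
  }
  prov <- list(); at <- 0L
  for (i in seq_along(cts)) {
    prov[[i]] <- list(tag = sprintf("party%d", i), rows = c(at + 1L, at + cts[[i]]$n))
    at <- at + cts[[i]]$n
  }
  new_ciphertext(z = unlist(lapply(cts, `[[`, "z")),
                 W = do.call(rbind, lapply(cts, `[[`, "W")),
                 F_ = do.call(rbind, lapply(cts, `[[`, "F")),
                 snp_ids = ref$snp_ids,
                 covariate_names = ref$covariate_names,
                 flags = ref$flags,
                 provenance = prov)
}

# ---- dual encryption -------------------------------------------------------

#' Dual-encrypt a restricted SNP panel for relatedness screening
#'
#' Right-multiplies the standardized genotypes at an agreed panel of test
#' SNPs by an orthogonal key: `F_R = H_R %*% P_R`. This is the mirror image
#' of the main scheme — the GRM `F_R t(F_R) = H_R t(H_R)` is preserved
#' (so duplicates and relatives can be found across cohorts) while the SNP
#' correlation structure is scrambled, making the panel useless for
#' association. All parties must use the same panel and, for cross-party
#' kinship to be meaningful, the same shared key.
#'
#' @param data `hegp_standardized`.
#' @param test_snp_ids ids of the panel SNPs (must exist in `data`).
#' @param key_R shared orthogonal key of dimension `length(test_snp_ids)`.
#' @param party_tag label carried in the output.
#' @return object of class `hegp_dual`: list with `F_R`, `test_snp_ids`,
#'   `party_tag`.
#' @export
dual_encrypt <- function(data, test_snp_ids, key_R, party_tag = "party") {
  stopifnot(inherits(data, "hegp_standardized"), inherits(key_R, "hegp_key"))
  miss <- setdiff(test_snp_ids, data$snp_ids)
  if (length(miss))
    stop(sprintf("test SNPs absent from data: %s", paste(head(miss, 3L), collapse = ", ")),
         call. = FALSE)
  if (key_R$n != length(test_snp_ids))
    stop("key_R dimension must equal the number of test SNPs", call. = FALSE)
  H_R <- data$H[, match(test_snp_ids, data$snp_ids), drop = FALSE]
  structure(list(F_R = H_R %*% key_R$P, test_snp_ids = as.character(test_snp_ids),
                 party_tag = party_tag),
            class = "hegp_dual")
}

#' Screen dual ciphertexts for cross-party relatives and duplicates
#'
#' Stacks the parties' dual ciphertexts and computes the panel GRM
#' `K_R = F t(F) / N_R`, whose cross-party entries estimate kinship between
#' individuals in different cohorts (about 1 for duplicates, 0.5 for
#' first-degree relatives, near 0 for unrelateds at panel size `N_R`).
#'
#' @param duals list of `hegp_dual` from the different parties (same panel,
#'   same shared key).
#' @param threshold report pairs with kinship at or above this; default 0.5.
#' @return a tibble with columns `party_i`, `row_i`, `party_j`, `row_j`,
#'   `kinship`, one row per flagged cross-party pair (all pairs of distinct
#'   parties). With a single party, the full panel GRM is attached as
#'   attribute `K_R` and the tibble covers within-party pairs.
#' @export
find_relatives <- function(duals, threshold = 0.5) {
  stopifnot(is.list(duals), length(duals) >= 1L,
            all(vapply(duals, inherits, logical(1L), "hegp_dual")))
  panel <- duals[[1L]]$test_snp_ids
  for (i in seq_along(duals)[-1L])
    if (!identical(duals[[i]]$test_snp_ids, panel))
      stop(sprintf("party %d used a different test-SNP panel", i), call. = FALSE)
  Fs <- lapply(duals, `[[`, "F_R")
  sizes <- vapply(Fs, nrow, integer(1L))
  F_all <- do.call(rbind, Fs)
  K <- tcrossprod(F_all) / length(panel)
  party_of <- rep(seq_along(duals), sizes)
  row_of <- unlist(lapply(sizes, seq_len))
  idx <- which(upper.tri(K) & K >= threshold, arr.ind = TRUE)
  keep <- if (length(duals) > 1L) party_of[idx[, 1L]] != party_of[idx[, 2L]] else rep(TRUE, nrow(idx))
  idx <- idx[keep, , drop = FALSE]
  out <- tibble::tibble(
    party_i = vapply(idx[, 1L], function(i) duals[[party_of[i]]]$party_tag, character(1L)),
    row_i = row_of[idx[, 1L]],
    party_j = vapply(idx[, 2L], function(i) duals[[party_of[i]]]$party_tag, character(1L)),
    row_j = row_of[idx[, 2L]],
    kinship = K[idx])
  out <- out[order(-out$kinship), ]
  if (length(duals) == 1L) attr(out, "K_R") <- K
  out
}

# ---- hardening -------------------------------------------------------------

#' Quantile-normalize an encrypted genotype matrix
#'
#' Rotated dosage columns are near-Gaussian already; replacing each column of
#' `F` by the standard normal quantiles `qnorm(rank / (n + 1))` of its ranks
#' applies a tiny nonlinear perturbation that preserves rank order (and so
#' association statistics almost exactly) while destroying the exact linear
#' relation with the plaintext — frustrating attacks that exploit residual
#' non-Gaussianity. Ties (possible only after rounding) break by original
#' row index, deterministically. `z` and `W` are left untouched.
#'
#' @param ct `hegp_ciphertext`, not already quantile normalized.
#' @return hardened `hegp_ciphertext` with the flag set.
#' @export
quantile_normalize <- function(ct) {
  stopifnot(inherits(ct, "hegp_ciphertext"))
  if (isTRUE(ct$flags$quantile_normalized))
    stop("ciphertext is already quantile normalized", call. = FALSE)
  n <- ct$n
  q <- qnorm(seq_len(n) / (n + 1))
  F_ <- apply(ct$F, 2L, function(col) q[rank(col, ties.method = "first")])
  out <- ct
  out$F <- F_
  out$flags$quantile_normalized <- TRUE
  out
}

#' Round ciphertext payloads to significant digits
#'
#' Storage/transfer hardening: fewer digits degrade decryption further at a
#' small, monotone cost in association accuracy.
#'
#' @param ct `hegp_ciphertext`.
#' @param digits significant digits to keep (`>= 1`).
#' @param round_zw also round `z` and `W`; default `TRUE`.
#' @return `hegp_ciphertext` with `rounded_digits` recorded.
#' @export
round_ciphertext <- function(ct, digits, round_zw = TRUE) {
  stopifnot(inherits(ct, "hegp_ciphertext"))
  if (!is.numeric(digits) || length(digits) != 1L || digits < 1)
    stop("digits must be a positive integer", call. = FALSE)
  digits <- as.integer(digits)
  out <- ct
  out$F <- signif(ct$F, digits)
  if (round_zw) {
    out$z <- signif(ct$z, digits)
    out$W <- signif(ct$W, digits)
  }
  out$flags$rounded_digits <- digits
  out
}

# ---- mixed-model transform encryption -------------------------------------

#' Encrypt by the mixed-model (whitening) transformation
#'
#' Multiplies the data by `A^{-1}` where `A^2 = V = sigma_g^2 K + sigma_e^2 I`,
#' optionally followed by an orthogonal rotation (`P A^{-1}`). The whitened
#' phenotype has identity covariance and the mixed-model log-likelihood (and
#' hence GWAS P-values) is preserved, but — unlike orthogonal encryption —
#' variance components and heritability can no longer be estimated from the
#' ciphertext, and SNP linkage disequilibrium is not conserved (`A^{-1}` is
#' symmetric, not orthogonal). With `n^2` free parameters it is presumably
#' harder to invert.
#'
#' @param data `hegp_standardized`.
#' @param K `hegp_grm` computed from the same data.
#' @param vc [estimate_vc_reml()] fit of `(y, X, K)`.
#' @param post_rotation optional `hegp_key` applied after whitening.
#' @return `hegp_ciphertext` flagged `mixed_transform`.
#' @export
mixed_transform_encrypt <- function(data, K, vc, post_rotation = NULL) {
  .check_standardized(data)
  stopifnot(inherits(K, "hegp_grm"), inherits(vc, "hegp_vc"))
  n <- nrow(data$H)
  stopifnot(nrow(K$K) == n)
  eK <- eigen(K$K, symmetric = TRUE)
  v <- vc$sigma_g2 * eK$values + vc$sigma_e2
  if (min(v) <= 1e-12 * max(v))
    stop("variance matrix V is singular; cannot whiten", call. = FALSE)
  # A^{-1} = E diag(1/sqrt(v)) t(E)
  Ainv <- eK$vectors %*% (t(eK$vectors) / sqrt(v))
  if (!is.null(post_rotation)) {
    stopifnot(inherits(post_rotation, "hegp_key"), post_rotation$n == n)
    Ainv <- post_rotation$P %*% Ainv
  }
  new_ciphertext(z = Ainv %*% data$y, W = Ainv %*% data$X, F_ = Ainv %*% data$H,
                 snp_ids = data$snp_ids, covariate_names = data$covariate_names,
                 flags = list(mixed_transform = TRUE))
}
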