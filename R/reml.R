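#' Estimate variance components and heritability by REML
#'
#' Fits `Var(y) = sigma_g^2 K + sigma_e^2 I` by restricted maximum
#' likelihood, working in the eigenbasis of the GRM so each candidate
#' heritability costs only O(n p) after a single eigendecomposition. The
#' restricted likelihood is profiled over `h2 = sigma_g^2 / (sigma_g^2 +
#' sigma_e^2)` on a grid of step 0.001 over `[0, 1)` and refined by
#' golden-section search — deterministic, no starting values.
#'
#' Because the eigenvalues of `P K t(P)` equal those of `K` and `t(E) y`
#' transforms consistently, the fit is identical (to numerical precision) on
#' plaintext `(y, X, K)` and ciphertext `(z, W, P K t(P))`.
#'
#' @param y phenotype (or encrypted phenotype `z`), length `n`.
#' @param X covariate matrix (or `W`), `n x p`; may have zero columns.
#' @param K `hegp_grm` (plaintext or ciphertext GRM).
#' @return object of class `hegp_vc`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `reml_loglik`, `eigvals`.
#' @export
estimate_vc_reml <- function(y, X, K) {
  stopifnot(inherits(K, "hegp_grm"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(K$K) == n)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  eK <- eigen(K$K, symmetric = TRUE)
  if (min(eK$values) < -1e-6 * max(abs(eK$values)) - 1e-8)
    stop("K is not positive semi-definite within tolerance", call. = FALSE)
  d <- pmax(eK$values, 0)
  ys <- drop(crossprod(eK$vectors, y))
  Xs <- crossprod(eK$vectors, X)
  p <- ncol(X)
  ldXX <- if (p) determinant(crossprod(X), logarithm = TRUE)$modulus else 0

  restricted_ll <- function(h2) {
    v <- h2 * d + (1 - h2)
    if (min(v) <= 0) return(-Inf)
    w <- 1 / v
    if (p) {
      XtVX <- crossprod(Xs, Xs * w)
      beta <- solve(XtVX, crossprod(Xs, ys * w))
      r <- ys - drop(Xs %*% beta)
      rss <- sum(r^2 * w)
      ldX <- determinant(XtVX, logarithm = TRUE)$modulus
    } else {
      rss <- sum(ys^2 * w)
      ldX <- 0
    }
    df <- n - p
    s2 <- rss / df
    -0.5 * (df * log(2 * pi * s2) + sum(log(v)) + ldX - ldXX + df)
  }

  grid <- seq(0, 0.999, by = 1e-3)
  ll <- vapply(grid, restricted_ll, numeric(1L))
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(restricted_ll, c(lo, hi), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  h2 <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  llmax <- max(opt$objective, ll[i])
  # recover the total-variance scale at the optimum
  v <- h2 * d + (1 - h2); w <- 1 / v
  if (p) {
    beta <- solve(crossprod(Xs, Xs * w), crossprod(Xs, ys * w))
    rss <- sum((ys - drop(Xs %*% beta))^2 * w)
  } else rss <- sum(ys^2 * w)
  s2 <- rss / (n - p)
  structure(list(sigma_g2 = h2 * s2, sigma_e2 = (1 - h2) * s2, h2 = h2,
                 reml_loglik = llmax, eigvals = d),
            class = "hegp_vc")
}

#' @export
print.hegp_vc <- function(x, ...) {
  cat(sprintf("<hegp_vc> sigma_g2 = %.5f, sigma_e2 = %.5f, h2 = %.5f (REML loglik %.3f)\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$reml_loglik))
  invisible(x)
}

#' Whitening operator for the mixed model
#'
#' Builds `A^{-1}` (and `A`) from the eigendecomposition of the GRM and
#' fitted variance components, where `A^2 = V = sigma_g^2 K + sigma_e^2 I`.
#' Applying `A^{-1}` converts generalized least squares into ordinary least
#' squares with unit residual variance.
#'
#' @param K `hegp_grm`.
#' @param vc `hegp_vc`.
#' @return object of class `hegp_whitener` with functions `apply_inv(M)` and
#'   `apply(M)`.
#' @export
whitening_operator <- function(K, vc) {
  stopifnot(inherits(K, "hegp_grm"), inherits(vc, "hegp_vc"))
  eK <- eigen(K$K, symmetric = TRUE)
  v <- vc$sigma_g2 * pmax(eK$values, 0) + vc$sigma_e2
  if (min(v) <= 1e-12 * max(v))
    stop("variance matrix V is singular", call. = FALSE)
  E <- eK$vectors
  structure(list(
    apply_inv = function(M) E %*% (crossprod(E, as.matrix(M)) / sqrt(v)),
    apply = function(M) E %*% (crossprod(E, as.matrix(M)) * sqrt(v)),
    eigvals = eK$values, v = v),
    class = "hegp_whitener")
}
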