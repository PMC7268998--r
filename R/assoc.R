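new_assoc <- function(snp_id, beta, se, stat, logP, df, model, flagged = NULL) {
  res <- tibble::tibble(snp_id = as.character(snp_id), beta = unname(beta),
                        se = unname(se), stat = unname(stat),
                        logP = unname(logP), df = df)
  if (!is.null(flagged)) res$flagged <- flagged
  structure(list(result = res, model = model), class = "hegp_assoc")
}

#' @export
print.hegp_assoc <- function(x, ...) {
  cat(sprintf("<hegp_assoc> model = %s, %d SNPs, max logP = %.3f\n",
              x$model, nrow(x$result), max(x$result$logP, na.rm = TRUE)))
  print(head(x$result))
  invisible(x)
}

# residualize columns of M on the column space of X (QR); errors on collinear X
.residualize <- function(M, X) {
  if (ncol(X) == 0L) return(M)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("covariates are collinear; drop redundant columns", call. = FALSE)
  M - qr.fitted(qx, M)
}

#' Single-SNP linear association scan
#'
#' Per-SNP ordinary least squares of the phenotype on covariates plus one
#' dosage column, identical on plaintext `(y, X, H)` and ciphertext
#' `(z, W, F)` because every quantity involved is an inner product preserved
#' by rotation. Reports the effect estimate, its SE, the t statistic and
#' `-log10` two-sided P with residual df `n - p - 1` (one less with an
#' intercept).
#'
#' @param y phenotype vector (plaintext `y` or encrypted `z`), length `n`.
#' @param M dosage-like matrix (`H`, `F`, or raw dosages), `n x m`.
#' @param X covariate matrix (or `W`), `n x p` or `NULL`.
#' @param add_intercept prepend a constant column; defaults to `FALSE`
#'   because standardized inputs are already mean-zero. Set `TRUE` for
#'   unstandardized data.
#' @param snp_ids optional ids; defaults to the column names of `M`.
#' @return `hegp_assoc`; get a tibble with [generics::tidy()].
#' @export
linear_assoc <- function(y, M, X = NULL, add_intercept = FALSE, snp_ids = NULL) {
  y <- as.numeric(y)
  M <- as.matrix(M)
  n <- length(y)
  stopifnot(nrow(M) == n)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  if (is.null(snp_ids)) snp_ids <- colnames(M)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(M)))
  df <- n - ncol(X) - 1L
  if (df < 1L) stop("not enough residual degrees of freedom", call. = FALSE)
  yr <- drop(.residualize(matrix(y), X))
  Mr <- .residualize(M, X)
  mtm <- colSums(Mr^2)
  flagged <- mtm <= .Machine$double.eps * 4 * n
  mtm_safe <- ifelse(flagged, 1, mtm)
  beta <- colSums(Mr * yr) / mtm_safe
  rss <- sum(yr^2) - beta^2 * mtm_safe
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / mtm_safe)
  stat <- beta / se
  logP <- -(pt(abs(stat), df, lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
  beta[flagged] <- NA_real_; se[flagged] <- NA_real_; stat[flagged] <- NA_real_
  logP[flagged] <- 0
  new_assoc(snp_ids, beta, se, stat, logP, df, model = "linear",
            flagged = if (any(flagged)) flagged else NULL)
}

#' Mixed-model association scan
#'
#' Whitens phenotype, covariates and dosages with `A^{-1}` (built from the
#' GRM eigendecomposition and REML variance components) and then runs the
#' ordinary least-squares scan. Works identically on plaintext and
#' ciphertext: on encrypted data pass `z`, `W`, `F` and the ciphertext GRM
#' `P K t(P)` with variance components re-estimated on the ciphertext.
#'
#' @inheritParams linear_assoc
#' @param vc `hegp_vc` estimated from the same `(y, X, K)`.
#' @param K `hegp_grm` for these individuals (plaintext or rotated).
#' @return `hegp_assoc` with model `"mixed"`.
#' @export
mixed_assoc <- function(y, X, M, vc, K, add_intercept = FALSE, snp_ids = NULL) {
  stopifnot(inherits(vc, "hegp_vc"), inherits(K, "hegp_grm"))
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(0, length(y), 0L)
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  wop <- whitening_operator(K, vc)
  if (is.null(snp_ids)) snp_ids <- colnames(M)
  out <- linear_assoc(drop(wop$apply_inv(matrix(y))),
                      wop$apply_inv(M),
                      if (ncol(X)) wop$apply_inv(X) else NULL,
                      add_intercept = FALSE, snp_ids = snp_ids)
  out$model <- "mixed"
  out
}

#' Ridge regression coefficients
#'
#' `(t(M) M + k I)^{-1} t(M) y` — invariant under any orthogonal rotation of
#' `(y, M)`, which is why genomic prediction by ridge/BLUP works unchanged on
#' ciphertext.
#'
#' @param y response (plaintext or rotated).
#' @param M predictor matrix (plaintext or rotated).
#' @param k ridge penalty, `>= 0`.
#' @return coefficient vector.
#' @export
ridge_estimate <- function(y, M, k) {
  stopifnot(k >= 0)
  M <- as.matrix(M)
  A <- crossprod(M)
  diag(A) <- diag(A) + k
  if (k == 0) {
    if (rcond(A) < .Machine$double.eps * 10)
      stop("t(M) M is singular and k = 0; increase the ridge penalty", call. = FALSE)
  }
  drop(solve(A, crossprod(M, as.numeric(y))))
}

#' Additive + dominance association at one SNP
#'
#' Fits `y ~ X + h_j + t_j` where `t_j` is the standardized dominance
#' indicator, and reports the marginal additive and dominance estimates plus
#' a 2-df joint F test against the covariate-only null. If the additive and
#' dominance columns are collinear (e.g. no homozygous-alternate carriers)
#' the model drops to the additive 1-df test with a warning.
#'
#' @param y phenotype (or `z`).
#' @param X covariates (or `W`), may be `NULL`.
#' @param H standardized dosages (or `F`).
#' @param T_std standardized dominance matrix, same shape and rotation as `H`.
#' @param j SNP index (column of `H`).
#' @return list with `beta_add`, `se_add`, `gamma_dom`, `se_dom`, `fstat`,
#'   `df1`, `df2`, `logP`.
#' @export
dominance_assoc <- function(y, X, H, T_std, j) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  h <- as.matrix(H)[, j]
  t_ <- as.matrix(T_std)[, j]
  yr <- drop(.residualize(matrix(y), X))
  D <- .residualize(cbind(h, t_), X)
  qd <- qr(D)
  df1 <- qd$rank
  if (df1 < 2L) {
    warning("additive and dominance columns are collinear at this SNP; dropping to a 1-df additive test")
    D <- D[, 1L, drop = FALSE]
    qd <- qr(D)
    df1 <- 1L
  }
  df2 <- n - ncol(X) - df1
  fit <- qr.coef(qd, yr)
  res <- yr - qr.fitted(qd, yr)
  rss1 <- sum(res^2)
  rss0 <- sum(yr^2)
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  logP <- -(pf(fstat, df1, df2, lower.tail = FALSE, log.p = TRUE)) / log(10)
  s2 <- rss1 / df2
  XtXinv <- chol2inv(qr.R(qd))
  ses <- sqrt(diag(XtXinv) * s2)
  list(beta_add = unname(fit[1L]), se_add = ses[1L],
       gamma_dom = if (df1 == 2L) unname(fit[2L]) else NA_real_,
       se_dom = if (df1 == 2L) ses[2L] else NA_real_,
       fstat = fstat, df1 = df1, df2 = df2, logP = logP)
}

# ---- logistic non-invariance demonstration --------------------------------

# overflow-safe log(1 + exp(x))
.log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

.logistic_negll <- function(theta, y, Xj) {
  eta <- drop(Xj %*% theta)
  -(sum(y * eta) - sum(.log1pexp(eta)))
}

# the rotated objective an analyst of the ciphertext would maximize: the
# invariant bilinear part uses (Py, PXj); the log-partition term only has
# PXj available, so it is evaluated on the rotated design
.rotated_negll <- function(theta, z, Wj) {
  eta <- drop(Wj %*% theta)
  -(sum(z * eta) - sum(.log1pexp(eta)))
}

#' Demonstrate that logistic regression is not preserved by rotation
#'
#' The logistic log-likelihood splits into `t(y) Xj alpha` — invariant under
#' any orthogonal `P` — and a log-partition term `sum(log(1 + exp(Xj
#' alpha)))` that transforms with the data. Maximizing the plaintext
#' likelihood and the rotated-data objective therefore gives different
#' estimates: case-control outcomes are no longer 0/1 after rotation and the
#' model ceases to be logistic. This function fits both sides by direct
#' numerical maximization and reports the discrepancy.
#'
#' After rotation the outcome is no longer 0/1 and the objective is no
#' longer a log-likelihood; it need not even be bounded above. Both
#' maximizations are therefore run inside a generous box (`|theta| <=
#' bound`); the rotated fit hitting the box is itself a symptom of the
#' broken model.
#'
#' @param y01 binary 0/1 phenotype.
#' @param X covariate matrix (an intercept column is added internally).
#' @param gj single SNP dosage-like column.
#' @param key `hegp_key` used to rotate.
#' @param bound box constraint on the parameters, default 25.
#' @return list with `theta_plain`, `theta_rotated`, `max_abs_diff`.
#' @export
logistic_invariance_report <- function(y01, X, gj, key, bound = 25) {
  stopifnot(all(y01 %in% c(0, 1)), inherits(key, "hegp_key"))
  n <- length(y01)
  if (is.null(X)) X <- matrix(0, n, 0L)
  Xj <- cbind(`(Intercept)` = 1, as.matrix(X), snp = as.numeric(gj))
  stopifnot(key$n == n)
  start <- rep(0, ncol(Xj))
  fit_p <- optim(start, .logistic_negll, y = y01, Xj = Xj,
                 method = "L-BFGS-B", lower = -bound, upper = bound,
                 control = list(maxit = 500, factr = 1e4))
  if (max(abs(fit_p$par)) > 15)
    stop("separation detected: logistic estimates diverge on the plaintext",
         call. = FALSE)
  z <- drop(key$P %*% y01)
  Wj <- key$P %*% Xj
  fit_r <- optim(start, .rotated_negll, z = z, Wj = Wj,
                 method = "L-BFGS-B", lower = -bound, upper = bound,
                 control = list(maxit = 500, factr = 1e4))
  theta_p <- fit_p$par; theta_r <- fit_r$par
  names(theta_p) <- names(theta_r) <- colnames(Xj)
  list(theta_plain = theta_p, theta_rotated = theta_r,
       max_abs_diff = max(abs(theta_p - theta_r)))
}

#' Mixed-model log-likelihood at given parameters
#'
#' Direct evaluation of `-2 log l` for the model
#' `y = X alpha + h_j beta_j + e`, `Var(e) = sigma_g^2 K + sigma_e^2 I`
#' (multivariate normal). Because the residual quadratic form, `log|V|` and
#' the data transform consistently, the value is identical on
#' `(z, W, F, P K t(P))` for any orthogonal `P` — the direct numerical
#' statement of likelihood invariance.
#'
#' @param y,X phenotype and covariates (plain or rotated).
#' @param hj single dosage column (plain or rotated); `NULL` to omit.
#' @param K `hegp_grm` (plain or rotated).
#' @param alpha,beta_j,sigma_g2,sigma_e2 parameter values.
#' @return scalar `-2 log l` including the `n log(2 pi)` constant.
#' @export
mixed_loglik <- function(y, X, hj, K, alpha, beta_j, sigma_g2, sigma_e2) {
  stopifnot(inherits(K, "hegp_grm"))
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  mu <- if (ncol(X)) drop(X %*% alpha) else 0
  if (!is.null(hj)) mu <- mu + as.numeric(hj) * beta_j
  eK <- eigen(K$K, symmetric = TRUE)
  v <- sigma_g2 * eK$values + sigma_e2
  r <- drop(crossprod(eK$vectors, y - mu))
  sum(r^2 / v) + sum(log(v)) + n * log(2 * pi)
}
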