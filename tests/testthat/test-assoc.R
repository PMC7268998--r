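test_that("linear association matches the correlation identity and calibrates", {
  set.seed(1)
  n <- 200
  y <- standardize_vector(rnorm(n))
  m1 <- standardize_vector(0.3 * y + rnorm(n))
  a <- linear_assoc(y, cbind(snp = m1), add_intercept = TRUE)
  r <- cor(y, m1)
  expect_equal(a$result$stat, r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-10)
  expect_equal(a$result$df, n - 2L)
  # without the (redundant) intercept the scan gains one residual df
  expect_equal(linear_assoc(y, cbind(snp = m1))$result$df, n - 1L)

  # type-I error calibration under the null
  co <- make_cohort(n = 500, m = 2000, h2 = 0, p_cov = 0, seed = 2)
  a0 <- linear_assoc(co$dat$y, co$dat$H)
  frac <- mean(a0$result$logP > -log10(0.05))
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)

  # degenerate SNP flagged, collinear covariates error
  M <- co$dat$H[, 1:3]; M[, 2] <- 0
  a_f <- linear_assoc(co$dat$y, M)
  expect_equal(a_f$result$logP[2], 0)
  expect_true(a_f$result$flagged[2])
  X_bad <- cbind(co$dat$H[, 1], co$dat$H[, 1] * 2)
  expect_error(linear_assoc(co$dat$y, co$dat$H, X_bad), "collinear")
})

test_that("association logP is invariant under orthogonal encryption", {
  co <- make_cohort(n = 500, m = 1000, p_cov = 2, seed = 3)
  key <- sample_stiefel(500, seed = 4)
  ct <- encrypt(key, co$dat)
  a_p <- linear_assoc(co$dat$y, co$dat$H, co$dat$X)
  a_c <- linear_assoc(ct$z, ct$F, ct$W)
  expect_lte(max(abs(a_p$result$logP - a_c$result$logP)), 1e-6)
  expect_lte(mean(abs(a_p$result$beta - a_c$result$beta)), 1e-10)
})

test_that("REML recovers simulated heritability and is rotation-invariant", {
  # parameter recovery at true h2 = 0.5 (moderate n, several replicates)
  h2_hat <- vapply(1:5, function(r) {
    co <- make_cohort(n = 600, m = 800, h2 = 0.5, p_cov = 0, seed = 100 + r)
    estimate_vc_reml(co$dat$y, NULL, grm(co$dat$H))$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.08)

  # invariance: identical fit from rotated data
  co <- make_cohort(n = 300, m = 400, h2 = 0.4, seed = 5)
  key <- sample_stiefel(300, seed = 6)
  ct <- encrypt(key, co$dat)
  vc_p <- estimate_vc_reml(co$dat$y, co$dat$X, grm(co$dat$H))
  vc_c <- estimate_vc_reml(ct$z, ct$W, grm(ct$F))
  expect_equal(vc_p$h2, vc_c$h2, tolerance = 1e-6)
  expect_equal(vc_p$reml_loglik, vc_c$reml_loglik, tolerance = 1e-6)
  # eigenvalues of PKP' equal eigenvalues of K
  expect_equal(vc_p$eigvals, vc_c$eigvals, tolerance = 1e-8)

  # pure-noise phenotype pins h2 at the boundary (large cohort)
  acc <- acceptance_cohort()
  set.seed(7)
  vc0 <- estimate_vc_reml(standardize_vector(rnorm(1000)), NULL, acc$K_plain)
  expect_lte(vc0$h2, 0.05)

  expect_error(estimate_vc_reml(co$dat$y, NULL,
                                structure(list(K = -diag(300), n_snps = 1),
                                          class = "hegp_grm")),
               "positive semi-definite")
})

test_that("mixed model reduces to OLS at sigma_g2 = 0 and finds planted signal", {
  co <- make_cohort(n = 200, m = 100, p_cov = 0, seed = 8)
  K <- grm(co$dat$H)
  vc0 <- structure(list(sigma_g2 = 0, sigma_e2 = 1, h2 = 0,
                        reml_loglik = NA, eigvals = NULL), class = "hegp_vc")
  m0 <- mixed_assoc(co$dat$y, NULL, co$dat$H, vc0, K)
  a0 <- linear_assoc(co$dat$y, co$dat$H)
  expect_lte(max(abs(m0$result$logP - a0$result$logP)), 1e-8)

  # power: one causal SNP at beta = 0.5 SD is the top hit in most replicates
  hits <- vapply(1:10, function(r) {
    set.seed(300 + r)
    G <- sim_genotypes(1000, 50, seed = 300 + r)
    H <- standardize_genotypes(G)
    y <- standardize_vector(H[, 25] * 0.5 + rnorm(1000))
    K <- grm(H)
    vc <- estimate_vc_reml(y, NULL, K)
    which.max(mixed_assoc(y, NULL, H, vc, K)$result$logP) == 25
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("mixed-model scan is invariant under encryption with independent REML fits", {
  acc <- acceptance_cohort()
  dat <- acc$cohort$dat; ct <- acc$ct
  m_p <- mixed_assoc(dat$y, dat$X, dat$H, acc$vc_plain, acc$K_plain)
  m_c <- mixed_assoc(ct$z, ct$W, ct$F, acc$vc_cipher, acc$K_cipher)
  expect_lte(mean(abs(m_p$result$logP - m_c$result$logP)), 1e-4)
})

test_that("subset GRMs computed from ciphertext equal rotated plaintext GRMs", {
  co <- make_cohort(n = 150, m = 80, seed = 9)
  key <- sample_stiefel(150, seed = 10)
  ct <- encrypt(key, co$dat)
  idx <- 1:40  # "chromosome 1"
  K_sub_cipher <- grm(ct$F[, idx])$K
  K_sub_plain <- grm(co$dat$H[, idx])$K
  expect_lte(max(abs(K_sub_cipher - key$P %*% K_sub_plain %*% t(key$P))), 1e-8)
})

test_that("ridge estimates are rotation-invariant with correct closed forms", {
  set.seed(11)
  n <- 100; q <- 8
  M <- qr.Q(qr(matrix(rnorm(n * q), n, q)))  # orthonormal columns
  y <- rnorm(n)
  expect_equal(ridge_estimate(y, M, 1), drop(crossprod(M, y)) / 2,
               tolerance = 1e-10)
  key <- sample_stiefel(n, seed = 12)
  expect_equal(ridge_estimate(key$P %*% y, key$P %*% M, 0.37),
               ridge_estimate(y, M, 0.37), tolerance = 1e-8)
  expect_lte(max(abs(ridge_estimate(y, M, 1e8))), 1e-4)
  Msing <- cbind(M[, 1], M[, 1])
  expect_error(ridge_estimate(y, Msing, 0), "singular")
})

test_that("dominance model detects recessive architecture and rotates cleanly", {
  set.seed(13)
  n <- 500
  G <- sim_genotypes(n, 30, seed = 14, maf_range = c(0.3, 0.5))
  H <- standardize_genotypes(G)
  T_raw <- dominance_matrix(G)
  T_std <- apply(T_raw, 2, standardize_vector)

  # purely additive effect: dominance estimate is null in most replicates
  cover <- vapply(1:20, function(r) {
    set.seed(500 + r)
    y <- standardize_vector(H[, 5] * 0.4 + rnorm(n))
    d <- dominance_assoc(y, NULL, H, T_std, 5)
    abs(d$gamma_dom) < 2 * d$se_dom
  }, logical(1))
  expect_gte(mean(cover), 0.9)

  # recessive effect: the 2-df joint test beats the additive-only test
  set.seed(15)
  rec <- (G$values[, 5] == 2) * 1
  y_rec <- standardize_vector(rec * 0.6 + rnorm(n))
  d2 <- dominance_assoc(y_rec, NULL, H, T_std, 5)
  a1 <- linear_assoc(y_rec, H[, 5, drop = FALSE])
  expect_gt(d2$logP, 0.5 * a1$result$logP)

  # invariance under a shared key rotating both H and T
  key <- sample_stiefel(n, seed = 16)
  d_plain <- dominance_assoc(y_rec, NULL, H, T_std, 5)
  d_rot <- dominance_assoc(key$P %*% y_rec, NULL, key$P %*% H, key$P %*% T_std, 5)
  expect_equal(d_plain$logP, d_rot$logP, tolerance = 1e-6)

  # collinear additive/dominance columns drop to 1 df with a warning
  G1 <- dosage_matrix(cbind(a = c(0, 0, 1, 1, 0, 1, 0, 1)))
  H1 <- standardize_genotypes(G1)
  T1 <- apply(dominance_matrix(G1), 2, standardize_vector)
  set.seed(17)
  expect_warning(d1 <- dominance_assoc(rnorm(8), NULL, H1, T1, 1), "collinear")
  expect_equal(d1$df1, 1L)
})

test_that("logistic regression is not preserved by rotation", {
  set.seed(18)
  n <- 500
  G <- sim_genotypes(n, 5, seed = 19, maf_range = c(0.2, 0.5))
  H <- standardize_genotypes(G)
  y01 <- sim_case_control(H, beta = log(2), causal_index = 3, seed = 20)

  rep_id <- logistic_invariance_report(y01, NULL, H[, 3], identity_key(n))
  expect_lte(rep_id$max_abs_diff, 1e-4)

  key <- sample_stiefel(n, seed = 21)
  rep_rot <- logistic_invariance_report(y01, NULL, H[, 3], key)
  expect_gt(rep_rot$max_abs_diff, 0.1)

  # the bilinear component is exactly invariant at fixed parameters
  Xj <- cbind(1, H[, 3])
  alpha <- c(0.2, 0.5)
  plain_part <- sum(y01 * (Xj %*% alpha))
  rot_part <- sum((key$P %*% y01) * ((key$P %*% Xj) %*% alpha))
  expect_equal(plain_part, rot_part, tolerance = 1e-10)

  # separation errors out
  y_sep <- as.numeric(H[, 1] > 0)
  expect_error(logistic_invariance_report(y_sep, NULL, H[, 1], key), "eparation")
})

test_that("tidiers and autoplot expose results as tibbles and ggplots", {
  co <- make_cohort(n = 100, m = 30, seed = 22)
  a <- linear_assoc(co$dat$y, co$dat$H, co$dat$X)
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("snp_id", "beta", "se", "stat", "logP", "df", "model"))
  g <- glance(a)
  expect_equal(g$n_snps, 30L)
  vc <- estimate_vc_reml(co$dat$y, co$dat$X, grm(co$dat$H))
  expect_named(glance(vc), c("sigma_g2", "sigma_e2", "h2", "reml_loglik"))
  expect_s3_class(autoplot(a), "ggplot")
  prof <- key_correlation_profile(sample_stiefel(100, seed = 23), co$dat$H)
  expect_s3_class(autoplot(prof), "ggplot")
})
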