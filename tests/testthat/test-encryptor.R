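test_that("encryption preserves SNP correlations and destroys subject structure", {
  co <- make_cohort(n = 120, m = 60, seed = 1)
  key <- sample_stiefel(120, seed = 2)
  ct <- encrypt(key, co$dat)
  expect_identical(ct$snp_ids, co$dat$snp_ids)
  expect_null(ct$sample_ids)
  # L preserved exactly
  expect_lte(max(abs(crossprod(ct$F) - crossprod(co$dat$H))), 1e-8)
  # GRM transformed: intersubject correlations destroyed
  expect_gt(max(abs(tcrossprod(ct$F) - tcrossprod(co$dat$H))), 0.1)

  ct_id <- encrypt(identity_key(120), co$dat)
  expect_equal(ct_id$F, co$dat$H, ignore_attr = TRUE)
  expect_equal(ct_id$z, co$dat$y)

  expect_error(encrypt(sample_stiefel(50, seed = 1), co$dat), "dimension mismatch")
  raw <- co$dat; raw$H <- raw$H + 1
  expect_error(encrypt(key, raw), "not standardized")
})

test_that("decryption round-trips within floating-point error", {
  co <- make_cohort(n = 80, m = 30, seed = 3)
  key <- sample_stiefel(80, seed = 4)
  ct <- encrypt(key, co$dat)
  dec <- decrypt(key, ct)
  expect_lte(mean(abs(dec$H - co$dat$H)), 1e-9)
  expect_lte(mean(abs(dec$y - co$dat$y)), 1e-9)
  expect_error(decrypt(sample_stiefel(20, seed = 1), ct), "dimension mismatch")
  expect_warning(dec_q <- decrypt(key, quantile_normalize(ct)), "lossy")
  expect_gt(mean(abs(dec_q$H - co$dat$H)), 1e-6)
})

test_that("block encryption equals the dense block-diagonal oracle", {
  co <- make_cohort(n = 200, m = 50, seed = 5)
  bk <- make_block_key(200, 100, seed = 6)
  ct <- encrypt_blocks(bk, co$dat)
  B <- block_key_matrix(bk)  # dense oracle
  expect_lte(max(abs(ct$F - B %*% co$dat$H)), 1e-10)
  expect_lte(max(abs(ct$z - drop(B %*% co$dat$y))), 1e-10)

  # single block = plain encrypt with that key
  bk1 <- make_block_key(200, 200, seed = 7)
  ct1 <- encrypt_blocks(bk1, co$dat)
  full <- as_key(block_key_matrix(bk1))
  ct1b <- encrypt(full, co$dat)
  expect_equal(ct1$F, ct1b$F, tolerance = 1e-10)

  # association is invariant under block encryption
  a_plain <- linear_assoc(co$dat$y, co$dat$H, co$dat$X)
  a_block <- linear_assoc(ct$z, ct$F, ct$W)
  expect_lte(mean(abs(a_plain$result$logP - a_block$result$logP)), 1e-6)

  expect_error(encrypt_blocks(make_block_key(100, 50, seed = 1), co$dat),
               "dimension mismatch")
})

test_that("federation equals pooled block-key analysis and validates inputs", {
  co <- make_cohort(n = 300, m = 80, p_cov = 0, seed = 8)
  parties <- split_cohort(co$G, co$ph$y, n_parties = 3, seed = 9)
  keys <- lapply(1:3, function(t) sample_stiefel(100, seed = 10 + t))
  dats <- lapply(parties, function(p) standardize_data(p$G, p$y))
  cts <- Map(encrypt, keys, dats)
  fed <- federate(cts)
  expect_equal(fed$n, 300)
  expect_length(fed$provenance, 3L)

  # oracle: stack the same per-party standardized plaintexts, encrypt with the
  # implied block-diagonal key (identity permutation), compare the mixed scan
  H_pool <- do.call(rbind, lapply(dats, `[[`, "H"))
  y_pool <- unlist(lapply(dats, `[[`, "y"))
  B <- matrix(0, 300, 300)
  at <- 0
  for (t in 1:3) { B[at + 1:100, at + 1:100] <- keys[[t]]$P; at <- at + 100 }
  expect_lte(max(abs(fed$F - B %*% H_pool)), 1e-10)

  K_fed <- grm(fed$F)
  vc_fed <- estimate_vc_reml(fed$z, NULL, K_fed)
  m_fed <- mixed_assoc(fed$z, NULL, fed$F, vc_fed, K_fed)
  K_pool <- grm(B %*% H_pool)
  vc_pool <- estimate_vc_reml(B %*% y_pool, NULL, K_pool)
  m_pool <- mixed_assoc(B %*% y_pool, NULL, B %*% H_pool, vc_pool, K_pool)
  expect_lte(mean(abs(m_fed$result$logP - m_pool$result$logP)), 1e-6)

  expect_identical(federate(cts[1])$F, cts[[1]]$F)
  shuffled <- cts[[2]]
  shuffled$snp_ids <- rev(shuffled$snp_ids)
  expect_error(federate(list(cts[[1]], shuffled)), "SNP ids differ")
  qn <- quantile_normalize(cts[[2]])
  expect_error(federate(list(cts[[1]], qn)), "flags differ")
})

test_that("dual encryption preserves the panel GRM and scrambles SNP structure", {
  co <- make_cohort(n = 150, m = 120, p_cov = 0, seed = 12)
  panel <- co$dat$snp_ids[1:100]
  key_R <- sample_stiefel(100, seed = 13)
  dual <- dual_encrypt(co$dat, panel, key_R)
  H_R <- co$dat$H[, 1:100]
  expect_lte(max(abs(tcrossprod(dual$F_R) - tcrossprod(H_R))), 1e-8)
  # columns uncorrelated with the plaintext panel columns
  rho <- vapply(1:100, function(j) cor(dual$F_R[, j], H_R[, j]), numeric(1))
  expect_lt(abs(mean(rho)), 0.05)

  dual_id <- dual_encrypt(co$dat, panel, identity_key(100))
  expect_equal(dual_id$F_R, H_R, ignore_attr = TRUE)
  expect_error(dual_encrypt(co$dat, c(panel, "nope"), key_R), "absent")
  expect_error(dual_encrypt(co$dat, panel[1:50], key_R), "dimension")
})

test_that("find_relatives flags planted duplicates and only them", {
  co <- make_cohort(n = 400, m = 120, p_cov = 0, seed = 14, maf_range = c(0.1, 0.5))
  parties <- split_cohort(co$G, co$ph$y, n_parties = 2, duplicates = 2, seed = 15)
  panel <- co$G$snp_ids[seq(1, 120, length.out = 100)]
  key_R <- sample_stiefel(100, seed = 16)
  duals <- lapply(seq_along(parties), function(t)
    dual_encrypt(standardize_data(parties[[t]]$G, parties[[t]]$y), panel, key_R,
                 party_tag = paste0("party", t)))
  hits <- find_relatives(duals, threshold = 0.5)
  strong <- hits[hits$kinship >= 0.9, ]
  expect_equal(nrow(strong), 2L)
  dup <- parties[[2]]$duplicated_from
  expect_setequal(strong$row_j, dup$party2_row)

  # null kinship fluctuates at scale 1/sqrt(N_R) = 0.1, so its extreme over
  # ~2e4 unrelated pairs sits well below the duplicate signal at 1
  expect_lt(max(hits$kinship[-(1:2)], 0), 0.9)

  solo <- find_relatives(duals[1], threshold = 2)
  expect_true(!is.null(attr(solo, "K_R")))
  expect_equal(dim(attr(solo, "K_R")), c(200L, 200L))

  bad <- duals[[2]]; bad$test_snp_ids <- rev(bad$test_snp_ids)
  expect_error(find_relatives(list(duals[[1]], bad)), "panel")
})

test_that("quantile normalization preserves ranks and association signal", {
  co <- make_cohort(n = 200, m = 100, p_cov = 0, seed = 17)
  key <- sample_stiefel(200, seed = 18)
  ct <- encrypt(key, co$dat)
  qn <- quantile_normalize(ct)
  expect_true(qn$flags$quantile_normalized)
  expect_identical(qn$z, ct$z)
  q_expect <- sort(qnorm(seq_len(200) / 201))
  for (j in c(1, 50, 100)) {
    expect_identical(order(qn$F[, j]), order(ct$F[, j]))
    expect_equal(sort(qn$F[, j]), q_expect)
  }
  expect_error(quantile_normalize(qn), "already")

  # a column that already is a permutation of the quantiles is unchanged
  ct2 <- ct
  ct2$F[, 1] <- q_expect[rank(ct$F[, 1], ties.method = "first")]
  qn2 <- quantile_normalize(ct2)
  expect_equal(qn2$F[, 1], ct2$F[, 1])
})

test_that("rounding trades decryption accuracy monotonically", {
  co <- make_cohort(n = 150, m = 80, p_cov = 0, seed = 19)
  key <- sample_stiefel(150, seed = 20)
  ct <- encrypt(key, co$dat)
  a0 <- linear_assoc(co$dat$y, co$dat$H)$result$logP

  a15 <- linear_assoc(round_ciphertext(ct, 15)$z, round_ciphertext(ct, 15)$F)
  expect_lte(mean(abs(a15$result$logP - a0)), 1e-9)

  d2 <- round_ciphertext(ct, 2); d6 <- round_ciphertext(ct, 6)
  err2 <- mean(abs(linear_assoc(d2$z, d2$F)$result$logP - a0))
  err6 <- mean(abs(linear_assoc(d6$z, d6$F)$result$logP - a0))
  expect_gt(err2, err6)
  expect_error(round_ciphertext(ct, 0), "positive")
})

test_that("mixed-transform encryption whitens, preserves logP, destroys LD", {
  co <- make_cohort(n = 300, m = 150, p_cov = 0, h2 = 0.5, seed = 21,
                    ld_rho = 0.6)
  K <- grm(co$dat$H)
  vc <- estimate_vc_reml(co$dat$y, NULL, K)
  ctA <- mixed_transform_encrypt(co$dat, K, vc)
  expect_true(ctA$flags$mixed_transform)
  # Var(z_A) = I contract: whitened phenotype has unit sample variance
  expect_equal(var(ctA$z), 1, tolerance = 0.15)
  # logP preserved vs plaintext mixed model
  m_plain <- mixed_assoc(co$dat$y, NULL, co$dat$H, vc, K)
  m_white <- linear_assoc(ctA$z, ctA$F)
  expect_lte(mean(abs(m_plain$result$logP - m_white$result$logP)), 1e-6)
  # LD is NOT conserved
  expect_gt(max(abs(crossprod(ctA$F) - crossprod(co$dat$H))), 0.1)
  expect_error(decrypt(sample_stiefel(300, seed = 1), ctA), "not invertible")

  # post-rotation variant still preserves logP
  ctAP <- mixed_transform_encrypt(co$dat, K, vc,
                                  post_rotation = sample_stiefel(300, seed = 22))
  m_rot <- linear_assoc(ctAP$z, ctAP$F)
  expect_lte(mean(abs(m_plain$result$logP - m_rot$result$logP)), 1e-6)
})

test_that("likelihood is invariant at arbitrary parameter points", {
  co <- make_cohort(n = 100, m = 40, seed = 23)
  key <- sample_stiefel(100, seed = 24)
  ct <- encrypt(key, co$dat)
  K <- grm(co$dat$H)
  Kc <- grm(ct$F)
  set.seed(25)
  for (i in 1:5) {
    alpha <- rnorm(2); beta <- rnorm(1)
    sg <- runif(1, 0.05, 1); se_ <- runif(1, 0.05, 1)
    ll_p <- mixed_loglik(co$dat$y, co$dat$X, co$dat$H[, 3], K, alpha, beta, sg, se_)
    ll_c <- mixed_loglik(ct$z, ct$W, ct$F[, 3], Kc, alpha, beta, sg, se_)
    expect_equal(ll_p, ll_c, tolerance = 1e-8)
  }
})

test_that("ciphertext containers round-trip bit-exactly and verify checksums", {
  co <- make_cohort(n = 60, m = 25, seed = 26)
  ct <- encrypt(sample_stiefel(60, seed = 27), co$dat)
  f <- withr::local_tempfile(fileext = ".hegp")
  write_ciphertext(ct, f)
  ct2 <- read_ciphertext(f)
  expect_identical(ct2$F, ct$F)
  expect_identical(ct2$z, ct$z)
  expect_identical(ct2$flags, ct$flags)
  obj <- readRDS(f); obj$z[1] <- obj$z[1] * (1 + 1e-12); saveRDS(obj, f)
  expect_error(read_ciphertext(f), "checksum")
})
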