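# Shared fixtures, generated in code. The large cohort used by the
# invariance checks is built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

# small cohort for unit tests: n individuals, m SNPs, optional covariates
make_cohort <- function(n = 100, m = 40, h2 = 0.3, p_cov = 2, seed = 42,
                        ...) {
  G <- sim_genotypes(n, m, seed = seed, ...)
  H <- standardize_genotypes(G)
  ph <- sim_phenotype(H, h2, seed = seed + 1)
  X <- if (p_cov > 0) {
    set.seed(seed + 2)
    matrix(rnorm(n * p_cov), n, p_cov,
           dimnames = list(NULL, paste0("cov", seq_len(p_cov))))
  }
  dat <- standardize_data(G, ph$y, X)
  list(G = G, dat = dat, ph = ph)
}

# the study-condition cohort (n = 1000, m = 2000, h2 = 0.3) shared by the
# homomorphism checks; one Stiefel key, plain and cipher REML fits
acceptance_cohort <- function() {
  if (!is.null(.fixture_env$acc)) return(.fixture_env$acc)
  cohort <- make_cohort(n = 1000, m = 2000, h2 = 0.3, p_cov = 2, seed = 20200422)
  key <- sample_stiefel(1000, seed = 101)
  ct <- encrypt(key, cohort$dat)
  acc <- list(cohort = cohort, key = key, ct = ct)
  acc$K_plain <- grm(cohort$dat$H)
  acc$K_cipher <- grm(ct$F)
  acc$vc_plain <- estimate_vc_reml(cohort$dat$y, cohort$dat$X, acc$K_plain)
  acc$vc_cipher <- estimate_vc_reml(ct$z, ct$W, acc$K_cipher)
  .fixture_env$acc <- acc
  acc
}
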