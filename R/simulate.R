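#' Simulate HWE genotype dosages
#'
#' Independent SNPs with dosages drawn `Binomial(2, pi_j)` (alternate-allele
#' count under Hardy-Weinberg equilibrium). Allele frequencies are drawn
#' uniformly in `maf_range` or taken from `mafs`. Monomorphic columns are
#' resampled by default (up to 50 attempts each) so downstream
#' standardization is valid; set `resample_monomorphic = FALSE` to keep them
#' and exercise the error path.
#'
#' An optional AR(1) mode induces linkage disequilibrium: adjacent SNPs share
#' latent allele gaussians with lag-1 correlation `ld_rho`, thresholded to
#' genotype classes at the HWE class boundaries, giving a nontrivial SNP
#' correlation matrix for LD-preservation tests.
#'
#' @param n individuals.
#' @param m SNPs.
#' @param maf_range length-2 numeric in `(0, 0.5]`, default `c(0.05, 0.5)`.
#' @param mafs optional explicit vector of `m` frequencies (overrides
#'   `maf_range`).
#' @param seed integer seed.
#' @param ld_rho AR(1) latent correlation between adjacent SNPs; 0 (default)
#'   gives independent SNPs.
#' @param resample_monomorphic resample constant columns (default `TRUE`).
#' @param freq_shift optional length-2 list for a crude two-subpopulation
#'   stress fixture: `list(prop = 0.5, delta = 0.1)` shifts the allele
#'   frequency of the second subpopulation by `delta` (clamped to (0.01,
#'   0.99)). Not a demographic model.
#' @return [dosage_matrix()] with `allele_freqs` set to the simulating
#'   frequencies.
#' @export
sim_genotypes <- function(n, m, maf_range = c(0.05, 0.5), mafs = NULL,
                          seed = NULL, ld_rho = 0,
                          resample_monomorphic = TRUE, freq_shift = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mafs)) {
    stopifnot(length(maf_range) == 2L, maf_range[1L] > 0, maf_range[2L] <= 0.5)
    mafs <- runif(m, maf_range[1L], maf_range[2L])
  }
  stopifnot(length(mafs) == m)
  if (ld_rho == 0) {
    G <- vapply(seq_len(m), function(j) {
      g <- rbinom(n, 2L, mafs[j])
      if (resample_monomorphic) {
        tries <- 0L
        while (var(g) == 0 && tries < 50L) {
          g <- rbinom(n, 2L, mafs[j]); tries <- tries + 1L
        }
      }
      g
    }, numeric(n))
  } else {
    stopifnot(abs(ld_rho) < 1)
    # two latent allele chains per individual; threshold at the standard
    # normal quantile of the allele frequency
    Z1 <- matrix(rnorm(n * m), n, m)
    Z2 <- matrix(rnorm(n * m), n, m)
    for (j in 2:m) {
      Z1[, j] <- ld_rho * Z1[, j - 1L] + sqrt(1 - ld_rho^2) * Z1[, j]
      Z2[, j] <- ld_rho * Z2[, j - 1L] + sqrt(1 - ld_rho^2) * Z2[, j]
    }
    thr <- qnorm(mafs)
    G <- (sweep(Z1, 2L, thr, "<") + sweep(Z2, 2L, thr, "<")) * 1
    if (resample_monomorphic) {
      for (j in which(apply(G, 2L, var) == 0)) {
        tries <- 0L
        while (var(G[, j]) == 0 && tries < 50L) {
          G[, j] <- rbinom(n, 2L, max(mafs[j], 0.05)); tries <- tries + 1L
        }
      }
    }
  }
  if (!is.null(freq_shift)) {
    n2 <- round(n * freq_shift$prop)
    rows <- seq_len(n2) + (n - n2)
    p2 <- pmin(pmax(mafs + freq_shift$delta, 0.01), 0.99)
    for (j in seq_len(m)) G[rows, j] <- rbinom(length(rows), 2L, p2[j])
  }
  dosage_matrix(G, snp_ids = sprintf("snp%04d", seq_len(m)),
                sample_ids = sprintf("ind%04d", seq_len(n)),
                allele_freqs = pmin(pmax(mafs, 1e-6), 1 - 1e-6))
}

#' Simulate an additive polygenic phenotype
#'
#' `y = H u + e` with effects `u ~ N(0, h2 / m_causal)` on the causal SNPs
#' and noise `e ~ N(0, 1 - h2)`, so the marginal phenotype variance is
#' approximately 1 and the narrow-sense heritability is `h2`.
#'
#' @param H standardized genotype matrix.
#' @param h2 heritability in `[0, 1]`.
#' @param n_causal number of causal SNPs, or `"infinitesimal"` (all SNPs).
#' @param seed integer seed.
#' @return list with `y` (length-`n` phenotype), `effects` (length-`m`, zero
#'   off the causal set), `causal` (indices).
#' @export
sim_phenotype <- function(H, h2, n_causal = "infinitesimal", seed = NULL) {
  H <- as.matrix(H)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(H); m <- ncol(H)
  causal <- if (identical(n_causal, "infinitesimal")) seq_len(m)
            else sort(sample.int(m, n_causal))
  u <- numeric(m)
  if (h2 > 0) u[causal] <- rnorm(length(causal), 0, sqrt(h2 / length(causal)))
  y <- drop(H %*% u) + rnorm(n, 0, sqrt(1 - h2))
  list(y = y, effects = u, causal = causal)
}

#' Plant a private variant
#'
#' Appends one SNP carried (dosage 1) by a single individual — the known
#' weak point of orthogonal encryption, used by the key-column recovery
#' attack.
#'
#' @param G [dosage_matrix()].
#' @param carrier_row the carrier's row index.
#' @param snp_id id for the new column.
#' @return `hegp_dosage` with one extra column.
#' @export
plant_private_variant <- function(G, carrier_row, snp_id = "private1") {
  stopifnot(inherits(G, "hegp_dosage"))
  n <- nrow(G$values)
  stopifnot(carrier_row >= 1, carrier_row <= n)
  col <- numeric(n); col[carrier_row] <- 1
  vals <- cbind(G$values, col)
  dosage_matrix(vals, snp_ids = c(G$snp_ids, snp_id),
                sample_ids = G$sample_ids,
                allele_freqs = if (is.null(G$allele_freqs)) NULL
                               else c(G$allele_freqs, 1 / (2 * n)))
}

#' Split a cohort into parties, optionally planting duplicates
#'
#' Partitions rows into `n_parties` near-equal disjoint sets over a common
#' SNP panel, then copies `duplicates` individuals from party 1 over the
#' last rows of party 2 — the fixture for cross-party relatedness screening.
#'
#' @param G [dosage_matrix()].
#' @param y phenotype vector.
#' @param X covariate matrix or `NULL`.
#' @param n_parties number of parties, `>= 1`.
#' @param duplicates individuals copied from party 1 into party 2.
#' @param seed integer seed (controls the random partition).
#' @return list of parties, each `list(G, y, X, duplicated_from)` where
#'   `duplicated_from` maps duplicated rows of party 2 back to party-1 rows.
#' @export
split_cohort <- function(G, y, X = NULL, n_parties = 2L, duplicates = 0L,
                         seed = NULL) {
  stopifnot(inherits(G, "hegp_dosage"), n_parties >= 1L)
  n <- nrow(G$values)
  stopifnot(length(y) == n)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  parts <- split(perm, rep(seq_len(n_parties), length.out = n))
  sizes <- lengths(parts)
  if (duplicates > 0L && n_parties < 2L)
    stop("duplicates need at least two parties", call. = FALSE)
  if (duplicates > min(sizes))
    stop("more duplicates than the smallest party can hold", call. = FALSE)
  out <- vector("list", n_parties)
  for (t in seq_len(n_parties)) {
    rows <- sort(parts[[t]])
    Gt <- G$values[rows, , drop = FALSE]
    dup_from <- NULL
    if (t == 2L && duplicates > 0L) {
      src <- sort(parts[[1L]])[seq_len(duplicates)]
      tgt <- seq(to = length(rows), length.out = duplicates)
      Gt[tgt, ] <- G$values[src, , drop = FALSE]
      dup_from <- data.frame(party2_row = tgt, party1_row = seq_len(duplicates))
    }
    out[[t]] <- list(
      G = dosage_matrix(Gt, snp_ids = G$snp_ids,
                        sample_ids = paste0("p", t, "_", seq_along(rows)),
                        allele_freqs = G$allele_freqs),
      y = y[rows],
      X = if (is.null(X)) NULL else as.matrix(X)[rows, , drop = FALSE],
      duplicated_from = dup_from)
    if (t == 2L && duplicates > 0L)
      out[[t]]$y[dup_from$party2_row] <- y[sort(parts[[1L]])[seq_len(duplicates)]]
  }
  out
}

#' Simulate a case-control phenotype from a logistic model
#'
#' `Pr(y = 1) = plogis(intercept + H[, causal_index] * beta)`.
#'
#' @param H standardized genotype matrix.
#' @param beta log-odds effect of the causal SNP.
#' @param causal_index column of `H` carrying the effect.
#' @param intercept baseline log-odds (default 0, prevalence 1/2).
#' @param seed integer seed.
#' @return integer 0/1 vector.
#' @export
sim_case_control <- function(H, beta, causal_index, intercept = 0, seed = NULL) {
  H <- as.matrix(H)
  stopifnot(causal_index >= 1, causal_index <= ncol(H))
  if (!is.null(seed)) set.seed(seed)
  p <- plogis(intercept + H[, causal_index] * beta)
  rbinom(nrow(H), 1L, p)
}
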