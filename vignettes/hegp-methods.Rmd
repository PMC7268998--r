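---
title: "Orthogonal homomorphic encryption for quantitative genetics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal homomorphic encryption for quantitative genetics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegp)
```

## The model

A quantitative-trait GWAS works with a phenotype vector $y$ ($n$
individuals), a covariate matrix $X$ ($n \times p$) and a dosage matrix $G$
($n \times m$ SNPs, entries in $[0,2]$ counting alternate alleles). Dosages
are standardized column-wise to $H$, either by population allele frequency,
$H_{ij} = (G_{ij} - 2\pi_j)/\sqrt{2\pi_j(1-\pi_j)}$, or empirically (sample
mean and SD); $y$ and each column of $X$ are standardized to mean 0,
variance 1. The mixed model for SNP $j$ is

$$y = X\alpha + h_j \beta_j + e, \qquad
  \mathrm{Var}(e) = V = \sigma_g^2 K + \sigma_e^2 I,$$

with the genomic relationship matrix $K = HH^{\mathsf T}/m$ and
heritability $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.

The encryption key is a random orthogonal $n \times n$ matrix $P$ and the
ciphertext is $\{z, W, F\} = \{Py, PX, PH\}$. Orthogonality gives three
facts the whole package rests on:

1. $F^{\mathsf T}F = H^{\mathsf T}H$: SNP correlations (LD) survive exactly;
2. $FF^{\mathsf T} = P\,(HH^{\mathsf T})\,P^{\mathsf T}$: the GRM is rotated
   — individual identities are destroyed but its *eigenvalues* are not,
   and the spectrum is all that REML and the whitening transform consume;
3. the Gaussian log-likelihood is invariant at every parameter point (the
   quadratic form, $\log|V|$ and the data rotate consistently), so maximum
   likelihood and REML estimates, t statistics and P-values coincide on
   plaintext and ciphertext.

Assumptions worth stating: the trait is quantitative with (approximately)
normal residuals; genotypes are fully imputed (missing data are rejected,
never imputed internally — imputation quality is an upstream
responsibility); and the analyst of the ciphertext is content with
SNP-level inference, since individual-level quantities are deliberately
destroyed. Case-control traits break the scheme: the logistic
log-likelihood splits into an invariant bilinear term $y^{\mathsf T}X_j
\alpha_j$ and a log-partition term that transforms with the data, so rotated
estimates differ — the rotated objective is not even guaranteed bounded,
which is why `logistic_invariance_report()` maximizes both sides inside a
generous box ($|\theta| \le 25$) and treats hitting the box as part of the
demonstration.

## Key generation

`sample_stiefel()` draws $P$ Haar-uniformly. The default generator follows
the polar recipe: draw $M$ with iid $N(0,1)$ entries and form
$P = M\,(M^{\mathsf T}M)^{-1/2}$. We evaluate that matrix through the SVD
$M = U S V^{\mathsf T}$, for which it equals $U V^{\mathsf T}$ — identical
in exact arithmetic to the eigendecomposition route, but stable when $M$ is
ill-conditioned (at small $n$, repeated eigen-based construction
occasionally drifted above the $10^{-8}$ orthogonality tolerance; the SVD
form stays at machine precision). A `qr_haar` generator (QR factorization
with column signs corrected by $\mathrm{sign}(\mathrm{diag}\,R)$) is
provided because it is cheaper; both are Haar-uniform and the generator is
recorded in the key metadata. Keys are serialized as full double-precision
matrices, never as RNG seeds: a seed would itself be the secret, and RNG
drift across platforms would silently change the key.

Not every orthogonal matrix is a usable key — the identity, permutations,
and anything near them leave the data recognizable.
`key_correlation_profile()` computes the per-column correlation
$\rho = x^{\mathsf T}Px/(n-1)$ between each standardized data column and
its rotation; a good key gives a null-like sample with mean
$\approx 0$ at scale $1/\sqrt{n}$. The unsuitability flag triggers when
$|\bar\rho| > 3\,\mathrm{sd}(\rho)/\sqrt{m}$ — a three-standard-error rule
on the actual data columns, chosen because the requirement is "mean close
to zero" and no sharper cut is canonical. Both mean and median absolute
off-diagonals of $P^{\mathsf T}P$ are reported by `orthogonality_error()`,
since "typical magnitude" can be read either way; at $n = 1000$ both sit
near $10^{-16}$–$10^{-13}$ depending on generator and dimension.

`build_key_path()` interpolates a one-parameter family $P(\lambda)$ with
$P(0) = I$ and $P(1) = P$ by scaling the rotation angles of the real Schur
form $P = Q T Q^{\mathsf T}$ ($T$ block-diagonal with $2 \times 2$ rotation
blocks). The real Schur route (LAPACK `dgees` via `Matrix::Schur`)
guarantees real-valued $P(\lambda)$, avoiding complex round-off leaking
into a ciphertext, and gives the group property
$P(\lambda)P(\mu) = P(\lambda+\mu)$ by construction. A key with
$\det P = -1$ contains an odd number of reflections; one $-1$ block then
has no smooth path to the identity inside the rotation group, is held
fixed, and a warning is raised (pairs of $-1$ blocks are joined into
angle-$\pi$ rotations and interpolate normally). Generic Haar draws are
affected only half the time and only on a one-dimensional subspace; key
paths are a diagnostic tool, not part of encryption proper.

For cohorts too large for one dense key, `make_block_key()` permutes
individuals randomly and encrypts blocks of at most `max_block` with
independent keys; the permutation hides the blocking and the implied full
key (block-diagonal times permutation) is orthogonal. Rounding error in
$P^{\mathsf T}P$ grows slowly with $n$, which is the other reason to block
very large cohorts.

## REML and association

`estimate_vc_reml()` profiles the restricted likelihood over
$h^2 \in [0, 1)$ on the eigenbasis of $K$: one eigendecomposition, then
each candidate $h^2$ costs $O(np)$. The profile is evaluated on a grid of
step $10^{-3}$ and refined by golden-section search in the winning
interval — deterministic, derivative-free, no starting values, and immune
to the local maxima a quasi-Newton REML can find at the $h^2$ boundary.
The total-variance scale is profiled out analytically. Invariance on
ciphertext is automatic because only the spectrum of $K$ and rotated inner
products enter.

`linear_assoc()` residualizes phenotype and dosages on the covariates once
(QR), then scans all SNPs vectorized; t statistics use residual df
$n - p - 1$ (one less with an intercept). `add_intercept` defaults to
`FALSE` because standardized inputs are mean-zero; with it, the scan
reproduces the textbook identity $t = r\sqrt{(n-2)/(1-r^2)}$. Degenerate
(constant) SNP columns are flagged with logP 0 rather than erroring a
whole scan; collinear covariates error. `mixed_assoc()` whitens with
$A^{-1} = E\,\mathrm{diag}(1/\sqrt{\sigma_g^2 d_i + \sigma_e^2})\,
E^{\mathsf T}$ and calls the same scan. No leave-one-chromosome-out
correction is applied when the GRM contains the tested SNPs; proximal
contamination is accepted as-is and documented here.

Dominance coding: $T_{ij} = 0$ iff $G_{ij} = 0$, thresholded at
`zero_tol = 0.05` for imputed dosages (the indicator is only defined for
integral dosages; 0.05 is comfortably below the smallest plausible true
dosage mass near 1). `dominance_assoc()` reports marginal additive and
dominance estimates plus the 2-df joint F test, degrading to 1 df with a
warning when the two columns are collinear (e.g. no homozygous-alternate
carriers).

Two standardization conventions deliberately coexist: the SNP correlation
matrix uses $L = H^{\mathsf T}H/n$ while empirical column standardization
uses the sample SD ($n-1$ denominator), so $\mathrm{diag}(L) = (n-1)/n$,
not 1. The mismatch is kept as-is rather than rescaled — the diagonal
simply records the variance convention — and tests assert the chosen
convention. Allele frequencies are stored and used as alternate-allele
frequencies throughout (no re-polarization to the minor allele), which
keeps standardization invertible and fixes the orientation of the
Hardy–Weinberg genotype-class weights at
$\{(1-\pi)^2, 2\pi(1-\pi), \pi^2\}$ for dosages $\{0, 1, 2\}$ — the
orientation under which the standardized modes provably have weighted mean
0 and variance 1.

## Federation, dual encryption, hardening

`federate()` stacks independently encrypted cohorts; this equals
encrypting the stacked per-cohort-standardized plaintexts with the implied
block-diagonal key, which is how the equivalence test is phrased.
Standardization is per-cohort: parties cannot pool frequencies without
sharing plaintext, so pooled standardization is not the default (the
package exposes population-frequency mode if parties agree on external
frequencies). SNP ids, covariate definitions and hardening flags must
match exactly across parties and are checked, naming the first
discrepancy.

`dual_encrypt()` right-multiplies a restricted panel,
$F_R = H_R P_R$, preserving the panel GRM while scrambling SNP structure.
Cross-party kinship requires every party to use the *same* $P_R$, so
`find_relatives()` assumes a shared key distributed out-of-band —
deliberately weaker than the main scheme, and used only to agree on a
deduplicated cohort before real sharing; revealing relationships is
inherently risky and the tool confines that risk to a 100-SNP panel. At
panel size $N_R$ the null kinship between unrelateds fluctuates at scale
$1/\sqrt{N_R}$, and a *duplicate's* kinship is a diagonal-type GRM entry
with sampling spread of the same order, so with the default
$N_R \sim 100$ the practical operating point is the 0.5 threshold
(relatives and duplicates both clear it; the null extreme over tens of
thousands of pairs stays near 0.4).

`quantile_normalize()` replaces each ciphertext genotype column by the
standard normal quantiles $\Phi^{-1}(k/(n+1))$ of its ranks. Rank order —
hence association statistics, almost exactly — is preserved, while exact
linear decryption is destroyed: on the standard cohort the round-trip
error grows from $\sim 10^{-15}$ to $\sim 4 \times 10^{-2}$ (seven orders
of magnitude) while the logP correlation with plaintext stays above 0.99.
Ties (possible only after rounding) break by original row index,
deterministically. `round_ciphertext()` keeps a stated number of
significant digits; fewer digits monotonically trade association accuracy
for decryption degradation.

`mixed_transform_encrypt()` is the alternative encryptor $A^{-1}$ (or
$PA^{-1}$): the whitened phenotype has identity covariance and mixed-model
logP is preserved, but variance components are no longer estimable from
the ciphertext and LD is not conserved ($A^{-1}$ is symmetric, not
orthogonal). Such ciphertexts refuse orthogonal decryption and the `h2`
CLI command rejects them.

## The attack suite

The package implements the evaluation attacks, not a working decryption:
`l1_score()` (mean absolute elementwise difference, "good" below 0.4 —
requiring the plaintext, so an evaluation harness only),
`brute_force_attack()` (random Stiefel candidates, guarded to $n \le 16$;
good keys appear at roughly one per $10^{n-1}$ draws and essentially never
reconstruct the plaintext), the Hardy–Weinberg mixture objective
`hwe_objective()` (kernel SD default $\tau = 0.1$: positive for imputed
dosages, small enough to concentrate mass at the modes), and
`private_variant_attack()`.

The private-variant inversion deserves a note. Under empirical
standardization a single-carrier column becomes $\sqrt{n}\,e_i -
\mathbf{1}/\sqrt{n}$, so its ciphertext is $\sqrt{n}\,P_i - p/\sqrt{n}$
with $p$ the key row sums, and $P_i = (F_j + p/\sqrt{n})/\sqrt{n}$. The
constant is derived from this package's sample-SD convention rather than
taken from any fixed formula, because it depends on the variance
denominator; the inversion oracle test (correlation $\ge 0.999$ with the
true key column) validates it. Importantly, the inversion is *exactly*
consistent for any standardized column ($P^{\mathsf T}p = \mathbf{1}$ and
mean-zero columns make the recovered vector unit-norm identically), so
misuse cannot be detected algebraically; when allele frequencies are
supplied, the candidate column is instead vetted by decoding the carrier's
genotype row ($\hat P_i^{\mathsf T} F$) and requiring it to cluster at the
per-SNP Hardy–Weinberg modes (mean distance $\le 0.1$).

The remaining attack classes — compression, pedigree
quadratic systems, incremental factorization, and independent-components
refinement — are documented in the audit report as known but are not
implemented; the nonconvex maximization of the Hardy–Weinberg objective
over the orthogonal group (Cayley-transform methods) is likewise out of
scope, with only the objective and candidate scoring provided.

## The simulator, and what passing tests do not show

`sim_genotypes()` draws independent SNPs as $\mathrm{Binomial}(2, \pi_j)$
under Hardy–Weinberg equilibrium with frequencies uniform on
$[0.05, 0.5]$ by default; monomorphic columns are resampled (a flag keeps
them to exercise the error path). An AR(1) latent-Gaussian mode induces LD
so that LD-preservation tests are not vacuous, and a crude
two-subpopulation frequency-shift option exists purely as a stress
fixture. `sim_phenotype()` adds infinitesimal or sparse additive effects
scaled to a target $h^2$ with unit marginal variance.
The generator emulates the statistical structure the scheme manipulates —
HWE genotype mixtures, polygenic covariance, private variants, split
cohorts with planted duplicates, logistic case-control traits. It does not
emulate realistic LD maps, pedigree or coalescent structure, admixture,
genotyping error or informative missingness; passing tests therefore
demonstrate the algebraic and statistical contracts of the scheme, not its
behavior on any particular real cohort.

Problem sizes in the shipped tests and acceptance script: the main cohort
is $n = 1000$, $m = 2000$, $h^2 = 0.3$ with a $1000 \times 1000$ key;
federation uses three cohorts of 300; relatedness screening a 100-SNP
panel over 400 individuals; brute force $n = 8$ with $10^4$ trials. These
sizes make every property measurable at comfortable margins while keeping
a full run to a few minutes on one CPU. At these dimensions REML
heritability has sampling SE $\approx \sqrt{2m}/n \approx 0.06$, so
single-replicate $\hat h^2$ values a couple of SE from the simulated
target are expected; the homomorphism claims compare plaintext with
ciphertext, which agree to $10^{-6}$ or better regardless.

## Known limitations

* Quantitative traits only; logistic models are demonstrably not preserved.
* Missing genotypes are rejected; impute first.
* Subsets of individuals cannot be analyzed after encryption unless
  encrypted separately (encrypt a sex covariate instead, or split first).
* Private (single-carrier) variants leak the carrier's key column; strip
  ultra-rare variants before encrypting.
* The scheme is not provably secure: the key space is continuous, small
  key perturbations make small ciphertext perturbations, and security
  rests on the empirical hardness of the inversion attacks shipped here.
* SNP ids travel in the clear by design (hits must be interpretable);
  sample ids never do.
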