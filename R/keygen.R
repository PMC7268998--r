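#' Sample a random orthogonal key from the Stiefel manifold
#'
#' Draws an `n x n` orthogonal matrix uniformly (Haar measure over the
#' orthogonal group). The default generator is the explicit polar
#' construction: simulate `M` with iid `N(0,1)` entries, eigendecompose
#' `t(M) %*% M = V S t(V)`, and return `P = M V S^{-1/2} t(V)`. The
#' `"qr_haar"` generator instead QR-factorizes `M` and corrects column signs
#' by the sign of `diag(R)`; both are Haar-uniform, the QR route is cheaper.
#'
#' @param n key dimension (number of individuals).
#' @param seed optional integer seed; with a fixed seed the draw is
#'   reproducible on one platform.
#' @param generator `"stiefel"` (polar construction, default) or `"qr_haar"`.
#' @return an object of class `hegp_key`: list with `P`, `n`, `generator`,
#'   `seed`.
#' @export
sample_stiefel <- function(n, seed = NULL, generator = c("stiefel", "qr_haar")) {
  generator <- match.arg(generator)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  if (generator == "stiefel") {
    # the polar factor M (t(M) M)^{-1/2}; computed through the SVD
    # M = U S t(V), for which the same matrix is U t(V) — identical in exact
    # arithmetic, stable when M is ill-conditioned
    sv <- svd(M)
    P <- sv$u %*% t(sv$v)
  } else {
    qrf <- qr(M)
    P <- qr.Q(qrf) %*% diag(sign(diag(qr.R(qrf))), n)
  }
  new_key(P, generator = generator, seed = seed)
}

new_key <- function(P, generator = "custom", seed = NULL, check = TRUE) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (check) .assert_orthogonal(P)
  structure(list(P = P, n = n, generator = generator, seed = seed),
            class = "hegp_key")
}

#' Wrap an existing matrix as an orthogonal key
#'
#' Validates orthogonality (`max |t(P)P - I| <= 1e-8`, `|det P| = 1` within
#' `1e-6`) and tags the key `"custom"` (or `"identity"`).
#'
#' @param P orthogonal matrix.
#' @param generator tag recorded in the key metadata.
#' @return `hegp_key`.
#' @export
as_key <- function(P, generator = "custom") new_key(P, generator = generator)

#' Identity key (useful as a null / debugging key)
#' @param n dimension.
#' @return `hegp_key` with `P = I`.
#' @export
identity_key <- function(n) new_key(diag(n), generator = "identity", check = FALSE)

.assert_orthogonal <- function(P, tol = 1e-8) {
  if (nrow(P) != ncol(P)) stop("key matrix must be square", call. = FALSE)
  G <- crossprod(P)
  err <- max(abs(G - diag(nrow(P))))
  if (err > tol)
    stop(sprintf("matrix is not orthogonal: max |t(P)P - I| = %.3g", err),
         call. = FALSE)
  d <- abs(det(P))
  if (abs(d - 1) > 1e-6)
    stop(sprintf("matrix is not orthogonal: |det| = %.8f", d), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.hegp_key <- function(x, ...) {
  cat(sprintf("<hegp_key> %d x %d, generator = %s%s\n", x$n, x$n, x$generator,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Numerical orthogonality of a key
#'
#' Summarizes the off-diagonal of `t(P) %*% P`, which would be exactly zero
#' for a perfect key; rounding error grows slowly with dimension. Both mean
#' and median absolute off-diagonal magnitudes are reported (alongside the
#' max), since "typical" can be read either way.
#'
#' @param key `hegp_key`.
#' @return list with `max_offdiag`, `mean_offdiag`, `median_offdiag`,
#'   `max_diag_dev` (departure of the diagonal from 1).
#' @export
orthogonality_error <- function(key) {
  stopifnot(inherits(key, "hegp_key"))
  G <- crossprod(key$P)
  off <- abs(G[row(G) != col(G)])
  list(max_offdiag = if (length(off)) max(off) else 0,
       mean_offdiag = if (length(off)) mean(off) else 0,
       median_offdiag = if (length(off)) median(off) else 0,
       max_diag_dev = max(abs(diag(G) - 1)))
}

#' Plaintext-ciphertext correlation profile of a key
#'
#' For each standardized data column `x`, the correlation with its rotation
#' is `t(x) %*% P %*% x / (n - 1)`. A good key leaves no trace of the
#' original: the per-column correlations should look like the null
#' correlation of two random vectors, mean approximately 0 at scale
#' `1/sqrt(n)`. The key is flagged unsuitable when
#' `|mean(rho)| > 3 * sd(rho) / sqrt(m)`.
#'
#' @param key `hegp_key`.
#' @param H column-standardized matrix (`n x m`) to profile against.
#' @return object of class `hegp_key_profile`: list with `per_column`,
#'   `mean`, `sd`, `good`.
#' @export
key_correlation_profile <- function(key, H) {
  stopifnot(inherits(key, "hegp_key"))
  H <- as.matrix(H)
  if (nrow(H) != key$n)
    stop(sprintf("dimension mismatch: key is %d x %d but data has %d rows",
                 key$n, key$n, nrow(H)), call. = FALSE)
  rho <- colSums(H * (key$P %*% H)) / (key$n - 1)
  m <- length(rho)
  mu <- mean(rho); s <- sd(rho)
  structure(list(per_column = rho, mean = mu, sd = s,
                 good = abs(mu) <= 3 * s / sqrt(m)),
            class = "hegp_key_profile")
}

#' @export
print.hegp_key_profile <- function(x, ...) {
  cat(sprintf("<hegp_key_profile> m = %d columns, mean rho = %.4g, sd = %.4g, %s\n",
              length(x$per_column), x$mean, x$sd,
              if (x$good) "key looks good" else "KEY FLAGGED UNSUITABLE"))
  invisible(x)
}

# ---- key path: P(lambda) interpolation via real Schur form -----------------

#' Decompose a key into a smooth one-parameter family
#'
#' An orthogonal matrix is a product of planar rotations: its real Schur
#' form `P = Q T t(Q)` is block diagonal with 2x2 rotation blocks (angles
#' `theta`) and entries +/-1. Scaling every angle by `lambda` yields a family
#' `P(lambda)` with `P(0) = I`, `P(1) = P` and
#' `P(lambda) P(mu) = P(lambda + mu)` — a smooth path from the identity to
#' the key, used to study how encryption quality decays near the identity.
#' Keys with `det(P) = -1` carry a lone reflection (-1 block) that cannot be
#' connected to the identity; it is held fixed, with a warning.
#'
#' @param key `hegp_key`.
#' @return object of class `hegp_key_path`.
#' @export
build_key_path <- function(key) {
  stopifnot(inherits(key, "hegp_key"))
  .assert_orthogonal(key$P)
  sch <- Matrix::Schur(key$P)
  Q <- as.matrix(sch$Q); T_ <- as.matrix(sch$T)
  n <- nrow(T_)
  # walk the quasi-diagonal: 2x2 rotation blocks where the subdiagonal is
  # nonzero, scalar +/-1 blocks otherwise
  blocks <- list(); i <- 1L
  while (i <= n) {
    if (i < n && abs(T_[i + 1L, i]) > 1e-10) {
      theta <- atan2(T_[i + 1L, i], T_[i, i])
      blocks[[length(blocks) + 1L]] <- list(start = i, size = 2L, theta = theta)
      i <- i + 2L
    } else {
      blocks[[length(blocks) + 1L]] <-
        list(start = i, size = 1L, value = sign(T_[i, i]))
      i <- i + 1L
    }
  }
  n_neg <- sum(vapply(blocks, function(b)
    b$size == 1L && b$value < 0, logical(1L)))
  if (n_neg %% 2L == 1L)
    warning("key has det(P) = -1: one reflection is held fixed along the path, so reconstruct(0) differs from the identity on a 1-dimensional subspace")
  # pair up -1 scalar blocks into angle-pi rotations so they interpolate
  neg <- which(vapply(blocks, function(b) b$size == 1L && b$value < 0, logical(1L)))
  if (length(neg) >= 2L) {
    for (k in seq_len(length(neg) %/% 2L)) {
      a <- neg[2L * k - 1L]; b <- neg[2L * k]
      blocks[[a]] <- list(start = blocks[[a]]$start, size = 1L, pair = blocks[[b]]$start,
                          theta = pi)
      blocks[[b]] <- list(start = blocks[[b]]$start, size = 0L)  # consumed
    }
  }
  structure(list(Q = Q, blocks = blocks, n = n, base = key),
            class = "hegp_key_path")
}

#' Reconstruct a key along the path
#'
#' @param path a [build_key_path()] result.
#' @param lambda real interpolation parameter; 0 gives the identity, 1 the
#'   base key, and values add: `P(lambda) P(mu) = P(lambda + mu)`.
#' @return `hegp_key` tagged `"custom"`.
#' @export
reconstruct_key <- function(path, lambda) {
  stopifnot(inherits(path, "hegp_key_path"), is.numeric(lambda), length(lambda) == 1L)
  n <- path$n
  T_ <- diag(n)
  for (b in path$blocks) {
    if (b$size == 2L) {
      th <- b$theta * lambda
      i <- b$start
      T_[i, i] <- cos(th); T_[i, i + 1L] <- -sin(th)
      T_[i + 1L, i] <- sin(th); T_[i + 1L, i + 1L] <- cos(th)
    } else if (b$size == 1L && !is.null(b$pair)) {
      # paired reflections rotate through angle pi in their joint plane
      th <- b$theta * lambda
      i <- b$start; j <- b$pair
      T_[i, i] <- cos(th); T_[i, j] <- -sin(th)
      T_[j, i] <- sin(th); T_[j, j] <- cos(th)
    } else if (b$size == 1L) {
      T_[b$start, b$start] <- b$value  # +1, or an unpaired -1 held fixed
    }
  }
  new_key(path$Q %*% T_ %*% t(path$Q), generator = "custom", check = FALSE)
}

# ---- block keys ------------------------------------------------------------

#' Build a permuted block-diagonal key for large cohorts
#'
#' Sampling one huge orthogonal key is expensive and accumulates rounding
#' error, so individuals are first randomly permuted (hiding any grouping)
#' and then encrypted in blocks of at most `max_block` with independent
#' Stiefel keys. The implied full key is the block-diagonal matrix composed
#' with the permutation, and is itself orthogonal.
#'
#' @param n cohort size.
#' @param max_block maximum individuals per block.
#' @param seed optional integer seed.
#' @return object of class `hegp_block_key`: list with `permutation` (the
#'   row order applied before the blocks), `keys`, `block_sizes`, `max_block`.
#' @export
make_block_key <- function(n, max_block, seed = NULL) {
  stopifnot(n >= 1)
  if (max_block < 1 || max_block > n)
    stop("max_block must satisfy 1 <= max_block <= n", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  n_full <- n %/% max_block
  sizes <- rep(max_block, n_full)
  if (n %% max_block > 0L) sizes <- c(sizes, n %% max_block)
  keys <- lapply(sizes, function(sz) sample_stiefel(sz))
  structure(list(permutation = perm, keys = keys,
                 block_sizes = as.integer(sizes), max_block = as.integer(max_block),
                 n = as.integer(n), seed = seed),
            class = "hegp_block_key")
}

#' @export
print.hegp_block_key <- function(x, ...) {
  cat(sprintf("<hegp_block_key> n = %d in %d blocks (sizes %s)\n",
              x$n, length(x$keys), paste(x$block_sizes, collapse = ", ")))
  invisible(x)
}

#' Materialize the full orthogonal matrix implied by a block key
#'
#' Mostly for testing at small `n`; production encryption applies the
#' permutation and blocks without forming this matrix.
#'
#' @param bk `hegp_block_key`.
#' @return dense `n x n` orthogonal matrix.
#' @export
block_key_matrix <- function(bk) {
  stopifnot(inherits(bk, "hegp_block_key"))
  n <- bk$n
  B <- matrix(0, n, n)
  at <- 0L
  for (k in seq_along(bk$keys)) {
    sz <- bk$block_sizes[k]
    B[at + seq_len(sz), at + seq_len(sz)] <- bk$keys[[k]]$P
    at <- at + sz
  }
  Perm <- diag(n)[bk$permutation, , drop = FALSE]
  B %*% Perm
}

# apply/invert a block key to an n-row matrix without densifying
.block_apply <- function(bk, M) {
  M <- as.matrix(M)[bk$permutation, , drop = FALSE]
  at <- 0L
  for (k in seq_along(bk$keys)) {
    sz <- bk$block_sizes[k]
    idx <- at + seq_len(sz)
    M[idx, ] <- bk$keys[[k]]$P %*% M[idx, , drop = FALSE]
    at <- at + sz
  }
  M
}

.block_unapply <- function(bk, M) {
  M <- as.matrix(M)
  at <- 0L
  for (k in seq_along(bk$keys)) {
    sz <- bk$block_sizes[k]
    idx <- at + seq_len(sz)
    M[idx, ] <- crossprod(bk$keys[[k]]$P, M[idx, , drop = FALSE])
    at <- at + sz
  }
  M[order(bk$permutation), , drop = FALSE]
}
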