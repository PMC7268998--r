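#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association scan into a tibble
#'
#' @param x `hegp_assoc`.
#' @param ... unused.
#' @return tibble with one row per SNP: `snp_id`, `beta`, `se`, `stat`,
#'   `logP`, `df`, `model`.
#' @method tidy hegp_assoc
#' @export
tidy.hegp_assoc <- function(x, ...) {
  out <- x$result
  out$model <- x$model
  out
}

#' One-line summary of an association scan
#' @param x `hegp_assoc`.
#' @param ... unused.
#' @return tibble with `model`, `n_snps`, `max_logP`, `top_snp`, `df`.
#' @method glance hegp_assoc
#' @export
glance.hegp_assoc <- function(x, ...) {
  r <- x$result
  i <- which.max(r$logP)
  tibble::tibble(model = x$model, n_snps = nrow(r),
                 max_logP = r$logP[i], top_snp = r$snp_id[i], df = r$df[1L])
}

#' Tidy variance components
#' @param x `hegp_vc`.
#' @param ... unused.
#' @return long tibble of `term`, `estimate`.
#' @method tidy hegp_vc
#' @export
tidy.hegp_vc <- function(x, ...) {
  tibble::tibble(term = c("sigma_g2", "sigma_e2", "h2"),
                 estimate = c(x$sigma_g2, x$sigma_e2, x$h2))
}

#' One-line summary of a variance-component fit
#' @param x `hegp_vc`.
#' @param ... unused.
#' @return tibble with `sigma_g2`, `sigma_e2`, `h2`, `reml_loglik`.
#' @method glance hegp_vc
#' @export
glance.hegp_vc <- function(x, ...) {
  tibble::tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, h2 = x$h2,
                 reml_loglik = x$reml_loglik)
}

#' Tidy a key-quality correlation profile
#' @param x `hegp_key_profile`.
#' @param ... unused.
#' @return tibble of per-column correlations.
#' @method tidy hegp_key_profile
#' @export
tidy.hegp_key_profile <- function(x, ...) {
  tibble::tibble(column = seq_along(x$per_column), rho = x$per_column)
}
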