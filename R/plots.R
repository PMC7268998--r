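#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of an association scan
#'
#' SNPs in input order against `-log10 P`, with the conventional genome-wide
#' and nominal reference lines.
#'
#' @param object `hegp_assoc`.
#' @param threshold horizontal reference line, default `-log10(5e-8)`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hegp_assoc
#' @export
autoplot.hegp_assoc <- function(object, threshold = -log10(5e-8), ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$logP)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::labs(x = "SNP index", y = expression(-log[10](P)),
                  title = sprintf("%s-model association scan", object$model)) +
    ggplot2::theme_minimal()
}

#' Histogram of plaintext-ciphertext column correlations for a key
#'
#' A good key's per-column correlations look like a null sample centred on
#' zero at scale `1/sqrt(n)`; mass away from zero flags an unsuitable key
#' (e.g. one too close to the identity).
#'
#' @param object `hegp_key_profile` from [key_correlation_profile()].
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hegp_key_profile
#' @export
autoplot.hegp_key_profile <- function(object, bins = 50, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "red") +
    ggplot2::labs(x = "cor(column, rotated column)", y = "count",
                  subtitle = sprintf("mean = %.4g, sd = %.4g — %s",
                                     object$mean, object$sd,
                                     if (object$good) "key looks good"
                                     else "key flagged unsuitable")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
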