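# content checksum over the double payload: layout-sensitive, cheap, and
# independent of the serializer
.payload_checksum <- function(x) {
  v <- as.numeric(x)
  sprintf("%.17g|%.17g|%d", sum(v), sum(abs(v) * seq_along(v) %% 997), length(v))
}

#' Write an orthogonal key to disk
#'
#' Keys are stored as the full double-precision matrix (never as an RNG
#' seed: seeds drift across platforms, and a seed would itself be the
#' secret), wrapped with shape and generator metadata plus a content
#' checksum that is verified on load.
#'
#' @param key `hegp_key` or `hegp_block_key`.
#' @param path output path.
#' @export
write_key <- function(key, path) {
  stopifnot(inherits(key, c("hegp_key", "hegp_block_key")))
  payload <- if (inherits(key, "hegp_key")) key$P
             else c(list(perm = key$permutation),
                    lapply(key$keys, `[[`, "P"))
  obj <- list(format = "hegp-key", version = 1L,
              class = class(key)[1L],
              n = key$n,
              generator = if (inherits(key, "hegp_key")) key$generator else "block",
              block_sizes = if (inherits(key, "hegp_block_key")) key$block_sizes,
              permutation = if (inherits(key, "hegp_block_key")) key$permutation,
              matrices = if (inherits(key, "hegp_key")) list(key$P)
                         else lapply(key$keys, `[[`, "P"),
              created = format(Sys.time(), tz = "UTC"))
  obj$checksum <- .payload_checksum(unlist(obj$matrices))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a key written by [write_key()]
#'
#' Refuses to load when the stored checksum does not match the payload.
#'
#' @param path key file.
#' @return `hegp_key` or `hegp_block_key`.
#' @export
read_key <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hegp-key"))
    stop("not a hegp key file", call. = FALSE)
  if (!identical(obj$checksum, .payload_checksum(unlist(obj$matrices))))
    stop("key file checksum mismatch: refusing to load", call. = FALSE)
  if (identical(obj$class, "hegp_key"))
    return(new_key(obj$matrices[[1L]], generator = obj$generator, check = FALSE))
  keys <- lapply(obj$matrices, function(P) new_key(P, check = FALSE))
  structure(list(permutation = obj$permutation, keys = keys,
                 block_sizes = obj$block_sizes,
                 max_block = max(obj$block_sizes), n = obj$n, seed = NULL),
            class = "hegp_block_key")
}

#' Write a ciphertext container
#'
#' Single-file container holding the header (format version, dimensions,
#' flags, SNP ids, covariate names, per-block provenance) and the
#' double-precision payloads `z`, `W`, `F`; round-trips bit-exactly and is
#' checksummed. No sample identifiers are present by construction.
#'
#' @param ct `hegp_ciphertext`.
#' @param path output path (conventionally `.hegp`).
#' @export
write_ciphertext <- function(ct, path) {
  stopifnot(inherits(ct, "hegp_ciphertext"))
  obj <- list(format = "hegp-ciphertext", version = 1L,
              n = ct$n, m = ct$m, p = ct$p,
              flags = ct$flags, snp_ids = ct$snp_ids,
              covariate_names = ct$covariate_names,
              provenance = ct$provenance,
              z = ct$z, W = ct$W, F = ct$F)
  obj$checksum <- .payload_checksum(c(obj$z, obj$W, obj$F))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a ciphertext container
#' @param path file written by [write_ciphertext()].
#' @return `hegp_ciphertext`.
#' @export
read_ciphertext <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hegp-ciphertext"))
    stop("not a hegp ciphertext file", call. = FALSE)
  if (!identical(obj$checksum, .payload_checksum(c(obj$z, obj$W, obj$F))))
    stop("ciphertext checksum mismatch: refusing to load", call. = FALSE)
  new_ciphertext(obj$z, obj$W, obj$F, obj$snp_ids, obj$covariate_names,
                 flags = obj$flags, provenance = obj$provenance)
}
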