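#' Derive a stable sub-seed from a master seed and string labels
#'
#' A small deterministic string hash (djb2 over "seed:label:..."), reduced
#' modulo 2^31 - 1 so the result is always a valid 32-bit R integer seed.
#' Used to fan one master seed out to independent per-stream / per-stage
#' seeds: adding a stream or stage never perturbs the others.
#'
#' @param seed integer master seed
#' @param ... character labels
#' @return integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  s <- paste(c(as.character(as.integer(seed)), ...), collapse = ":")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
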