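#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus a sequence of labels (module,
#' line, replicate, ...) to a new integer seed. Each simulator sub-step draws
#' from its own derived stream so that, e.g., adding replicate pools does not
#' perturb the values generated for earlier ones.
#'
#' @param seed Master integer seed.
#' @param ... Character or numeric labels identifying the sub-stream.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- abs(as.double(seed)) %% 2147483629
  for (code in utf8ToInt(labels)) {
    h <- (h * 31 + code) %% 2147483629
  }
  as.integer(h + 1)
}
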