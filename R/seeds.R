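#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels into a
#' 32-bit non-negative integer. Stage seeds are pure functions of the master
#' seed and the labels, so changing one stage's labels never perturbs another
#' stage's random stream.
#'
#' @param master Integer master seed.
#' @param ... Further labels (coerced to character) identifying the stream,
#'   e.g. a stage name, observer id, run index or iteration number.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "quest", 12)
derive_seed <- function(master, ...) {
  labels <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                  collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}
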