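#' Derive a per-stage seed from a global seed
#'
#' Hashes the stage name together with the global seed so that each pipeline
#' stage consumes an independent, reproducible random stream, insulated from
#' changes in how much randomness upstream stages draw.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# rowwise parallel minimum over the columns of a matrix
row_mins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
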