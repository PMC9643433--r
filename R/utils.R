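#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif prcomp sd t.test p.adjust var
#' @importFrom utils read.delim write.table head
NULL

# Consistent argument failure with the caller's name in the message.
stop_arg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a base seed
#'
#' Experiments take a single integer seed and fan it out to the stages that
#' need independent randomness (stimulus generation, noise simulation,
#' resampling, network initialisation). Offsets are fixed per stage so any
#' stage can be rerun in isolation. Kept below 2^31 - 1 by folding.
#'
#' @param seed Integer base seed.
#' @param offset Integer stage offset.
#' @return An integer seed.
#' @export
child_seed <- function(seed, offset) {
  s <- (as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# clip to [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
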