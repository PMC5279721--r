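`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit polynomial string hash; used to derive independent
# random substreams from one user-facing seed so that adding a metric to the
# generator does not shift draws of the others.
str_hash31 <- function(s) {
  h <- 7
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

#' Derive a substream seed from a global seed and a stream label
#'
#' All randomness in the package is keyed by a single global seed plus a
#' textual stream label, so independent quantities use independent streams.
#'
#' @param seed integer global seed.
#' @param stream character label of the random stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  (((seed %% 2147483647) * 48271) %% 2147483647 + str_hash31(stream)) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Resolve tail = "auto" to the direction of the observed group difference;
# one-tailed directions are otherwise an explicit caller choice.
resolve_tail <- function(tail, summary_a, summary_b) {
  tail <- tail[1]
  if (!identical(tail, "auto")) {
    return(match.arg(tail, c("two-tailed", "one-tailed-greater", "one-tailed-less")))
  }
  if (isTRUE(summary_a > summary_b)) {
    "one-tailed-greater"
  } else if (isTRUE(summary_a < summary_b)) {
    "one-tailed-less"
  } else {
    "two-tailed"
  }
}
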