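#' Seeded random substreams
#'
#' A `uf_stream` is an independent, reproducible source of random variates.
#' Every stochastic process in a simulation run (each arrival stream, the
#' exam-type draw, service times, setup times, the DVT slot draw, the random
#' assignment policy) gets its own substream, so that two experiments sharing
#' a master seed see identical arrivals and service demands even when a policy
#' consumes a different number of policy-specific draws — the common-random-
#' numbers setup used when comparing dispatch policies.
#'
#' Substreams are Mersenne-Twister generators whose seeds are derived by
#' hashing the pair (seed, stream_id); the same pair always reproduces the
#' same draw sequence, and distinct labels give streams that are for all
#' practical purposes independent.
#'
#' @param seed Integer master seed.
#' @param stream_id Character label naming the stochastic process.
#' @return An object of class `uf_stream`.
#' @examples
#' s <- rand_stream(42, "arrivals")
#' draw_stream(s, function() runif(3))
#' @export
rand_stream <- function(seed, stream_id = "default") {
  check_number(seed, "seed")
  if (!is.character(stream_id) || length(stream_id) != 1L) {
    stop_input("`stream_id` must be a single string.")
  }
  sub_seed <- derive_seed(seed, stream_id)
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env$stream_id <- stream_id
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(sub_seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  env$state <- get(".Random.seed", envir = globalenv())
  restore_rng(old)
  class(env) <- "uf_stream"
  env
}

# 31-base rolling hash of the label folded into the seed, kept in [1, 2^31-2].
derive_seed <- function(seed, stream_id) {
  h <- 0
  for (ch in utf8ToInt(stream_id)) h <- (h * 31 + ch) %% 2147483647
  out <- (abs(as.numeric(seed)) * 48271 + h * 69621) %% 2147483629
  as.integer(out + 1)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate a random expression on a stream
#'
#' Swaps the stream's generator state in, evaluates `fn`, and swaps it back
#' out, advancing the stream. The caller's RNG state is untouched.
#'
#' @param stream A [rand_stream()] object.
#' @param fn A zero-argument function performing random draws.
#' @return The value of `fn()`.
#' @export
draw_stream <- function(stream, fn) {
  if (!inherits(stream, "uf_stream")) stop_input("`stream` must be a uf_stream.")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    restore_rng(old)
  })
  fn()
}

#' @export
print.uf_stream <- function(x, ...) {
  cat(sprintf("<uf_stream seed=%d id=%s>\n", x$seed, x$stream_id))
  invisible(x)
}
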