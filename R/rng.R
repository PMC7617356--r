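#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one master seed, fanned out into
#' named substreams (e.g. "init", "mutation", "run3") so that stages can be
#' re-run independently without perturbing each other's draws.
#'
#' @param seed Master seed (integer).
#' @param stream Substream name (character scalar).
#' @return An integer seed in [0, 2^31 - 2], a deterministic function of
#'   `(seed, stream)`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(((abs(as.numeric(seed)) %% 48611) * 44111 + h) %% 2147483646)
}

# length-safe shuffle / draw (avoids sample()'s scalar expansion)
shuffle_ <- function(x) x[sample.int(length(x))]
draw_ <- function(x, m) x[sample.int(length(x), m)]

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded by `seed`, restoring the caller's RNG
#' state afterwards so library code never disturbs user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
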