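#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores the previous stream so callers see no RNG side effects. With
#' `seed = NULL` the expression runs on the ambient stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' Deterministically maps a master seed plus any number of string/numeric
#' labels (sample id, day, stage name, ...) to a positive 32-bit integer, so
#' every stochastic stage of the pipeline consumes its own reproducible
#' substream.
#'
#' @param seed Master integer seed.
#' @param ... Labels identifying the substream.
#' @return A positive integer < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 1987654321
  as.integer((abs(as.numeric(seed)) %% 483647 * 2017 + h) %% 2147480009 + 1)
}

# Truncated normal draws via inverse-CDF; exact and vectorised. `lower` and
# `upper` may be vectors (per-draw bounds).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  x <- qnorm(u, mean, sd)
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Short stable hex digest of an R object (for manifest config hashes).
object_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 1987654321
  sprintf("%08x", as.integer(h %% 2147483647))
}
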