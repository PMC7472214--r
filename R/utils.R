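# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from a global seed
#'
#' Expands one global seed into reproducible per-stage seeds so pipeline
#' stages can be re-run in isolation. Uses a splitmix-style integer mix of
#' the seed with a stage label hash, reduced modulo 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g., \code{"cohort"}).
#' @return A single integer seed in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 1000003   # polynomial string hash, overflow-safe
  }
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + h * 7919) %% 2147483647)
}

# Polynomial rolling hash of a deparsed R object; used to stamp outputs
# with a configuration fingerprint.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(s)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
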