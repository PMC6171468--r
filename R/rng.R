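# Private seeded RNG streams.  Each generator instance owns one stream;
# draws swap the stream's saved state into R's RNG and swap the caller's
# state back afterwards, so no generator ever perturbs global RNG state and
# every stream is reproducible from its integer seed alone.

new_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

rng_unif <- function(rng, n, min = 0, max = 1)
  with_rng(rng, stats::runif(n, min, max))
rng_int <- function(rng, n, k) with_rng(rng, sample.int(k, n, replace = TRUE))
rng_pois <- function(rng, n, lambda) with_rng(rng, stats::rpois(n, lambda))
rng_exp <- function(rng, n, rate) with_rng(rng, stats::rexp(n, rate))
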