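# Internal helpers: seeded evaluation and derived sub-seeds.
#
# Every stochastic operation takes its own `seed` argument; the pipeline
# derives one sub-seed per stage from a master seed so that adding a stage
# never perturbs the random stream of another.

# Evaluate `expr` under a temporary RNG state; restores .Random.seed after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed for stage `i`, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 1000003) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# Population (1/n) standard deviation.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}
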