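# Internal helpers: an isolated, resumable RNG stream so that every seeded
# operation is deterministic and none disturbs the caller's .Random.seed.

local_rng <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer `seed` is required")
  state <- NULL
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old, envir = globalenv())
    })
    expr_fun()
  }
  list(
    sample = function(x, size, replace = FALSE)
      run(function() x[sample.int(length(x), size, replace = replace)]),
    sample_int = function(n, size, replace = FALSE)
      run(function() sample.int(n, size, replace = replace)),
    runif = function(n, min = 0, max = 1)
      run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1)
      run(function() stats::rnorm(n, mean, sd)),
    rpois = function(n, lambda)
      run(function() stats::rpois(n, lambda)),
    derive = function(offset) {
      # child stream with a seed decorrelated from the parent's
      local_rng((seed * 69069 + offset) %% 2147483647)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
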