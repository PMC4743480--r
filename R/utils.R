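# Isolated RNG stream: draws are reproducible from `seed` and do not
# disturb (or depend on) the caller's global RNG state.
local_rng <- function(seed) {
  state <- NULL
  run <- function(fn) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = .GlobalEnv)
    res <- fn()
    state <<- get(".Random.seed", envir = .GlobalEnv)
    if (is.null(old)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
    res
  }
  list(
    sample = function(x, size = length(x), replace = FALSE) {
      run(function() x[sample.int(length(x), size, replace = replace)])
    },
    runif = function(n, min = 0, max = 1) {
      run(function() stats::runif(n, min, max))
    },
    rnorm = function(n, mean = 0, sd = 1) {
      run(function() stats::rnorm(n, mean, sd))
    },
    rbinom = function(n, size, prob) {
      run(function() stats::rbinom(n, size, prob))
    },
    int = function(n, max) run(function() sample.int(max, n, replace = TRUE))
  )
}

# run fn() under a temporary global seed, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  fn()
}
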