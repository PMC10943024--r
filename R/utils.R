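# internal helpers shared across modules

# sample() treats a length-1 numeric vector as 1:n; this never does
resample <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# derive independent child seeds from the current RNG state (one root seed
# per user-facing generator; children keep the construction phases decoupled)
child_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
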