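# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a scalar first argument as 1:x; this always samples from
# the supplied values.
sample1 <- function(values, prob = NULL) {
  if (length(values) == 1) return(values)
  sample(values, 1, prob = prob)
}

# Quantile convention used throughout: linear interpolation between order
# statistics (R's default type 7).
qtl <- function(x, p) unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
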