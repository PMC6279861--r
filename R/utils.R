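#' @keywords internal
"_PACKAGE"

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
# All generators in the package are pure functions of (arguments, seed).
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-unit seed from a base seed; stays below 2^31 - 1.
derive_seed <- function(seed, index, stream = 0L) {
  base <- (as.numeric(seed) %% 2147483647) + 1
  ((base * 48271 + as.numeric(index) * 1000003 + as.numeric(stream) * 7919) %%
    2147483647)
}

stop_invalid <- function(msg, class = "nawmrad_invalid_argument") {
  stop(errorCondition(msg, class = c(class, "nawmrad_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population standard deviation (divisor n).
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# Entropy helper with the 0 * log(0) == 0 convention.
plogp <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p) / log(base))
}
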