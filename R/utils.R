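# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. Keeps every generator a pure function
# of (config, seed) without clobbering user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage sub-seed from a global seed so that toggling one stage
# does not shift another stage's random stream. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Population standard deviation (divides by n, not n - 1).
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 1L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
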