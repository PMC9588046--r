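# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# derive a child seed from a master seed; stays below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483562L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

stopf <- function(fmt, ..., class = "contextchoice_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}
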