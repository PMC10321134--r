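#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Every stochastic routine in the package funnels
# its randomness through this helper so that a single integer seed fixes a
# whole run.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

# Derive a stage-specific child seed from a master seed. Keeps results of
# one stage invariant to how often other stages draw. Stays within 32-bit
# integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 1117) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Largest-remainder apportionment of `n` into parts proportional to `w`,
# ties broken by position order.
largest_remainder <- function(n, w) {
  stopifnot(n >= 0, all(w >= 0), sum(w) > 0)
  q <- n * w / sum(w)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(w))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Population (divide-by-n) variance and standard deviation; the package's
# fixed estimator for filtering and standardization.
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))
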