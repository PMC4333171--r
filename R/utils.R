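# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All user-facing stochastic operations
# funnel through this so that results are a pure function of their seed.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a base seed and a string tag,
# kept within 32-bit integer range.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (seq_along(utf8ToInt(as.character(tag))) %% 97L + 1L))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Scale a vector to have exactly the target variance (population-style,
# divide by realized sd); zero target or degenerate input gives zeros.
scaleToVar <- function(x, targetVar) {
  if (targetVar <= 0 || length(x) < 2L) return(rep(0, length(x)))
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s * sqrt(targetVar)
}

# Draw from a scaled inverse chi-square with the convention
# density(s2) propto s2^-(df/2 + 1) exp(-S / (2 s2)).
rScaledInvChisq <- function(n, df, S) {
  S / rchisq(n, df = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
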