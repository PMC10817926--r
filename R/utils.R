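# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that a master seed fully determines every output.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Counter-based substream derivation: mixes a master seed with one or two
# counters into a stable 31-bit seed. Adding pigs/boluses to a cohort does not
# reshuffle the substreams of earlier ones.
derive_seed <- function(master, i, j = 0L) {
  m <- 2147483647 # 2^31 - 1
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(i) * 16807 + 1) %% m
  x <- (x * 48271 + as.numeric(j) * 69621 + 1) %% m
  as.integer(x)
}

# Trapezoidal integral of y over uniformly spaced samples with step dt.
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

# Sample skewness (moment estimator).
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
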