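`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) without overflow; tolerates -Inf entries
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `code` under `seed` without touching the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Interpolated weighted percentile: the value at cumulative normalized
# weight `prob`, with cumulative weight evaluated at bin midpoints.
weighted_percentile <- function(x, w, prob = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (prob <= s[1L]) return(x[1L])
  n <- length(x)
  if (prob >= s[n]) return(x[n])
  stats::approx(s, x, xout = prob, ties = "ordered")$y
}

weighted_mean_ <- function(x, w) sum(w * x) / sum(w)

weighted_sd_ <- function(x, w) {
  w <- w / sum(w)
  sqrt(sum(w * (x - sum(w * x))^2))
}

# Normal-consistent weighted median absolute deviation
weighted_mad_ <- function(x, w) {
  m <- weighted_percentile(x, w, 0.5)
  1.4826 * weighted_percentile(abs(x - m), w, 0.5)
}

z975 <- function(level = 0.95) stats::qnorm(1 - (1 - level) / 2)
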