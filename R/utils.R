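# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Moving-average smoothing of a matrix with an edge-aware square window of
# the given radius (in cells). radius 0 returns the input unchanged.
smooth_matrix <- function(m, radius) {
  radius <- as.integer(radius)
  if (radius <= 0L) return(m)
  run_mean <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - radius, 1L)
    hi <- pmin(seq_len(n) + radius, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  m <- apply(m, 2, run_mean)
  t(apply(m, 1, run_mean))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}
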