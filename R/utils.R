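# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

# Draw from the multivariate hypergeometric: subsample `k` unit counts
# without replacement from an urn with `counts[i]` units of category i.
# Sequential conditional rhyper; exact and O(length(counts)).
subsample_counts <- function(counts, k) {
  total <- sum(counts)
  stopifnot(k <= total)
  out <- numeric(length(counts))
  remaining <- total
  for (i in seq_along(counts)) {
    if (k <= 0) break
    ni <- counts[i]
    if (remaining == ni) {
      out[i] <- k
      k <- 0
      break
    }
    x <- stats::rhyper(1, ni, remaining - ni, k)
    out[i] <- x
    k <- k - x
    remaining <- remaining - ni
  }
  out
}
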