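# Brute-force oracle for the conditional product-limit estimate: evaluates
# F(x)/F(t*) directly from the defining indicator sums, independent of the
# package's implementation.
npmle_oracle <- function(x, t, at) {
  v <- sort(unique(x))
  vapply(at, function(x0) {
    out <- 1
    for (vj in v[v > x0]) {
      nj <- sum(x == vj)
      Nj <- sum(x <= vj & vj <= t)
      out <- out * (1 - nj / Nj)
    }
    out
  }, numeric(1L))
}

# Samples with integer times and ties, always satisfying x <= t
random_tied_sample <- function(n, seed) {
  set.seed(seed)
  x <- sample(1:6, n, replace = TRUE)
  truncated_sample(x, x + sample(0:4, n, replace = TRUE))
}

# A family grid reused by property-style tests
spec_grid <- list(
  tto_family("exponential", 0.05),
  tto_family("exponential", 1),
  tto_family("weibull", 0.05, 0.5),
  tto_family("weibull", 1, 2),
  tto_family("loglogistic", 0.05, 0.5),
  tto_family("loglogistic", 1, 2)
)

# truncation times so large that F(t) = 1 to double precision even for
# the heavy-tailed log-logistic with shape 0.5
draw_untruncated <- function(spec, n, seed) {
  set.seed(seed)
  truncated_sample(qtto(runif(n), spec), rep(1e19, n))
}
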