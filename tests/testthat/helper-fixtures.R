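# small designs used across test files
tiny_design <- function(n_cpgs = 400, noise_sd = 0.15, seed = 1, ...) {
  simulation_design(n_cpgs = n_cpgs, noise_sd = noise_sd, seed = seed, ...)
}

# exhaustive two-sided Fisher p over all 2x2 tables with fixed margins,
# independent of the package implementation (pure choose() arithmetic)
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k), numeric(1))
  sum(prob[prob <= prob[support == a] * (1 + 1e-7)])
}

# upper-tail hypergeometric P[X >= k] by term-wise enumeration
enum_hyper_upper <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  xs <- k:min(K, n)
  sum(vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1)))
}
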