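# Brute-force oracle for the below-NLI metrics: explicit loop over levels
# and sides, sharing no code with the package implementation.
brute_force_below_nli <- function(pred, obs, nli) {
  keys <- c("C5", "C6", "C7", "C8", "T1", "L2", "L3", "L4", "L5", "S1")
  lv <- spinal_levels()
  nli_i <- lv$index[lv$label == nli]
  res <- c()
  for (k in keys) {
    k_i <- lv$index[lv$label == k]
    if (k_i > nli_i) {
      for (s in c("left", "right")) {
        res <- c(res, pred[paste0(k, "_", s)] - obs[paste0(k, "_", s)])
      }
    }
  }
  list(rmse = sqrt(mean(res^2)), mean_resid = mean(res))
}

# Vectorized Monte-Carlo power of the two t-test designs (independent of the
# package's noncentral-t computations).
mc_power <- function(type, n, delta, sd, alpha, reps = 1e5, seed = 99) {
  withr::with_seed(seed, {
    if (type == "paired") {
      x <- matrix(rnorm(n * reps, delta, sd), n, reps)
      s <- sqrt((colSums(x^2) - n * colMeans(x)^2) / (n - 1))
      tt <- colMeans(x) / (s / sqrt(n))
      mean(abs(tt) > qt(1 - alpha / 2, n - 1))
    } else {
      a <- matrix(rnorm(n * reps, delta, sd), n, reps)
      b <- matrix(rnorm(n * reps, 0, sd), n, reps)
      va <- (colSums(a^2) - n * colMeans(a)^2) / (n - 1)
      vb <- (colSums(b^2) - n * colMeans(b)^2) / (n - 1)
      tt <- (colMeans(a) - colMeans(b)) / sqrt((va + vb) / 2) * sqrt(n / 2)
      mean(abs(tt) > qt(1 - alpha / 2, 2 * n - 2))
    }
  })
}
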