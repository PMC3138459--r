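# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: a textbook scalar recursion for the spline
# basis and a contingency-table estimator for simple-binning MI.

# scalar Cox-de Boor recursion, straight from the recursive definition
cdb_recursive <- function(i, m, z, kn) {
  if (m == 1L) return(as.numeric(z >= kn[i] && z < kn[i + 1L]))
  d1 <- kn[i + m - 1L] - kn[i]
  d2 <- kn[i + m] - kn[i + 1L]
  a <- if (d1 > 0) (z - kn[i]) / d1 * cdb_recursive(i, m - 1L, z, kn) else 0
  b <- if (d2 > 0) (kn[i + m] - z) / d2 * cdb_recursive(i + 1L, m - 1L, z, kn) else 0
  a + b
}

# simple-binning (hard histogram) MI with R equal-width bins over the
# observed range of each variable; the k = 1 pipeline must reproduce this
hist_bin <- function(v, R) {
  z <- (v - min(v)) / (max(v) - min(v)) * R
  pmin(floor(z) + 1L, R)
}
hist_mi_oracle <- function(x, y, R, log_base = 2) {
  J <- table(factor(hist_bin(x, R), 1:R), factor(hist_bin(y, R), 1:R)) / length(x)
  px <- rowSums(J)
  py <- colSums(J)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) / log(log_base) }
  H(px) + H(py) - H(J)
}

# brute-force pairwise MI by looping mi_pair over all unordered pairs
naive_pairwise <- function(data, cfg) {
  n <- nrow(data)
  out <- matrix(0, n, n, dimnames = list(rownames(data), rownames(data)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    out[i, j] <- out[j, i] <- mi_pair(data[i, ], data[j, ], cfg)
  diag(out) <- self_entropies(data, cfg)
  out
}

# three-gene Markov chain with Hill responses, for DPI recovery checks
simulate_chain <- function(m, seed, noise_sd = 0.05) {
  set.seed(seed)
  x <- runif(m)
  y <- x^2 / (0.25 + x^2) + rnorm(m, sd = noise_sd)
  yc <- pmin(pmax(y, 0), 1)
  z <- yc^2 / (0.25 + yc^2) + rnorm(m, sd = noise_sd)
  rbind(X = x, Y = y, Z = z)
}
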