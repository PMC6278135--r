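# Adjusted Rand index between two partitions, from the closed-form
# pair-counting definition (independent of any clustering code under test).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n_pairs <- comb2(length(a))
  expected <- sum_i * sum_j / n_pairs
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Brute-force likelihood-ratio crossover: exhaustive sign-change search of
# the density difference on a fine grid over (0, 1); returns a percent.
grid_crossover <- function(a1, b1, a2, b2, step = 1e-4) {
  x <- seq(step, 1 - step, by = step)
  d <- stats::dbeta(x, a1, b1) - stats::dbeta(x, a2, b2)
  i <- which(d[-length(d)] * d[-1] <= 0)
  mu1 <- a1 / (a1 + b1)
  mu2 <- a2 / (a2 + b2)
  mid <- (x[i] + x[i + 1]) / 2
  inside <- mid >= min(mu1, mu2) & mid <= max(mu1, mu2)
  if (any(inside)) mid <- mid[inside]
  100 * mid[1]
}
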