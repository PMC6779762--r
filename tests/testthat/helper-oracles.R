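# Independent oracles used across test files.

# binary entropy (bits)
h2 <- function(p) {
  q <- c(p, 1 - p)
  q <- q[q > 0]
  -sum(q * log2(q))
}

# Shannon entropy of a distribution (bits)
h2_vec <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# brute-force capacity of a 2-input channel: grid search over p1
grid_capacity_2 <- function(W, n_grid = 2001) {
  p1 <- seq(0, 1, length.out = n_grid)
  max(vapply(p1, function(p) {
    ps <- c(p, 1 - p)
    pr <- as.numeric(crossprod(W, ps))
    terms <- W * log2(sweep(W, 2, pr, "/"))
    terms[W == 0] <- 0
    sum(ps * rowSums(terms))
  }, numeric(1)))
}

# direct double-loop mutual information (bits), written independently of the
# package's vectorized implementation
mi_oracle <- function(p_s, W) {
  p_r <- colSums(p_s * W)
  acc <- 0
  for (j in seq_len(nrow(W))) {
    for (i in seq_len(ncol(W))) {
      if (W[j, i] > 0) {
        acc <- acc + p_s[j] * W[j, i] * log2(W[j, i] / p_r[i])
      }
    }
  }
  acc
}

# exact Poisson row for the bin layout used by channel_from_counts
binned_poisson_row <- function(lambda, edges) {
  bins <- length(edges) - 1
  lo <- 0
  hi <- ceiling(stats::qpois(1 - 1e-12, lambda)) + 5
  v <- lo:hi
  b <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- numeric(bins)
  for (k in seq_along(v)) out[b[k]] <- out[b[k]] + stats::dpois(v[k], lambda)
  out / sum(out)
}

# a fast small input for cheap simulations
tiny_input <- function(L = 20) with_L(standard_inputs()$I2, L)

# random well-conditioned channel
random_channel <- function(m, n, seed) {
  set.seed(seed)
  W <- matrix(stats::rexp(m * n), m, n)
  discrete_channel(W / rowSums(W))
}
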