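# Internal numerical helpers: bivariate normal densities, sampling, and
# stable log-sum-exp. Kept minimal; everything here is standard numerics.

# density of N(mu, Sigma) in 2-D at the rows of x (n x 2 matrix)
dmvn2 <- function(x, mu, Sigma, log = FALSE) {
  x <- matrix(x, ncol = 2L)
  R <- chol(Sigma)  # Sigma = R'R
  z <- backsolve(R, t(x) - as.numeric(mu), transpose = TRUE)
  logdet <- 2 * sum(log(diag(R)))
  ld <- -log(2 * pi) - 0.5 * logdet - 0.5 * colSums(z^2)
  if (log) ld else exp(ld)
}

# n draws from N(mu, Sigma) in 2-D
rmvn2 <- function(n, mu, Sigma) {
  R <- chol(Sigma)
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  sweep(z %*% R, 2L, as.numeric(mu), "+")
}

# integer durations from a truncated normal on [lower, upper]
rdur <- function(n, mean, sd, lower = 1, upper = Inf) {
  out <- integer(0)
  while (length(out) < n) {
    d <- round(stats::rnorm(n, mean, sd))
    d <- d[d >= lower & d <= upper]
    out <- c(out, as.integer(d))
  }
  out[seq_len(n)]
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# symmetric positive-definite guard: add delta to the diagonal if needed
regularize_cov <- function(Sigma, delta = 1) {
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(abs(ev), 1)) {
    Sigma <- Sigma + diag(delta, nrow(Sigma))
  }
  Sigma
}
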