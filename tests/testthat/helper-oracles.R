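# Independent brute-force oracles. These re-derive each quantity from its
# definition with naive loops, deliberately sharing no code with the
# package implementations.

oracle_size_factors <- function(m) {
  # reference genes: all counts positive
  ref <- which(apply(m, 1, function(r) all(r > 0)))
  geo <- numeric(length(ref))
  for (i in seq_along(ref)) geo[i] <- prod(m[ref[i], ])^(1 / ncol(m))
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    sf[j] <- median(m[ref, j] / geo)
  }
  sf / prod(sf)^(1 / length(sf))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, sorted[i] * m / i)
    adj[i] <- min(run_min, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# NB log-likelihood maximization for one gene, two groups with offsets.
oracle_nb_fit <- function(y, x, sf, alpha) {
  nll <- function(beta) {
    mu <- exp(log(sf) + beta[1] + x * beta[2])
    -sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  q <- y / sf
  start <- c(log(mean(q[x == 0]) + 0.5),
             log((mean(q[x == 1]) + 0.5) / (mean(q[x == 0]) + 0.5)))
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  fit$par[2] / log(2) # log2 fold change at the likelihood maximum
}

# Upper-tail hypergeometric by direct log-gamma summation.
oracle_hyper_tail <- function(N, K, n, k) {
  terms <- vapply(k:min(n, K), function(i) {
    lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  }, numeric(1))
  mx <- max(terms)
  exp(mx) * sum(exp(terms - mx))
}

oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mean(a) - mean(b)) / se
  p <- 2 * pt(-abs(t), na + nb - 2)
  c(t = t, p = p)
}
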