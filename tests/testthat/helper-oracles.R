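# Independent brute-force implementations used as oracles. These deliberately
# use explicit elementwise loops (never crossprod/trace identities) so they
# share no code path with the package.

slow_cov <- function(x, divisor = "n") {
  n <- nrow(x); p <- ncol(x)
  m <- numeric(p)
  for (j in seq_len(p)) m[j] <- sum(x[, j]) / n
  s <- matrix(0, p, p)
  div <- if (divisor == "n") n else n - 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    acc <- 0
    for (k in seq_len(n)) acc <- acc + (x[k, i] - m[i]) * (x[k, j] - m[j])
    s[i, j] <- acc / div
  }
  s
}

slow_slice_stats <- function(z, labels, pooled, divisor = "n") {
  # returns list(T, Ti, V, Vstar) computed by loops; pooled is the comparison
  # covariance (identity for standardized data).
  H <- max(labels)
  n <- nrow(z); p <- ncol(z)
  Ti <- numeric(p)
  V <- 0
  Vstar <- 0
  ep <- eigen(pooled, symmetric = TRUE)
  pooled_sqrt <- ep$vectors %*% diag(sqrt(pmax(ep$values, 0)), p) %*%
    t(ep$vectors)
  for (s in seq_len(H)) {
    idx <- which(labels == s)
    ph <- length(idx) / n
    zs <- z[idx, , drop = FALSE]
    cs <- slow_cov(zs, divisor)
    ms <- numeric(p)
    for (j in seq_len(p)) ms[j] <- sum(zs[, j]) / length(idx)
    for (i in seq_len(p)) {
      acc <- 0
      for (j in seq_len(p)) acc <- acc + (cs[i, j] - pooled[i, j])^2
      Ti[i] <- Ti[i] + ph * acc
    }
    ev <- eigen(cs, symmetric = TRUE, only.values = TRUE)$values
    V <- V + ph * (sum((sqrt(pmax(ev, 0)) - 1)^2) + sum(ms^2))
    e <- eigen(cs, symmetric = TRUE)
    cs_sqrt <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p) %*% t(e$vectors)
    accv <- 0
    for (i in seq_len(p)) for (j in seq_len(p)) {
      accv <- accv + (cs_sqrt[i, j] - pooled_sqrt[i, j])^2
    }
    Vstar <- Vstar + ph * (accv + sum(ms^2))
  }
  list(T = sum(Ti), Ti = Ti, V = V, Vstar = Vstar)
}

random_psd <- function(p, rank = p) {
  a <- matrix(rnorm(p * rank), p, rank)
  tcrossprod(a) / rank
}

# large-sample moment oracle: base R covariance (fine for 5e4 draws where the
# explicit-loop oracle would be too slow)
slow_cov_fast <- function(x) stats::cov(x)

# quick balanced two-group labels
two_groups <- function(n) rep(1:2, length.out = n)
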