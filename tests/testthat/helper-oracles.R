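# Independent oracles used across the suite. These are deliberately written
# with different algorithms than the package code paths they check.

# NIPALS PLS1: iterative deflation of X. For a single response, NIPALS and
# SIMPLS are algebraically equivalent, so predictions must coincide.
nipals_pls1 <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  x_means <- colMeans(X)
  Xa <- sweep(X, 2, x_means)
  y0 <- y - mean(y)
  p <- ncol(X)
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  qv <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xa, y0))
    w <- w / sqrt(sum(w^2))
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(y0 * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    W[, a] <- w
    P[, a] <- p_a
    qv[a] <- q_a
  }
  B <- drop(W %*% solve(crossprod(P, W), qv))
  list(
    coef = B,
    predict = function(newdata) {
      drop(sweep(as.matrix(newdata), 2, x_means) %*% B) + mean(y)
    }
  )
}

# moment-matched lognormal parameters, the closed form the generator uses
lnorm_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# random fingerprint-free regression instance for PLS checks
random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rnorm(n)
  list(X = X, y = y)
}
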