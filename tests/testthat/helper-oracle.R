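# Brute-force Fine-Gray oracle: computes the weighted subdistribution
# partial likelihood, score and information by explicit risk-set
# enumeration with its own Kaplan-Meier estimate of the censoring
# distribution.  Deliberately independent of the package's incremental
# implementation (no shared code paths beyond base R).
fg_brute <- function(time, status, X, ipw, beta) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  ct <- sort(unique(time[status == 0]))
  surv <- numeric(length(ct))
  s <- 1
  for (k in seq_along(ct)) {
    atrisk <- sum(time >= ct[k])
    d <- sum(time == ct[k] & status == 0)
    s <- s * (1 - d / atrisk)
    surv[k] <- s
  }
  Gminus <- function(t) {
    idx <- sum(ct < t)
    if (idx == 0) 1 else surv[idx]
  }
  eta <- drop(X %*% beta)
  tev <- sort(unique(time[status == 1]))
  ll <- 0
  sc <- numeric(p)
  H <- matrix(0, p, p)
  for (t in tev) {
    w <- numeric(n)
    for (i in seq_len(n)) {
      if (time[i] >= t) {
        w[i] <- 1
      } else if (status[i] == 2) {
        w[i] <- Gminus(t) / max(Gminus(time[i]), 1e-12)
      }
    }
    a <- ipw * w * exp(eta)
    S0 <- sum(a)
    S1 <- drop(t(X) %*% a)
    S2 <- t(X) %*% (a * X)
    for (i in which(time == t & status == 1)) {
      ll <- ll + ipw[i] * (eta[i] - log(S0))
      sc <- sc + ipw[i] * (X[i, ] - S1 / S0)
      H <- H + ipw[i] * (S2 / S0 - (S1 / S0) %*% t(S1 / S0))
    }
  }
  list(loglik = ll, score = sc, info = H)
}

# random micro-dataset with mixed event types and random weights
random_micro_data <- function(n = sample(4:10, 1)) {
  time <- round(rexp(n), 2) + 0.01
  status <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  if (!any(status == 1)) status[sample(n, 1)] <- 1L
  list(time = time, status = as.integer(status),
       X = matrix(rnorm(2 * n), n, 2),
       ipw = runif(n, 0.3, 3))
}
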