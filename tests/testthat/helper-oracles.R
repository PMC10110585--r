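# Independent brute-force oracles for the metric suite. These deliberately
# avoid the package's code paths (and stats::cor / stats::quantile where the
# package uses them) so agreement is a real cross-check.

oracle_bias <- function(obs, pred) {
  r <- sort(obs - pred)
  n <- length(r)
  if (n %% 2 == 1) r[(n + 1) / 2] else (r[n / 2] + r[n / 2 + 1]) / 2
}

# type-7 linear-interpolation quantile, written out by hand
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_precision <- function(obs, pred) {
  r <- obs - pred
  oracle_quantile7(r, 0.75) - oracle_quantile7(r, 0.25)
}

oracle_mse <- function(obs, pred) {
  s <- 0
  for (i in seq_along(obs)) s <- s + (obs[i] - pred[i])^2
  s / length(obs)
}

oracle_p30 <- function(obs, pred, fraction = 0.30) {
  hits <- 0
  for (i in seq_along(obs)) {
    if (abs(pred[i] - obs[i]) <= fraction * obs[i]) hits <- hits + 1
  }
  100 * hits / length(obs)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# exhaustive pair counting: every (positive, negative) pair scores 1 if the
# positive outranks the negative, 1/2 on ties
oracle_auc <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# random small prediction problems for oracle-equivalence sweeps
random_metric_case <- function(n) {
  obs <- runif(n, 20, 90)
  pred <- obs * runif(n, 0.6, 1.4) + rnorm(n, 0, 5)
  list(obs = obs, pred = abs(pred) + 1)
}
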