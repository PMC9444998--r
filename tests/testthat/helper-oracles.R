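# Independent brute-force reference implementations used to cross-check the
# package's statistics. Each is written from the defining formula, not from
# the code paths it checks.

oracle_quantile <- function(x, p) {
  # linear interpolation between order statistics ("type 7")
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_bh <- function(p) {
  # step-up: adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  rho <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(rho = rho, p = p)
}

oracle_ks <- function(a, b) {
  # exact sweep of the two ECDFs over the pooled support
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(grid, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

oracle_weighted_stats <- function(values, ages, center, sd) {
  w <- exp(-(ages - center)^2 / (2 * sd^2))
  m <- sum(w * values) / sum(w)
  list(mean = m, sd = sqrt(sum(w * (values - m)^2) / sum(w)))
}

oracle_metrics <- function(y, yhat) {
  e <- y - yhat
  n <- length(y)
  vres <- sum((e - mean(e))^2) / (n - 1)
  vy <- sum((y - mean(y))^2) / (n - 1)
  list(ev = 1 - vres / vy,
       mae = sum(abs(e)) / n,
       medae = oracle_quantile(abs(e), 0.5))
}

oracle_one_sample_t <- function(a) {
  n <- length(a)
  tval <- mean(a) / (stats::sd(a) / sqrt(n))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = n - 1))
}
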