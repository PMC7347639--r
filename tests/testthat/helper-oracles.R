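# Independent brute-force oracles used to check the package implementations.
# These are deliberately written as plain, slow, direct translations of the
# definitions, sharing no code with R/.

# Tricube-weighted local-linear smoother at each observed x: nearest
# ceiling(f * n) points by distance, weighted least squares via lm.wfit.
oracle_lowess <- function(x, y, f) {
  n <- length(x)
  q <- min(n, max(2L, as.integer(ceiling(f * n))))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
    keep <- w > 0
    if (sum(keep) == 1 || length(unique(x[keep])) == 1) {
      return(sum(w[keep] * y[keep]) / sum(w[keep]))
    }
    fit <- stats::lm.wfit(cbind(1, x[keep]), y[keep], w[keep])
    cf <- fit$coefficients
    if (anyNA(cf)) sum(w[keep] * y[keep]) / sum(w[keep]) else cf[1] + cf[2] * x[i]
  }, numeric(1))
}

# Average ranks by direct enumeration: rank(v_i) = #(v < v_i) + (#(v == v_i)+1)/2.
oracle_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

# Spearman rho = Pearson correlation of the average-rank vectors, closed form.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# All permutations of 1..n, as a list.
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Exhaustive linear scans for the onset rules (values = full-year vector).
oracle_start_cumulative <- function(values, fraction) {
  v <- ifelse(is.na(values), 0, values)
  total <- sum(v)
  if (total <= 0) return(NA_integer_)
  cum <- 0
  for (d in seq_along(v)) {
    cum <- cum + v[d]
    if (cum >= fraction * total) return(d)
  }
  NA_integer_
}

oracle_start_consecutive <- function(values, run_length) {
  n <- length(values)
  for (d in seq_len(n - run_length + 1L)) {
    win <- values[d:(d + run_length - 1L)]
    if (all(!is.na(win) & win > 0)) return(d)
  }
  NA_integer_
}

oracle_start_absolute <- function(values, threshold) {
  for (d in seq_along(values)) {
    if (!is.na(values[d]) && values[d] >= threshold) return(d)
  }
  NA_integer_
}

# O(n^2) enumeration of every missing run.
oracle_longest_gap <- function(miss) {
  best <- 0L
  n <- length(miss)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(miss[i:j])) best <- max(best, j - i + 1L)
    }
  }
  best
}

# Closed-form simple least squares (slope, intercept).
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Wrap a plain vector as a daily series on days 1..n of 2015.
vec_series <- function(v, kind = "pollen", year = 2015) {
  values <- rep(NA_real_, pollenproxy::days_in_year(year))
  values[seq_along(v)] <- v
  pollenproxy::daily_series(values, year, kind, window = c(1L, length(v)))
}

# A random partially-missing pollen-like year (plain RNG, no generator code).
random_year_values <- function(year = 2015, miss_prob = 0.2) {
  n <- pollenproxy::days_in_year(year)
  v <- stats::rlnorm(n, meanlog = 2, sdlog = 1.5)
  v[stats::runif(n) < miss_prob] <- NA_real_
  v
}
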