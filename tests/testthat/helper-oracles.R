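# Independent oracles used across test files. Each reimplements the relevant
# definition from scratch (no calls into the package's detection paths).

# Log-rank O/E table computed by direct enumeration over distinct event times.
oracle_logrank <- function(time_a, time_b) {
  times <- sort(unique(c(time_a, time_b)))
  num <- 0
  den <- 0
  for (t in times) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t)
    d1 <- sum(time_a == t); d2 <- sum(time_b == t)
    n <- n1 + n2; d <- d1 + d2
    if (n < 2 || d == 0) next
    e1 <- d * n1 / n
    v <- d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    num <- num + (d1 - e1)
    den <- den + v
  }
  if (den == 0) return(0)
  num^2 / den
}

# Product-limit estimator by hand (no censoring required by callers).
oracle_km <- function(times) {
  tt <- sort(unique(times))
  n_at_risk <- vapply(tt, function(t) sum(times >= t), 0)
  d <- vapply(tt, function(t) sum(times == t), 0)
  surv <- cumprod(1 - d / n_at_risk)
  list(time = tt, surv = surv)
}

# Balanced two-way ANOVA sums of squares from the textbook decomposition.
oracle_anova_ss <- function(y, A, B) {
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cell <- interaction(A, B)
  ss_cells <- sum(tapply(y, cell, function(v) length(v) * (mean(v) - gm)^2))
  ssab <- ss_cells - ssa - ssb
  ssr <- sum((y - ave(y, cell))^2)
  list(A = ssa, B = ssb, AB = ssab, resid = ssr, total = sum((y - gm)^2))
}

# Independent apnea scan: recompute a half-period running-max envelope and a
# preceding-10-breath running-median baseline with plain loops, then find the
# maximal sample intervals satisfying (envelope <= 10% of baseline) and
# (length >= two complete cycles) by exhaustive extension.
oracle_apnea_intervals <- function(flow, fs, breath_rate) {
  n <- length(flow)
  w <- max(3L, as.integer(round(0.5 * 60 / breath_rate * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  env <- numeric(n)
  ax <- abs(flow)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    # replicate edge padding: pad with the first/last sample value
    pad_lo <- if (i - half < 1L) rep(ax[1], 1L - (i - half)) else numeric(0)
    pad_hi <- if (i + half > n) rep(ax[n], (i + half) - n) else numeric(0)
    env[i] <- max(c(pad_lo, ax[lo:hi], pad_hi))
  }
  period_n <- 60 / breath_rate * fs
  n_cycles <- max(1L, floor(n / period_n))
  amp <- vapply(seq_len(n_cycles), function(c) {
    max(ax[(floor((c - 1) * period_n) + 1L):min(n, floor(c * period_n))])
  }, 0)
  base_cycle <- vapply(seq_len(n_cycles), function(c) {
    if (c <= 1L) median(amp[seq_len(min(10L, n_cycles))])
    else median(amp[max(1L, c - 10L):(c - 1L)])
  }, 0)
  base <- base_cycle[pmin(n_cycles, floor((seq_len(n) - 1) / period_n) + 1L)]
  sub <- env <= 0.10 * base
  win_n <- 2 * 60 / breath_rate * fs
  out <- list()
  i <- 1L
  while (i <= n) {
    if (sub[i] && (i == 1L || !sub[i - 1L])) {
      j <- i
      while (j < n && sub[j + 1L]) j <- j + 1L
      if ((j - i + 1L) / fs >= 2 * 60 / breath_rate) {
        out[[length(out) + 1L]] <- c(start = i, end = j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Below-threshold mass of a two-component Gaussian mixture by quadrature.
oracle_mixture_mass <- function(w, threshold, low, high) {
  dens <- function(x) {
    w * dnorm(x, low[1], low[2]) + (1 - w) * dnorm(x, high[1], high[2])
  }
  integrate(dens, -Inf, threshold, rel.tol = 1e-10)$value
}

new_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)
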