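# Independent oracles, deliberately written as plain linear-space /
# loop-based evaluations so they share no code path with the package.

# two-branch mixture likelihood summed in linear space
oracle_mixture_nll <- function(y, omega, mu, sigma, cp = 60) {
  ll <- 0
  for (yi in y) {
    li <- if (yi < cp) {
      omega * dlnorm(yi, mu, sigma)
    } else {
      omega * (1 - plnorm(cp, mu, sigma)) + (1 - omega)
    }
    ll <- ll + log(li)
  }
  -ll
}

# brute-force grid search over (omega, mu, sigma)
oracle_grid_fit <- function(y, cp = 60,
                            omega_grid = seq(0.01, 0.99, by = 0.01),
                            mu_grid, sigma_grid) {
  best <- list(nll = Inf)
  for (w in omega_grid) for (m in mu_grid) for (s in sigma_grid) {
    v <- oracle_mixture_nll(y, w, m, s, cp)
    if (is.finite(v) && v < best$nll) {
      best <- list(nll = v, omega = w, mu = m, sigma = s)
    }
  }
  best
}

# Kruskal-Wallis from the definition, loop-based mid-ranks
oracle_kw <- function(values, groups) {
  N <- length(values)
  r <- numeric(N)
  for (i in seq_len(N)) {
    r[i] <- sum(values < values[i]) + (sum(values == values[i]) + 1) / 2
  }
  g <- unique(groups)
  Rbar <- sapply(g, function(gg) mean(r[groups == gg]))
  ni <- sapply(g, function(gg) sum(groups == gg))
  H0 <- 12 / (N * (N + 1)) * sum(ni * (Rbar - mean(r))^2)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H0 / C
  list(H = H, p = pchisq(H, length(g) - 1, lower.tail = FALSE), ranks = r)
}

oracle_conover <- function(values, groups) {
  kw <- oracle_kw(values, groups)
  r <- kw$ranks
  N <- length(values)
  g <- sort(unique(groups))
  k <- length(g)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    na <- sum(groups == g[i]); nb <- sum(groups == g[j])
    num <- mean(r[groups == g[i]]) - mean(r[groups == g[j]])
    den <- sqrt(S2 * ((N - 1 - kw$H) / (N - k)) * (1 / na + 1 / nb))
    tt <- num / den
    out <- rbind(out, data.frame(
      group_a = g[i], group_b = g[j], statistic = tt,
      p_raw = 2 * pt(-abs(tt), N - k)
    ))
  }
  out
}

oracle_dunn <- function(values, groups) {
  kw <- oracle_kw(values, groups)
  r <- kw$ranks
  N <- length(values)
  g <- sort(unique(groups))
  k <- length(g)
  ties <- table(values)
  v <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    na <- sum(groups == g[i]); nb <- sum(groups == g[j])
    z <- (mean(r[groups == g[i]]) - mean(r[groups == g[j]])) /
      sqrt(v * (1 / na + 1 / nb))
    out <- rbind(out, data.frame(
      group_a = g[i], group_b = g[j], statistic = z,
      p_raw = 2 * pnorm(-abs(z))
    ))
  }
  out
}

# hand step-up Benjamini-Hochberg
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / seq(i, m)))
  }
  q
}

make_trials <- function(y, cp = 60) {
  data.frame(animal_id = sprintf("a%03d", seq_along(y)), latency_s = y)
}
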