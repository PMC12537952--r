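#' @keywords internal
"_PACKAGE"

# Counter-based expansion of one master seed into independent sub-seeds.
# A fixed affine step in GF(2^31 - 1) keeps every derived seed a positive
# 32-bit integer and makes stream k reproducible without generating
# streams 1..k-1.
seed_stream <- function(master, offset) {
  m <- 2147483647 # 2^31 - 1 (prime)
  a <- 48271      # minimal-standard multiplier
  x <- (as.numeric(master) %% m)
  s <- (a * ((x + 1009 * as.numeric(offset) + 1) %% m)) %% m
  # avoid the degenerate 0 state
  as.integer(if (s == 0) 1 else s)
}

mm_log <- function(stage, msg, level = "info") {
  if (isTRUE(getOption("mitomotor.quiet", FALSE)) && level == "info") {
    return(invisible(NULL))
  }
  message(sprintf("[%s] %s: %s", level, stage, msg))
}

# log(omega * S + (1 - omega)) computed in log space; S is a survival
# probability so both terms are in [0, 1].
log_censored_mass <- function(log_omega, log1m_omega, log_S) {
  a <- log_omega + log_S
  b <- log1m_omega
  hi <- pmax(a, b)
  ifelse(is.infinite(hi) & hi < 0, -Inf, hi + log1p(exp(pmin(a, b) - hi)))
}

cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
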