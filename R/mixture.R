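#' Right-censored lognormal mixture model for motor-test latencies
#'
#' Latency-to-complete data from timed motor tests (beam crossing, pole
#' descent) mix two outcomes: trials the mouse completes, with a lognormally
#' distributed time censored at the test ceiling, and trials it fails
#' outright, scored at the ceiling. The observed latency y follows
#' \deqn{y' \sim \omega\,\mathrm{LogNormal}(\mu,\sigma) + (1-\omega)\,\delta_{y_{60}},\qquad
#'   y = \min(y', 60),}
#' where \eqn{\omega} is the probability of finishing the task and
#' \eqn{\delta_{y_{60}}} a point mass at the 60-s ceiling. An uncensored
#' trial contributes \eqn{\omega f_{LN}(y;\mu,\sigma)} to the likelihood; a
#' trial recorded at the ceiling contributes
#' \eqn{\omega\,(1 - F_{LN}(60;\mu,\sigma)) + (1-\omega)} -- the model
#' cannot (and need not) distinguish a slow completion from a failure.
#'
#' @param omega completion probability, in [0, 1].
#' @param mu lognormal location, log-seconds.
#' @param sigma lognormal scale, log-seconds, > 0.
#' @param censor_point test ceiling in seconds (default 60).
#' @return an object of class `mixture_params`.
#' @export
mixture_params <- function(omega, mu, sigma, censor_point = 60) {
  stopifnot(
    is.numeric(omega), length(omega) == 1, omega >= 0, omega <= 1,
    is.numeric(mu), length(mu) == 1, is.finite(mu),
    is.numeric(sigma), length(sigma) == 1, sigma > 0,
    is.numeric(censor_point), censor_point > 0
  )
  structure(
    list(omega = omega, mu = mu, sigma = sigma, censor_point = censor_point),
    class = "mixture_params"
  )
}

#' Negative log-likelihood of the censored mixture
#'
#' Accumulates in log space; the censored branch
#' \eqn{\log(\omega S + 1 - \omega)} (S the lognormal survival at the
#' ceiling) uses log-sum-exp so small survival probabilities do not
#' underflow.
#'
#' @param trials trial table (see [validate_trials()]).
#' @param params a [mixture_params()] object.
#' @return the scalar negative log-likelihood; `+Inf` where the parameters
#'   assign zero probability to the data (e.g. `omega = 0` with an
#'   uncensored trial), never an exception.
#' @export
neg_log_likelihood <- function(trials, params) {
  stopifnot(inherits(params, "mixture_params"))
  trials <- validate_trials(trials, params$censor_point)
  y <- trials$latency_s
  cens <- trials$censored
  .mix_nll_parts(
    log_yu = log(y[!cens]), n_cens = sum(cens),
    omega = params$omega, mu = params$mu, sigma = params$sigma,
    log_cp = log(params$censor_point)
  )
}

# NLL from sufficient pieces; omega on the natural scale.
.mix_nll_parts <- function(log_yu, n_cens, omega, mu, sigma, log_cp) {
  n_u <- length(log_yu)
  nll <- 0
  if (n_u > 0) {
    if (omega == 0) return(Inf)
    # lognormal log-density evaluated from the log-data directly
    z <- (log_yu - mu) / sigma
    nll <- nll - n_u * log(omega) -
      sum(-log_yu - log(sigma) - 0.5 * log(2 * pi) - z^2 / 2)
  }
  if (n_cens > 0) {
    log_S <- stats::pnorm((log_cp - mu) / sigma, lower.tail = FALSE, log.p = TRUE)
    lc <- log_censored_mass(log(omega), log1p(-omega), log_S)
    if (!is.finite(lc)) return(Inf)
    nll <- nll - n_cens * lc
  }
  nll
}

# Objective and analytic gradient on the unconstrained scale
# theta = (logit omega, mu, log sigma).
.mix_nll_theta <- function(theta, log_yu, n_cens, log_cp) {
  omega <- stats::plogis(theta[1])
  .mix_nll_parts(log_yu, n_cens, omega, theta[2], exp(theta[3]), log_cp)
}

.mix_grad_theta <- function(theta, log_yu, n_cens, log_cp) {
  omega <- stats::plogis(theta[1])
  mu <- theta[2]
  s <- exp(theta[3])
  n_u <- length(log_yu)
  g_w <- g_mu <- g_s <- 0
  if (n_u > 0) {
    z <- (log_yu - mu) / s
    g_w <- g_w - n_u / omega
    g_mu <- g_mu - sum(z) / s
    g_s <- g_s - sum(z^2 - 1) / s
  }
  if (n_cens > 0) {
    a <- (log_cp - mu) / s
    S <- stats::pnorm(a, lower.tail = FALSE)
    C <- omega * S + 1 - omega
    phi <- stats::dnorm(a)
    g_w <- g_w - n_cens * (S - 1) / C
    g_mu <- g_mu - n_cens * omega * phi / (s * C)
    g_s <- g_s - n_cens * omega * phi * a / (s * C)
  }
  c(g_w * omega * (1 - omega), g_mu, g_s * s)
}

# Core optimizer over a set of starts; returns the best candidate.
.fit_mixture_theta <- function(log_yu, n_cens, log_cp, starts) {
  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(th0, .mix_nll_theta, gr = .mix_grad_theta,
                   log_yu = log_yu, n_cens = n_cens, log_cp = log_cp,
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) {
      best <- list(theta = res$par, value = res$value,
                   converged = res$convergence == 0)
    }
  }
  best
}

#' Maximum-likelihood fit of the censored lognormal mixture
#'
#' Minimizes the negative log-likelihood over the unconstrained
#' reparameterization (logit \eqn{\omega}, \eqn{\mu}, log \eqn{\sigma})
#' by BFGS with an analytic gradient, from five deterministic starts --
#' mixture likelihoods can be multimodal, so the best of the five wins.
#' Two regimes bypass the optimizer because the MLE is available in closed
#' form: with no censored trials the likelihood is monotone increasing in
#' \eqn{\omega}, so \eqn{\hat\omega = 1} (boundary) and
#' \eqn{(\hat\mu,\hat\sigma)} are the plain lognormal MLE; with no
#' uncensored trials completion is never observed, \eqn{(\mu,\sigma)} are
#' unidentifiable and the fit is declared degenerate rather than returning
#' arbitrary values. An interior estimate with logit \eqn{\omega} beyond
#' \eqn{\pm 12} is reported as the corresponding boundary.
#'
#' @param trials trial table with `latency_s` (and optional `censored`).
#' @param censor_point test ceiling, seconds.
#' @param warm_start optional `mixture_params` used as the only start
#'   (used internally by the bootstrap, where replicate data come from the
#'   fitted model so its MLE sits in the basin of attraction); the default
#'   multi-start schedule is used when NULL or when the warm fit fails.
#' @return object of class `mixture_fit`: `params`, `loglik`, `converged`,
#'   `boundary` (one of "none", "omega_at_1", "omega_at_0_degenerate"),
#'   `n_obs`, `n_censored`.
#' @export
fit_mle <- function(trials, censor_point = 60, warm_start = NULL) {
  trials <- validate_trials(trials, censor_point)
  y <- trials$latency_s
  cens <- trials$censored
  yu <- y[!cens]
  n <- length(y)
  n_cens <- sum(cens)

  if (length(yu) == 0) {
    # completion never observed: all mass on the ceiling point mass
    return(new_mixture_fit(
      omega = 0, mu = NA_real_, sigma = NA_real_, censor_point = censor_point,
      loglik = 0, converged = TRUE, boundary = "omega_at_0_degenerate",
      n_obs = n, n_censored = n_cens
    ))
  }
  if (length(unique(yu)) < 2) {
    stop("insufficient data to identify (mu, sigma): need >= 2 distinct uncensored latencies")
  }
  log_yu <- log(yu)
  if (n_cens == 0) {
    mu_hat <- mean(log_yu)
    sigma_hat <- sqrt(mean((log_yu - mu_hat)^2))
    ll <- sum(stats::dlnorm(yu, mu_hat, sigma_hat, log = TRUE))
    return(new_mixture_fit(
      omega = 1, mu = mu_hat, sigma = sigma_hat, censor_point = censor_point,
      loglik = ll, converged = TRUE, boundary = "omega_at_1",
      n_obs = n, n_censored = 0L
    ))
  }

  log_cp <- log(censor_point)
  mu0 <- log(stats::median(yu))
  s0 <- stats::sd(log_yu)
  starts <- if (!is.null(warm_start)) {
    list(c(stats::qlogis(min(max(warm_start$omega, 1e-6), 1 - 1e-6)),
           warm_start$mu, log(warm_start$sigma)))
  } else {
    list(
      c(stats::qlogis(0.25), mu0, log(s0)),
      c(stats::qlogis(0.50), mu0, log(s0)),
      c(stats::qlogis(0.90), mu0, log(s0)),
      c(stats::qlogis(0.50), mu0, log(2 * s0)),
      c(stats::qlogis(0.90), mu0, log(2 * s0))
    )
  }
  best <- .fit_mixture_theta(log_yu, n_cens, log_cp, starts)
  if (is.null(best) && !is.null(warm_start)) {
    starts <- list(
      c(stats::qlogis(0.25), mu0, log(s0)),
      c(stats::qlogis(0.50), mu0, log(s0)),
      c(stats::qlogis(0.90), mu0, log(s0)),
      c(stats::qlogis(0.50), mu0, log(2 * s0)),
      c(stats::qlogis(0.90), mu0, log(2 * s0))
    )
    best <- .fit_mixture_theta(log_yu, n_cens, log_cp, starts)
  }
  if (is.null(best)) {
    stop("mixture fit failed from every start")
  }

  eta <- best$theta[1]
  boundary <- "none"
  omega_hat <- stats::plogis(eta)
  if (eta > 12) {
    boundary <- "omega_at_1"
    omega_hat <- 1
  } else if (eta < -12) {
    boundary <- "omega_at_0_degenerate"
    omega_hat <- 0
  }
  new_mixture_fit(
    omega = omega_hat, mu = best$theta[2], sigma = exp(best$theta[3]),
    censor_point = censor_point,
    loglik = -.mix_nll_parts(log_yu, n_cens, omega_hat, best$theta[2],
                             exp(best$theta[3]), log_cp),
    converged = best$converged, boundary = boundary,
    n_obs = n, n_censored = n_cens
  )
}

new_mixture_fit <- function(omega, mu, sigma, censor_point, loglik,
                            converged, boundary, n_obs, n_censored) {
  params <- if (boundary == "omega_at_0_degenerate") {
    structure(list(omega = omega, mu = mu, sigma = sigma,
                   censor_point = censor_point), class = "mixture_params")
  } else {
    mixture_params(omega, mu, sigma, censor_point)
  }
  structure(
    list(params = params, loglik = loglik, converged = converged,
         boundary = boundary, n_obs = as.integer(n_obs),
         n_censored = as.integer(n_censored)),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Right-censored lognormal mixture fit\n")
  cat(sprintf("  n = %d trials (%d censored at %g s)\n",
              x$n_obs, x$n_censored, x$params$censor_point))
  cat(sprintf("  omega = %.4f   mu = %.4f   sigma = %.4f\n",
              x$params$omega, x$params$mu, x$params$sigma))
  cat(sprintf("  logLik = %.3f   converged = %s   boundary = %s\n",
              x$loglik, x$converged, x$boundary))
  invisible(x)
}

#' Draw latencies from the censored mixture
#'
#' Runs the generative model forward: a Bernoulli(\eqn{\omega}) completion
#' indicator; completers draw LogNormal(\eqn{\mu,\sigma}) censored at the
#' ceiling; failures score the ceiling.
#'
#' @param n number of trials.
#' @param params a [mixture_params()] object.
#' @return numeric latencies in (0, censor_point].
#' @export
rlatency <- function(n, params) {
  stopifnot(inherits(params, "mixture_params"))
  complete <- stats::runif(n) < params$omega
  y <- rep(params$censor_point, n)
  k <- sum(complete)
  if (k > 0) {
    y[complete] <- pmin(stats::rlnorm(k, params$mu, params$sigma),
                        params$censor_point)
  }
  y
}

#' Parametric-bootstrap confidence intervals for the mixture parameters
#'
#' Simulates `n_replicates` datasets of the original size from the fitted
#' parameters, refits each by maximum likelihood, and forms percentile
#' intervals of the replicate MLEs for \eqn{\omega}, \eqn{\mu} and
#' \eqn{\sigma}. Replicates whose refit fails (e.g. an all-censored draw)
#' are dropped and counted. Each replicate uses an independent seed derived
#' from the master seed by a counter-based scheme, so results are
#' reproducible and independent of replicate order.
#'
#' @param fit a converged [fit_mle()] result.
#' @param n_replicates number of bootstrap replicates (the study-scale
#'   default is 10,000).
#' @param level interval level (default 0.95).
#' @param seed master integer seed.
#' @return data.frame of class `bootstrap_ci` with one row per parameter:
#'   `parameter`, `estimate`, `lower`, `upper`, `level`, `n_replicates`,
#'   `n_failed`, `seed`; the replicate MLE matrix is in
#'   `attr(, "estimates")`.
#' @export
parametric_bootstrap <- function(fit, n_replicates = 10000, level = 0.95,
                                 seed = 1) {
  stopifnot(inherits(fit, "mixture_fit"), n_replicates >= 1,
            level > 0, level < 1)
  if (fit$boundary == "omega_at_0_degenerate") {
    stop("cannot bootstrap degenerate fit")
  }
  if (!fit$converged) stop("fit did not converge; refusing to bootstrap")
  p <- fit$params
  n <- fit$n_obs
  est <- matrix(NA_real_, n_replicates, 3,
                dimnames = list(NULL, c("omega", "mu", "sigma")))
  for (b in seq_len(n_replicates)) {
    set.seed(seed_stream(seed, b))
    y <- rlatency(n, p)
    refit <- tryCatch(
      fit_mle(data.frame(animal_id = "boot", latency_s = y),
              censor_point = p$censor_point, warm_start = p),
      error = function(e) NULL
    )
    if (is.null(refit) || refit$boundary == "omega_at_0_degenerate") next
    est[b, ] <- c(refit$params$omega, refit$params$mu, refit$params$sigma)
  }
  ok <- stats::complete.cases(est)
  n_failed <- sum(!ok)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- apply(est[ok, , drop = FALSE], 2, stats::quantile, probs = probs,
              names = FALSE)
  out <- data.frame(
    parameter = c("omega", "mu", "sigma"),
    estimate = c(p$omega, p$mu, p$sigma),
    lower = qs[1, ], upper = qs[2, ],
    level = level, n_replicates = n_replicates,
    n_failed = n_failed, seed = seed,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "estimates") <- est
  class(out) <- c("bootstrap_ci", "data.frame")
  out
}

#' Predictive-ECDF envelope and Q-Q points for graphical model assessment
#'
#' Simulates `n_draws` datasets of the observed size from the fitted model
#' and returns, on the grid of observed latencies, the pointwise
#' lower/upper predictive-ECDF band, the observed ECDF, and the fraction of
#' observed ECDF points inside the band. Q-Q points pair the uncensored
#' observed quantiles with theoretical quantiles of the fitted completion
#' distribution truncated at the ceiling (censored observations sit at the
#' ceiling by construction and carry no quantile information).
#'
#' @param fit a [fit_mle()] result.
#' @param trials the observed trial table.
#' @param n_draws number of predictive draws (>= 100).
#' @param band_level pointwise band level (default 0.95).
#' @param seed integer seed.
#' @return list with `envelope` (latency, lower, upper, observed),
#'   `qq` (theoretical, observed), and `fraction_inside`.
#' @export
predictive_ecdf_envelope <- function(fit, trials, n_draws = 1000,
                                     band_level = 0.95, seed = 1) {
  stopifnot(inherits(fit, "mixture_fit"), n_draws >= 100)
  trials <- validate_trials(trials, fit$params$censor_point)
  y <- trials$latency_s
  n <- length(y)
  grid <- sort(unique(y))
  p <- fit$params

  ecdf_at <- function(v) findInterval(grid, sort(v)) / length(v)
  set.seed(seed_stream(seed, 0))
  sims <- matrix(0, n_draws, length(grid))
  for (d in seq_len(n_draws)) sims[d, ] <- ecdf_at(rlatency(n, p))
  probs <- c((1 - band_level) / 2, 1 - (1 - band_level) / 2)
  band <- apply(sims, 2, stats::quantile, probs = probs, names = FALSE)
  obs <- ecdf_at(y)
  envelope <- data.frame(latency = grid, lower = band[1, ],
                         upper = band[2, ], observed = obs)

  yu <- sort(y[!trials$censored])
  qq <- if (length(yu) > 0 && !is.na(p$sigma)) {
    pp <- (seq_along(yu) - 0.5) / length(yu)
    F_cp <- stats::plnorm(p$censor_point, p$mu, p$sigma)
    data.frame(theoretical = stats::qlnorm(pp * F_cp, p$mu, p$sigma),
               observed = yu)
  } else {
    data.frame(theoretical = numeric(0), observed = numeric(0))
  }
  list(
    envelope = envelope,
    qq = qq,
    fraction_inside = mean(obs >= envelope$lower & obs <= envelope$upper)
  )
}
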