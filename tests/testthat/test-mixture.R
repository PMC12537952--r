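test_that("likelihood matches a linear-space evaluation of the two branches", {
  y <- c(10, 25, 60)
  p <- mixture_params(0.8, log(20), 0.5)
  expect_equal(neg_log_likelihood(make_trials(y), p),
               oracle_mixture_nll(y, 0.8, log(20), 0.5), tolerance = 1e-12)

  # seeded random cases across the parameter space
  set.seed(42)
  for (i in 1:20) {
    w <- runif(1, 0.05, 0.99)
    m <- runif(1, log(5), log(40))
    s <- runif(1, 0.2, 1)
    y <- rlatency(30, mixture_params(w, m, s))
    expect_equal(neg_log_likelihood(make_trials(y), mixture_params(w, m, s)),
                 oracle_mixture_nll(y, w, m, s), tolerance = 1e-10)
  }
})

test_that("likelihood limits: omega = 1 is the plain lognormal, omega = 0 puts all mass on the ceiling", {
  y <- c(5, 12, 33)
  expect_equal(
    neg_log_likelihood(make_trials(y), mixture_params(1, log(15), 0.6)),
    -sum(dlnorm(y, log(15), 0.6, log = TRUE))
  )
  # single censored trial, omega = 0: likelihood 1, NLL contribution 0
  expect_equal(
    neg_log_likelihood(make_trials(60), mixture_params(0, log(15), 0.6)), 0)
  # omega = 0 with an uncensored trial: zero likelihood, not an error
  expect_identical(
    neg_log_likelihood(make_trials(c(10, 60)), mixture_params(0, 3, 0.5)),
    Inf)
  expect_error(neg_log_likelihood(make_trials(numeric(0)),
                                  mixture_params(0.5, 3, 0.5)),
               "no observations")
})

test_that("observed-data distribution integrates to one for any parameters", {
  set.seed(7)
  for (i in 1:10) {
    w <- runif(1); m <- runif(1, 1, 4); s <- runif(1, 0.1, 1.5)
    dens <- integrate(function(y) w * dlnorm(y, m, s), 0, 60,
                      rel.tol = 1e-9)$value
    atom <- w * (1 - plnorm(60, m, s)) + (1 - w)
    expect_equal(dens + atom, 1, tolerance = 1e-6)
  }
})

test_that("uncensored data give the closed-form lognormal MLE with omega at 1", {
  y <- c(5, 10, 20, 40)
  fit <- fit_mle(make_trials(y))
  expect_equal(fit$params$omega, 1)
  expect_equal(fit$boundary, "omega_at_1")
  expect_equal(fit$params$mu, mean(log(y)), tolerance = 1e-12)
  expect_equal(fit$params$sigma, sqrt(mean((log(y) - mean(log(y)))^2)),
               tolerance = 1e-12)
})

test_that("all-censored data are declared degenerate", {
  fit <- fit_mle(make_trials(rep(60, 10)))
  expect_equal(fit$boundary, "omega_at_0_degenerate")
  expect_equal(fit$params$omega, 0)
  expect_true(is.na(fit$params$mu) && is.na(fit$params$sigma))
  expect_error(parametric_bootstrap(fit, 10, seed = 1),
               "cannot bootstrap degenerate fit")
})

test_that("too few distinct uncensored latencies is an identification error", {
  expect_error(fit_mle(make_trials(c(12, 12, 60, 60))), "insufficient data")
})

test_that("MLE beats a brute-force grid and recovers simulated parameters", {
  set.seed(101)
  y <- rlatency(300, mixture_params(0.7, log(20), 0.4))
  fit <- fit_mle(make_trials(y))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$omega - 0.7), 0.08)

  grid <- oracle_grid_fit(
    y, omega_grid = seq(0.55, 0.85, by = 0.01),
    mu_grid = seq(log(20) - 0.2, log(20) + 0.2, by = 0.01),
    sigma_grid = seq(0.25, 0.55, by = 0.01)
  )
  nll_fit <- neg_log_likelihood(make_trials(y), fit$params)
  expect_gte(grid$nll, nll_fit - 1e-3)
})

test_that("fitted NLL never exceeds the NLL at the generating parameters", {
  true <- mixture_params(0.6, log(15), 0.5)
  for (s in 1:15) {
    set.seed(s)
    y <- rlatency(80, true)
    if (all(y == 60) || length(unique(y[y < 60])) < 2) next
    fit <- fit_mle(make_trials(y))
    expect_lte(neg_log_likelihood(make_trials(y), fit$params),
               oracle_mixture_nll(y, 0.6, log(15), 0.5) + 1e-8)
  }
})

test_that("adding censored trials never increases the completion estimate", {
  set.seed(11)
  yu <- rlnorm(40, log(15), 0.4)
  yu <- yu[yu < 60]
  prev <- Inf
  for (n_c in c(0, 5, 15, 30)) {
    fit <- fit_mle(make_trials(c(yu, rep(60, n_c))))
    expect_lte(fit$params$omega, prev + 1e-8)
    prev <- fit$params$omega
  }
})

test_that("scaling latencies and the ceiling shifts mu by log c and fixes omega, sigma", {
  set.seed(13)
  y <- rlatency(150, mixture_params(0.7, log(18), 0.45))
  fit1 <- fit_mle(make_trials(y), censor_point = 60)
  for (cc in c(0.5, 3)) {
    fit2 <- fit_mle(make_trials(cc * y), censor_point = cc * 60)
    expect_equal(fit2$params$omega, fit1$params$omega, tolerance = 1e-4)
    expect_equal(fit2$params$mu, fit1$params$mu + log(cc), tolerance = 1e-4)
    expect_equal(fit2$params$sigma, fit1$params$sigma, tolerance = 1e-4)
  }
})

test_that("bootstrap is deterministic given the seed and brackets the estimate", {
  set.seed(3)
  y <- rlatency(120, mixture_params(0.75, log(15), 0.4))
  fit <- fit_mle(make_trials(y))
  b1 <- parametric_bootstrap(fit, n_replicates = 100, seed = 99)
  b2 <- parametric_bootstrap(fit, n_replicates = 100, seed = 99)
  expect_identical(b1, b2)
  for (i in 1:3) {
    expect_lte(b1$lower[i], b1$estimate[i])
    expect_gte(b1$upper[i], b1$estimate[i])
  }
})

test_that("bootstrap of an uncensored omega-at-1 fit keeps omega at 1 and brackets mu", {
  set.seed(5)
  y <- pmin(rlnorm(60, log(8), 0.3), 59.9)  # all well below the ceiling
  fit <- fit_mle(make_trials(y))
  b <- parametric_bootstrap(fit, n_replicates = 100, seed = 4)
  est <- attr(b, "estimates")
  # a simulated draw can exceed 60 only with tiny probability here
  expect_gte(mean(est[, "omega"] == 1, na.rm = TRUE), 0.95)
  mu_row <- b[b$parameter == "mu", ]
  expect_lte(mu_row$lower, fit$params$mu)
  expect_gte(mu_row$upper, fit$params$mu)
})

test_that("predictive ECDF band is monotone, covers self-simulated data, and Q-Q uses the truncated completion distribution", {
  set.seed(21)
  params <- mixture_params(0.7, log(18), 0.45)
  y <- rlatency(200, params)
  fit <- fit_mle(make_trials(y))
  env <- predictive_ecdf_envelope(fit, make_trials(y), n_draws = 300,
                                  band_level = 0.95, seed = 8)
  expect_false(is.unsorted(env$envelope$lower))
  expect_false(is.unsorted(env$envelope$upper))
  expect_gte(env$fraction_inside, 0.9)
  # Q-Q theoretical quantiles come from the fitted lognormal truncated at 60
  expect_true(all(env$qq$theoretical <= 60))
  expect_equal(nrow(env$qq), sum(y < 60))
  expect_false(is.unsorted(env$qq$theoretical))
})

test_that("per-animal medians match a sort-based oracle and handle censoring", {
  tr <- data.frame(
    animal_id = c("a", "a", "a", "b", "b"),
    test = "pole",
    latency_s = c(12, 60, 30, 60, 60)
  )
  med <- median_summary(tr)
  expect_equal(med$median_latency_s[med$animal_id == "a"], 30)
  expect_equal(med$median_latency_s[med$animal_id == "b"], 60)

  set.seed(31)
  for (i in 1:10) {
    n <- sample(1:3, 1)
    y <- pmin(round(rlnorm(n, 3, 0.5), 2), 60)
    m <- median_summary(data.frame(animal_id = "x", latency_s = y))
    ys <- sort(y)
    oracle <- if (n %% 2 == 1) ys[(n + 1) / 2] else mean(ys[n / 2 + 0:1])
    expect_equal(m$median_latency_s, oracle)
  }
})

test_that("the analytic likelihood gradient matches central finite differences", {
  set.seed(47)
  y <- rlatency(120, mixture_params(0.7, log(18), 0.45))
  log_yu <- log(y[y < 60])
  n_c <- sum(y == 60)
  for (i in 1:5) {
    th <- c(runif(1, -1.5, 1.5), runif(1, 2, 3.5), runif(1, -1.2, 0.2))
    g <- mitomotor:::.mix_grad_theta(th, log_yu, n_c, log(60))
    fd <- vapply(1:3, function(j) {
      h <- 1e-6
      e <- replace(numeric(3), j, h)
      (mitomotor:::.mix_nll_theta(th + e, log_yu, n_c, log(60)) -
       mitomotor:::.mix_nll_theta(th - e, log_yu, n_c, log(60))) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})
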