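# direct access to the sampling engine for conditional-update oracles
engine <- function(Y, E, cands, flags, n_iter, burn_in = 0, thin = 1,
                   phi = NULL, theta = NULL, tau2 = NULL, sigma2 = 1,
                   alpha = 0.5, rho = 0.5, estimate_rho = FALSE,
                   seed = 1, s = 2, adapt = TRUE, centre = TRUE,
                   prior_tau2 = c(1, 0.01), prior_sigma2 = c(1, 0.01)) {
  n <- nrow(Y)
  Tn <- ncol(Y)
  if (is.null(phi)) phi <- matrix(0, n, Tn)
  if (is.null(theta)) theta <- rep(0, Tn)
  if (is.null(tau2)) tau2 <- rep(1, Tn)
  lookup <- stcarclust:::build_lookup(cands$M, cands$K, 1L)
  set.seed(seed)
  stcarclust:::.stcar_mcmc(
    Y, E, rep(1, n * Tn), 1L,
    cands$graph$edges$i - 1L, cands$graph$edges$j - 1L,
    cands$keep, cands$rowsums, cands$eigenvalues,
    lookup, cands$M, cands$K, Tn,
    FALSE, as.integer(s),
    estimate_rho, rho,
    1000, prior_tau2[1], prior_tau2[2], prior_sigma2[1], prior_sigma2[2],
    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
    0, phi, theta, tau2, sigma2, alpha,
    0L, 1L, c(flags, centre), adapt
  )
}

flag <- function(...) {
  f <- rep(FALSE, 7)
  names(f) <- c("beta", "phi", "theta", "tau2", "sigma2alpha", "rho", "w")
  f[c(...)] <- TRUE
  unname(f)
}

border_cands <- function(graph) stcarclust:::border_only_candidates(graph)

test_that("the Poisson log-likelihood matches the pmf", {
  # zero counts, eta = 0: -sum(E)
  E <- matrix(runif(12, 1, 5), 4, 3)
  expect_equal(
    log_poisson_likelihood(matrix(0, 4, 3), matrix(0, 4, 3), E),
    -sum(E)
  )
  # single cell Y = 3, E = 2, eta = 0: 3 log 2 - 2 up to the Y! constant
  expect_equal(
    log_poisson_likelihood(matrix(0, 1, 1), matrix(3, 1, 1), matrix(2, 1, 1)),
    3 * log(2) - 2
  )
  # random data: equals sum dpois + log(Y!) constant
  set.seed(4)
  Y <- matrix(rpois(12, 5), 4, 3)
  eta <- matrix(rnorm(12, 0, 0.3), 4, 3)
  expect_equal(
    log_poisson_likelihood(eta, Y, E),
    sum(dpois(Y, E * exp(eta), log = TRUE)) + sum(lgamma(Y + 1)),
    tolerance = 1e-10
  )
})

test_that("tau2 Gibbs draws follow the conjugate inverse-gamma", {
  g <- random_graph(5, p = 0.7, seed = 2)
  cands <- border_cands(g)
  set.seed(1)
  phi <- matrix(rnorm(5 * 2), 5, 2)
  Y <- matrix(0L, 5, 2)
  E <- matrix(1, 5, 2)
  rho <- 0.6
  res <- engine(Y, E, cands,
    flags = flag("tau2"), n_iter = 40000,
    phi = phi, rho = rho, seed = 3
  )
  for (t in 1:2) {
    quad <- as.numeric(phi[, t] %*% dense_Q(rho, g$W) %*% phi[, t])
    a <- 1 + 5 / 2
    b <- 0.01 + quad / 2
    draws <- res$tau2[, t]
    expect_equal(mean(draws), b / (a - 1), tolerance = 0.03)
    expect_equal(var(draws), b^2 / ((a - 1)^2 * (a - 2)), tolerance = 0.1)
  }
  # phi = 0 leaves the prior scale: mean scale / (shape + n/2 - 1)
  res0 <- engine(Y, E, cands,
    flags = flag("tau2"), n_iter = 40000,
    phi = matrix(0, 5, 2), seed = 4
  )
  expect_equal(mean(res0$tau2[, 1]), 0.01 / (1 + 5 / 2 - 1), tolerance = 0.03)
})

test_that("sigma2 and alpha Gibbs match a brute-force grid posterior", {
  g <- random_graph(4, seed = 5)
  cands <- border_cands(g)
  set.seed(7)
  Tn <- 8
  theta <- as.numeric(arima.sim(list(ar = 0.7), Tn, sd = 0.3))
  Y <- matrix(0L, 4, Tn)
  E <- matrix(1, 4, Tn)
  res <- engine(Y, E, cands,
    flags = flag("sigma2alpha"), n_iter = 60000,
    theta = theta, seed = 8
  )
  expect_true(all(res$alpha >= 0 & res$alpha <= 1))

  # grid posterior: p(alpha, sigma2 | theta) with sigma2 integrated out
  # analytically (inverse-gamma conjugacy) leaves a 1-d density in alpha
  agrid <- seq(0, 1, length.out = 4001)
  lp <- vapply(agrid, function(a) {
    ss <- theta[1]^2 + sum((theta[-1] - a * theta[-Tn])^2)
    -(1 + Tn / 2) * log(0.01 + ss / 2)
  }, numeric(1))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  expect_equal(mean(res$alpha), sum(agrid * post), tolerance = 0.02)
  expect_equal(
    sd(res$alpha), sqrt(sum(agrid^2 * post) - sum(agrid * post)^2),
    tolerance = 0.1
  )
  # sigma2 conditional given theta, alpha: check against closed form with
  # theta = 0 (prior shape 1 + T/2, scale 0.01)
  res0 <- engine(Y, E, cands,
    flags = flag("sigma2alpha"), n_iter = 40000,
    theta = rep(0, Tn), seed = 9
  )
  expect_equal(
    mean(res0$sigma2), 0.01 / (1 + Tn / 2 - 1),
    tolerance = 0.05
  )
  ks <- suppressWarnings(ks.test(res0$alpha, "punif"))
  expect_gt(ks$p.value, 1e-4) # degenerate theta: alpha ~ Uniform(0, 1)
})

test_that("phi updates target likelihood x CAR prior", {
  g <- random_graph(6, p = 0.6, seed = 11)
  cands <- border_cands(g)
  Tn <- 2
  # prior recovery: with uninformative data (and centring off) the
  # stationary distribution of phi_t is exactly N(0, tau2 Q(rho, W)^-1)
  Y <- matrix(0L, 6, Tn)
  E <- matrix(1e-8, 6, Tn)
  tau2 <- c(0.8, 1.6)
  rho <- 0.7
  res <- engine(Y, E, cands,
    flags = flag("phi"), n_iter = 60000, burn_in = 2000,
    tau2 = tau2, rho = rho, seed = 12, centre = FALSE
  )
  Sigma <- solve(dense_Q(rho, g$W))
  for (t in 1:Tn) {
    # risk samples at theta = beta = 0 are exp(phi)
    phis <- log(res$risk[, (t - 1) * 6 + (1:6)])
    expect_equal(
      apply(phis, 2, var), tau2[t] * base::diag(Sigma),
      tolerance = 0.15
    )
    expect_equal(
      cov(phis[, 1], phis[, 2]), tau2[t] * Sigma[1, 2],
      tolerance = 0.3
    )
    expect_equal(colMeans(phis), rep(0, 6), tolerance = 0.1)
  }

  # strong data pin phi at the empirical log ratios
  set.seed(13)
  phi_true <- matrix(rnorm(6 * Tn, 0, 0.5), 6, Tn)
  phi_true <- sweep(phi_true, 2, colMeans(phi_true))
  Eb <- matrix(5e5, 6, Tn)
  Yb <- matrix(rpois(6 * Tn, Eb * exp(phi_true)), 6, Tn)
  resb <- engine(Yb, Eb, cands,
    flags = flag("phi"), n_iter = 20000, burn_in = 5000,
    tau2 = c(1, 1), rho = 0.3, seed = 14
  )
  est <- matrix(colMeans(log(resb$risk)), 6, Tn)
  expect_equal(est, phi_true, tolerance = 0.02)
})

test_that("theta updates target likelihood x AR(1) prior", {
  g <- random_graph(4, seed = 15)
  cands <- border_cands(g)
  Tn <- 2
  Y <- matrix(0L, 4, Tn)
  E <- matrix(1e-8, 4, Tn)
  alpha <- 0.6
  sigma2 <- 0.5
  res <- engine(Y, E, cands,
    flags = flag("theta"), n_iter = 80000, burn_in = 2000,
    alpha = alpha, sigma2 = sigma2, seed = 16, centre = FALSE
  )
  # with centring off, the stationary joint is the AR(1) prior with
  # covariance [[s2, a s2], [a s2, s2 (1 + a^2)]]
  th <- res$theta
  expect_equal(var(th[, 1]), sigma2, tolerance = 0.1)
  expect_equal(var(th[, 2]), sigma2 * (1 + alpha^2), tolerance = 0.1)
  expect_equal(cov(th[, 1], th[, 2]), alpha * sigma2, tolerance = 0.15)
  expect_equal(colMeans(th), c(0, 0), tolerance = 0.05)

  # strong data pin theta at the log-ratio means
  Eb <- matrix(5e5, 4, Tn)
  theta_true <- c(0.4, -0.4)
  set.seed(17)
  Yb <- matrix(rpois(4 * Tn, Eb * exp(rep(theta_true, each = 4))), 4, Tn)
  resb <- engine(Yb, Eb, cands,
    flags = flag("theta"), n_iter = 20000, burn_in = 5000,
    alpha = 0.5, sigma2 = 10, seed = 18
  )
  ltb <- log(resb$risk)
  expect_equal(mean(ltb[, 1]) - mean(ltb[, 5]), 0.8, tolerance = 0.02)
})

test_that("rho is recovered from CAR-distributed surfaces", {
  g <- make_geography(100)
  cands <- border_cands(g)
  Tn <- 6
  rho_true <- 0.9
  tau2 <- 0.5
  Q <- dense_Q(rho_true, g$W)
  set.seed(19)
  U <- chol(Q)
  phi <- sqrt(tau2) * backsolve(U, matrix(rnorm(100 * Tn), 100))
  res <- engine(matrix(0L, 100, Tn), matrix(1e-8, 100, Tn), cands,
    flags = flag("rho"), n_iter = 20000, burn_in = 2000,
    phi = phi, tau2 = rep(tau2, Tn), rho = 0.5, estimate_rho = TRUE,
    seed = 20
  )
  ci <- quantile(res$rho[, 1], c(0.025, 0.975))
  expect_gt(rho_true, ci[1])
  expect_lt(rho_true, ci[2])
  expect_lt(ci[2] - ci[1], 0.3)
})

test_that("W sampling matches the exactly enumerated discrete posterior", {
  g <- random_graph(6, p = 0.6, seed = 21)
  parts <- fake_partitions(6, M = 1, K = 3, seed = 22)
  cands <- candidate_matrices(g, parts, variant = "A")
  expect_equal(n_candidates(cands), 3)
  set.seed(23)
  phi <- matrix(rnorm(6 * 2, 0, 0.8), 6, 2)
  out <- sample_w_posterior(cands, phi,
    tau2 = c(0.3, 0.6), rho = 0.8,
    n_sweeps = 30000, seed = 24
  )
  target <- exp(out$log_weights - max(out$log_weights))
  target <- target / sum(target)
  freq <- tabulate(out$trace, nbins = 3) / length(out$trace)
  expect_lt(sum(abs(freq - target)) / 2, 0.05)

  # self-consistency: surfaces drawn under a strong candidate structure
  # put the posterior mode on that candidate
  W2 <- stcarclust:::candidate_matrix(cands, 2)
  lab <- cands$labels[, 2]
  mu <- matrix(2 * (lab - mean(lab)), 6, 2)
  set.seed(25)
  phi_s <- mu + 0.05 * matrix(rnorm(12), 6, 2)
  out_s <- sample_w_posterior(cands, phi_s,
    tau2 = c(0.05, 0.05),
    rho = 0.9, n_sweeps = 20000, seed = 26
  )
  expect_equal(
    which.max(tabulate(out_s$trace, nbins = 3)),
    which.max(out_s$log_weights)
  )
})

test_that("full chains are seed-reproducible and well-behaved", {
  tf <- tiny_fit()
  fit <- tf$fit
  sim <- tf$sim
  fit2 <- fit_stcar(sim$data, sim$graph,
    variant = "A", rho = "estimated",
    K = 4, n_iter = 1500, burn_in = 700, thin = 4, seed = 7
  )
  expect_identical(fit$samples$risk, fit2$samples$risk)
  expect_identical(fit$samples$w, fit2$samples$w)

  # centring invariants hold in the retained samples
  expect_true(all(abs(rowMeans(fit$samples$theta)) < 1e-10))
  phis <- log(fit$samples$risk)
  # per-period spatial means equal beta0 + theta_t (phi centred out)
  for (t in 1:3) {
    block <- phis[, (t - 1) * 25 + (1:25)]
    expect_equal(
      rowMeans(block),
      fit$samples$beta[, 1] + fit$samples$theta[, t],
      tolerance = 1e-10
    )
  }
  expect_true(all(fit$samples$tau2 > 0))
  expect_true(all(fit$samples$sigma2 > 0))
  expect_true(all(fit$samples$alpha >= 0 & fit$samples$alpha <= 1))
  expect_true(all(fit$samples$rho > 0 & fit$samples$rho < 1))
  expect_true(all(is.finite(fit$samples$deviance)))
})

test_that("multi-chain runs pool post burn-in draws from every chain", {
  tf <- tiny_fit()
  sim <- tf$sim
  fit <- fit_stcar(sim$data, sim$graph,
    variant = "A", rho = "fixed", K = 3,
    n_iter = 600, burn_in = 200, thin = 4, n_chains = 2, seed = 5
  )
  expect_equal(nrow(fit$samples$w), 2 * 100)
  expect_equal(unique(fit$samples$chain), 1:2)
  # chains differ (different seeds) but agree in distribution
  expect_false(identical(
    fit$samples$risk[1:100, ],
    fit$samples$risk[101:200, ]
  ))
})

test_that("covariate effects are recovered in the full model", {
  g <- make_geography(36)
  set.seed(71)
  n <- 36
  Tn <- 3
  E <- matrix(runif(n * Tn, 40, 90), n, Tn)
  x <- matrix(rnorm(n * Tn), n, Tn)
  Y <- matrix(rpois(n * Tn, E * exp(0.2 + 0.6 * x)), n, Tn)
  d <- toy_counts(Y, E)
  d$xvar <- as.numeric(t(x))
  fit <- fit_stcar(d, g,
    variant = "N", rho = "fixed", covariates = "xvar",
    n_iter = 4000, burn_in = 2000, thin = 4, seed = 72
  )
  td <- tidy(fit)
  b1 <- td[td$term == "beta1", ]
  expect_equal(b1$estimate, 0.6, tolerance = 0.15)
  expect_gt(0.6, b1$conf.low - 0.05)
  expect_lt(0.6, b1$conf.high + 0.05)
})

test_that("variant B with one period matches variant A in distribution", {
  g <- make_geography(25)
  sim <- simulate_st_data(
    case = "1", Z = 1, SF = 1, rho = 0.9,
    n = 25, n_periods = 1, seed = 31, graph = g
  )
  res <- estimate_residuals(sim$data)
  pA <- cluster_partitions(res, "A", K = 3, seed = 3)
  cA <- candidate_matrices(g, pA, "A")
  pB <- cluster_partitions(res, "B", K = 3, seed = 3)
  cB <- candidate_matrices(g, pB, "B", n_periods = 1)
  fa <- fit_stcar(sim$data, g,
    variant = "A", candidates = cA, rho = "fixed",
    n_iter = 4000, burn_in = 1000, seed = 4
  )
  fb <- fit_stcar(sim$data, g,
    variant = "B", candidates = cB, rho = "fixed",
    n_iter = 4000, burn_in = 1000, seed = 5
  )
  # same stage-1 features, so identical candidate sets
  expect_equal(cA$keep, cB$keep)
  ra <- risk_estimates(fa)
  rb <- risk_estimates(fb)
  expect_equal(ra$estimate, rb$estimate, tolerance = 0.05)
  expect_equal(
    posterior_mode_w(fa)$index,
    posterior_mode_w(fb)$index
  )
})
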