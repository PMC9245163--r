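test_that("adjusted Rand index agrees with brute-force pair counting", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand(1:3, 1:4), "equal length")

  # closed form equals pair counting on all partitions of 6 items
  parts <- all_partitions(6)
  expect_length(parts, 203) # Bell number B(6)
  set.seed(1)
  idx <- cbind(
    sample(length(parts), 400, replace = TRUE),
    sample(length(parts), 400, replace = TRUE)
  )
  for (r in seq_len(nrow(idx))) {
    a <- parts[[idx[r, 1]]]
    b <- parts[[idx[r, 2]]]
    expect_equal(adjusted_rand(a, b), pair_count_ari(a, b), tolerance = 1e-12)
  }
})

test_that("adjusted Rand index is symmetric, relabelling-invariant, null at chance", {
  set.seed(2)
  for (r in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand(a, b), adjusted_rand(b, a))
    perm <- sample(4)
    expect_equal(adjusted_rand(perm[a], b), adjusted_rand(a, b))
  }
  # independent labellings at large n give values near zero
  set.seed(3)
  aris <- replicate(20, adjusted_rand(
    sample(1:3, 2000, replace = TRUE),
    sample(1:3, 2000, replace = TRUE)
  ))
  expect_lt(max(abs(aris)), 0.01)
})

test_that("period-local ARI handles arbitrary per-period labels", {
  tru <- tibble::tibble(
    area_id = rep(1:6, each = 2), time = rep(1:2, 6),
    level = rep(c(1, 1, 2, 2, 3, 3), each = 2)
  )
  est <- tru
  names(est)[3] <- "label"
  # permute labels differently in each period: still perfect agreement
  est$label[est$time == 2] <- c(3, 3, 1, 1, 2, 2)
  expect_equal(ari_over_periods(tru, est), 1)
  est$label[est$time == 2] <- c(1, 1, 1, 1, 1, 1)
  expect_lt(ari_over_periods(tru, est), 1)
})

test_that("rmse and coverage follow their definitions", {
  est <- tibble::tibble(
    area_id = c(1, 1, 2, 2), time = c(1, 2, 1, 2),
    estimate = c(1.0, 1.2, 0.8, 1.1),
    conf.low = c(0.9, 1.0, 0.7, 1.3),
    conf.high = c(1.1, 1.4, 0.9, 1.5)
  )
  tru <- tibble::tibble(
    area_id = c(1, 1, 2, 2), time = c(1, 2, 1, 2),
    risk = c(1.0, 1.3, 0.85, 1.2)
  )
  rc <- rmse_coverage(est, tru)
  expect_equal(rc$rmse, sqrt(mean(c(0, 0.1, -0.05, -0.1)^2)))
  expect_equal(rc$coverage, 3 / 4)
  # perfect estimates and infinite intervals are the degenerate limits
  est2 <- dplyr::mutate(est,
    estimate = tru$risk,
    conf.low = -Inf, conf.high = Inf
  )
  rc2 <- rmse_coverage(est2, tru)
  expect_equal(rc2$rmse, 0)
  expect_equal(rc2$coverage, 1)
  expect_error(rmse_coverage(est, tru[1:3, ]), "align")
})

test_that("DIC arithmetic and plug-in behave as defined", {
  expect_equal(
    unname(dic_pd(c(10, 12, 14), 11)), c(13, 1)
  )
  expect_equal(unname(dic_pd(rep(7, 5), 7)), c(7, 0))
  expect_error(dic_pd(numeric(0), 1), "no deviance")

  tf <- tiny_fit()
  d <- dic(tf$fit)
  expect_equal(unname(d["DIC"]), unname(d["Dbar"] + d["pd"]))
  expect_gt(d["pd"], 0)
  g <- glance(tf$fit)
  expect_equal(g$DIC, unname(d["DIC"]))
  # a deliberately mis-specified model fits worse on cluster data
  sim <- tf$sim
  fitN <- fit_stcar(sim$data, sim$graph,
    variant = "N", rho = "fixed",
    n_iter = 1500, burn_in = 700, thin = 4, seed = 7
  )
  expect_lt(glance(tf$fit)$DIC, glance(fitN)$DIC + 50)
})

test_that("posterior W summaries are consistent with the trace", {
  tf <- tiny_fit()
  fit <- tf$fit
  wp <- w_posterior(fit)
  expect_equal(sum(wp$prob), 1)
  mode_w <- posterior_mode_w(fit)
  expect_equal(
    mode_w$index,
    wp$index[which.max(wp$prob)]
  )
  cc <- cluster_counts(fit)
  expect_equal(nrow(cc), 3)
  expect_true(all(grepl("^\\d+ \\(\\d+, \\d+\\)$", cc$label)))
  expect_true(all(cc$lower <= cc$k_mode & cc$k_mode <= cc$upper))
  # the modal matrix's k is the modal k
  expect_equal(unique(cc$k_mode), mode_w$k)
  mp <- modal_partition(fit)
  expect_equal(nrow(mp), 25 * 3)
  expect_equal(
    sort(unique(mp$label)),
    sort(unique(fit$candidates$labels[, mode_w$index]))
  )
})

test_that("posterior mode ties break toward the smaller pd", {
  tf <- tiny_fit()
  fit <- tf$fit
  # force an artificial tie between two candidate indices
  S <- nrow(fit$samples$w)
  half <- S %/% 2
  fit$samples$w[, 1] <- rep(c(2L, 3L), c(half, S - half))
  mode_w <- posterior_mode_w(fit)
  pd2 <- stcarclust:::dic_parts(fit, which(fit$samples$w[, 1] == 2L))["pd"]
  pd3 <- stcarclust:::dic_parts(fit, which(fit$samples$w[, 1] == 3L))["pd"]
  expect_equal(mode_w$index, if (pd2 <= pd3) 2L else 3L)
})

test_that("Geweke diagnostics are calibrated", {
  set.seed(6)
  z_null <- replicate(20, geweke_z(rnorm(5000)))
  expect_lt(max(abs(z_null)), 4)
  shifted <- c(rnorm(3000, 0), rnorm(3000, 2))
  expect_gt(abs(geweke_z(shifted)), 5)
  expect_true(is.na(geweke_z(rep(1, 500))))
  expect_error(geweke_z(rnorm(50)), "too short")

  # agrees with the reference implementation on a stationary AR trace
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.5), 4000))
  z_ref <- unname(coda::geweke.diag(coda::mcmc(x))$z)
  expect_equal(geweke_z(x), z_ref, tolerance = 0.35)

  tf <- tiny_fit()
  gd <- geweke_diagnostics(tf$fit)
  expect_true(all(c("beta0", "sigma2", "alpha", "deviance") %in% gd$term))
})
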