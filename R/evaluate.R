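#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items
#' (Hubert-Arabie form, computed from the contingency table of the two
#' label vectors). 1 means identical partitions; values near 0 arise
#' for independent random labellings; negative values mean less
#' agreement than expected by chance. Labels may be arbitrary; the
#' index is invariant to relabelling.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (a scalar).
#' @export
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) {
    return(ifelse(sum_ij == expected, 1, 0))
  }
  (sum_ij - expected) / (maxi - expected)
}

#' RMSE and credible-interval coverage of risk estimates
#'
#' Root mean square error of the posterior-median risks against the
#' true risks, and the fraction of (area, period) cells whose credible
#' interval contains the truth.
#'
#' @param estimates tibble from [risk_estimates()] (columns `area_id`,
#'   `time`, `estimate`, `conf.low`, `conf.high`).
#' @param truth tibble with columns `area_id`, `time`, `risk` (e.g.
#'   the `truth` element of an `stcar_sim`).
#' @return a one-row tibble with `rmse` and `coverage`.
#' @export
rmse_coverage <- function(estimates, truth) {
  j <- dplyr::inner_join(
    estimates,
    dplyr::select(truth, "area_id", "time", "risk"),
    by = c("area_id", "time")
  )
  if (nrow(j) != nrow(estimates)) abort("estimates and truth do not align")
  tibble::tibble(
    rmse = sqrt(mean((j$estimate - j$risk)^2)),
    coverage = mean(j$conf.low <= j$risk & j$risk <= j$conf.high)
  )
}

#' Adjusted Rand index over all time periods
#'
#' Compares two spatio-temporal cluster structures by pair counting
#' over all `n x T` (area, period) cells. Cluster identities are
#' treated as local to each period for both structures (clustering
#' labels carry no meaning across periods), which is equivalent to
#' concatenating the per-period label vectors after making labels
#' period-unique. Identical per-period partitions give 1 whatever the
#' raw label ids.
#'
#' @param truth,estimate data frames with columns `area_id`, `time`
#'   and a label column (`level` for `truth`, `label` for `estimate`;
#'   a `label` column is used if both are present).
#' @return the adjusted Rand index (a scalar).
#' @export
ari_over_periods <- function(truth, estimate) {
  labcol <- function(d) if ("label" %in% names(d)) d$label else d$level
  key <- function(d) paste(d$time, labcol(d), sep = ":")
  tru <- dplyr::arrange(truth, .data$area_id, .data$time)
  est <- dplyr::arrange(estimate, .data$area_id, .data$time)
  if (nrow(tru) != nrow(est)) abort("structures do not align")
  adjusted_rand(key(tru), key(est))
}

#' Score a fit against simulation truth
#'
#' Convenience wrapper computing risk RMSE, 95% credible-interval
#' coverage and the adjusted Rand index between the true level
#' partition and the modal estimated partition over all time periods
#' (variant A repeats its single partition; see [ari_over_periods()]).
#'
#' @param fit an `stcar_fit`.
#' @param truth truth tibble of an `stcar_sim` (columns `area_id`,
#'   `time`, `risk`, `level`).
#' @return a one-row tibble with `rmse`, `coverage`, `ari`.
#' @export
evaluate_fit <- function(fit, truth) {
  rc <- rmse_coverage(risk_estimates(fit), truth)
  rc$ari <- ari_over_periods(
    dplyr::select(truth, "area_id", "time", "level"),
    modal_partition(fit)
  )
  rc
}

#' Geweke convergence diagnostic
#'
#' The z-score comparing the mean of the first `frac1` of a chain with
#' the mean of the last `frac2`, using spectral-density estimates of
#' the variances (autoregressive fit at frequency zero), so
#' autocorrelation in the chain is accounted for. |z| above about 2-3
#' indicates the chain has not reached stationarity. A constant trace
#' has no information and returns `NA`.
#'
#' @param x numeric vector, one parameter's trace (length >= 100).
#' @param frac1,frac2 fractions of the chain to compare (defaults 0.1
#'   and 0.5).
#' @return the z-score, or `NA` if not computable.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  if (length(x) < 100) abort("trace too short for a Geweke diagnostic")
  if (sd(x) == 0) {
    return(NA_real_)
  }
  x1 <- x[seq_len(floor(frac1 * length(x)))]
  x2 <- x[(length(x) - floor(frac2 * length(x)) + 1):length(x)]
  s1 <- spectrum0_ar(x1)
  s2 <- spectrum0_ar(x2)
  if (!is.finite(s1) || !is.finite(s2) || s1 + s2 <= 0) {
    return(NA_real_)
  }
  (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
}

# spectral density at frequency zero via an AIC-selected AR fit
spectrum0_ar <- function(x) {
  if (sd(x) == 0) {
    return(0)
  }
  fit <- tryCatch(
    ar(x, aic = TRUE, order.max = min(30, floor(length(x) / 5))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(var(x))
  }
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke diagnostics for a fitted model
#'
#' Applies [geweke_z()] to the retained trace of each monitored scalar
#' parameter of the first chain.
#'
#' @param fit an `stcar_fit`.
#' @return a tibble with columns `term` and `z`.
#' @export
geweke_diagnostics <- function(fit) {
  sm <- fit$samples
  first <- which(sm$chain == 1)
  traces <- c(
    list(beta0 = sm$beta[first, 1]),
    setNames(
      lapply(seq_len(ncol(sm$theta)), function(t) sm$theta[first, t]),
      paste0("theta[", seq_len(ncol(sm$theta)), "]")
    ),
    setNames(
      lapply(seq_len(ncol(sm$tau2)), function(t) sm$tau2[first, t]),
      paste0("tau2[", seq_len(ncol(sm$tau2)), "]")
    ),
    list(sigma2 = sm$sigma2[first], alpha = sm$alpha[first]),
    list(deviance = sm$deviance[first])
  )
  tibble::tibble(
    term = names(traces),
    z = vapply(traces, function(v) {
      if (length(v) >= 100) geweke_z(v) else NA_real_
    }, numeric(1))
  )
}

#' Poisson log-likelihood of a model state
#'
#' `sum_it [Y_it (ln E_it + eta_it) - E_it exp(eta_it)]` up to the
#' `Y!` constant, with `eta_it` the linear predictor on the log-risk
#' scale. Exposed mainly for testing and for computing deviances of
#' externally constructed states.
#'
#' @param eta matrix of linear predictors (areas x periods).
#' @param Y,E observed and expected count matrices.
#' @return the log-likelihood (a scalar).
#' @export
log_poisson_likelihood <- function(eta, Y, E) {
  sum(Y * (log(E) + eta) - E * exp(eta))
}

#' Sample the neighbourhood matrix with all else fixed
#'
#' Runs only the two-move Metropolis-Hastings update for the
#' neighbourhood matrix, holding `phi`, `tau2` and `rho` fixed. Because
#' the other parameters never move, the candidate log-posterior weights
#' are constants, and the chain's visit frequencies can be compared
#' with the exactly enumerated discrete posterior
#' `p(W | phi) \propto prod_t N(phi_t; 0, tau2_t Q(rho, W)^{-1})`.
#'
#' @param cands a [candidate_matrices()] result (variant A).
#' @param phi matrix of spatial effects (areas x periods).
#' @param tau2 vector of per-period variances.
#' @param rho spatial dependence parameter.
#' @param n_sweeps number of sweeps (each sweep = move 1 + move 2).
#' @param s window half-width of move 1.
#' @param seed integer seed.
#' @return a list with `trace` (sampled candidate index per sweep) and
#'   `log_weights` (exact unnormalised log posterior per candidate).
#' @export
sample_w_posterior <- function(cands, phi, tau2, rho, n_sweeps = 1e5,
                               s = 2, seed = 1) {
  stopifnot(inherits(cands, "candidate_set"), cands$variant == "A")
  phi <- as.matrix(phi)
  Tn <- ncol(phi)
  if (length(tau2) == 1) tau2 <- rep(tau2, Tn)
  # exact per-candidate log weights (W-dependent terms only)
  lw <- vapply(seq_len(nrow(cands$info)), function(m) {
    kp <- cands$keep[, m]
    ld <- sum(log(rho * cands$eigenvalues[, m] + 1 - rho))
    s_t <- vapply(seq_len(Tn), function(t) {
      d <- phi[cands$graph$edges$i[kp], t] - phi[cands$graph$edges$j[kp], t]
      sum(d^2)
    }, numeric(1))
    sum(ld / 2 - rho * s_t / (2 * tau2))
  }, numeric(1))

  n <- cands$graph$n
  dummyY <- matrix(0L, n, Tn)
  dummyE <- matrix(1, n, Tn)
  lookup <- build_lookup(cands$M, cands$K, 1L)
  set.seed(seed)
  res <- .stcar_mcmc(
    dummyY, dummyE, rep(1, n * Tn), 1L,
    cands$graph$edges$i - 1L, cands$graph$edges$j - 1L,
    cands$keep, cands$rowsums, cands$eigenvalues,
    lookup, cands$M, cands$K, Tn,
    FALSE, as.integer(s),
    FALSE, rho,
    1000, 1, 0.01, 1, 0.01,
    as.integer(n_sweeps), 0L, 1L,
    0, phi, rep(0, Tn), tau2, 1, 0.5,
    rep(0L, Tn), rep(1L, Tn),
    c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE), FALSE
  )
  list(trace = as.integer(res$w[, 1]), log_weights = lw)
}
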