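#' Posterior risk estimates
#'
#' Posterior medians and equal-tailed credible intervals of the disease
#' risks `R_it` for every area and time period.
#'
#' @param fit an `stcar_fit`.
#' @param level credible level (default 0.95).
#' @return a tibble with columns `area_id`, `time`, `estimate`
#'   (posterior median), `mean`, `conf.low`, `conf.high`.
#' @export
risk_estimates <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "stcar_fit"))
  a <- (1 - level) / 2
  qs <- apply(fit$samples$risk, 2, quantile, probs = c(a, 0.5, 1 - a))
  n <- fit$dims$n
  Tn <- fit$dims$n_periods
  grid <- expand.grid(area = seq_len(n), time_idx = seq_len(Tn))
  tibble::tibble(
    area_id = fit$dims$areas[grid$area],
    time = fit$dims$times[grid$time_idx],
    estimate = qs[2, ],
    mean = colMeans(fit$samples$risk),
    conf.low = qs[1, ],
    conf.high = qs[3, ]
  ) %>%
    dplyr::arrange(.data$area_id, .data$time)
}

#' Posterior distribution of the neighbourhood matrix
#'
#' Relative frequency of each candidate neighbourhood matrix among the
#' retained samples (all chains pooled); per time period for variant B.
#'
#' @param fit an `stcar_fit`.
#' @return a tibble with columns `t` (`NA` for variants A/N), `index`,
#'   `method`, `k`, `prob`.
#' @export
w_posterior <- function(fit) {
  stopifnot(inherits(fit, "stcar_fit"))
  info <- fit$candidates$info
  w <- fit$samples$w
  per_t <- fit$config$variant == "B"
  cols <- seq_len(ncol(w))
  out <- purrr::map(cols, function(ci) {
    tab <- table(factor(w[, ci], levels = info$index))
    tibble::tibble(
      t = if (per_t) ci else NA_integer_,
      index = info$index,
      method = info$method,
      k = info$k,
      prob = as.numeric(tab) / sum(tab)
    )
  })
  dplyr::bind_rows(out)
}

#' Posterior mode of the neighbourhood matrix
#'
#' The most frequently sampled candidate index (per period for variant
#' B), the estimated cluster/discontinuity structure. If several
#' candidates tie for the mode, the one whose sample subset yields the
#' smaller effective number of parameters pd is chosen, in the
#' interests of parsimony.
#'
#' @param fit an `stcar_fit`.
#' @return a tibble with columns `t` (`NA` for A/N), `index`, `method`,
#'   `k`, `prob`.
#' @export
posterior_mode_w <- function(fit) {
  stopifnot(inherits(fit, "stcar_fit"))
  info <- fit$candidates$info
  w <- fit$samples$w
  per_t <- fit$config$variant == "B"
  out <- purrr::map(seq_len(ncol(w)), function(ci) {
    tab <- table(w[, ci])
    best <- as.integer(names(tab)[tab == max(tab)])
    if (length(best) > 1) {
      pds <- vapply(best, function(ix) {
        rows <- which(w[, ci] == ix)
        dic_parts(fit, rows)["pd"]
      }, numeric(1))
      best <- best[which.min(pds)]
    } else {
      best <- best[1]
    }
    tibble::tibble(
      t = if (per_t) ci else NA_integer_,
      index = best,
      method = info$method[best],
      k = info$k[best],
      prob = max(tab) / nrow(w)
    )
  })
  dplyr::bind_rows(out)
}

#' Modal cluster partition
#'
#' The stage-1 partition that generated the posterior-mode
#' neighbourhood matrix, as per-area labels for each time period
#' (variant A repeats its single partition across periods; the
#' border-sharing mode gives the all-one-cluster partition). Labels
#' are the raw stage-1 cluster ids and are only meaningful within a
#' period; see [ari_over_periods()] for comparing partitions across
#' the whole panel.
#'
#' @param fit an `stcar_fit`.
#' @return a tibble with columns `area_id`, `time`, `label`.
#' @export
modal_partition <- function(fit) {
  mode_w <- posterior_mode_w(fit)
  Tn <- fit$dims$n_periods
  per_t <- fit$config$variant == "B"
  out <- purrr::map(seq_len(Tn), function(t) {
    ix <- if (per_t) mode_w$index[t] else mode_w$index[1]
    tibble::tibble(
      area_id = fit$dims$areas,
      time = fit$dims$times[t],
      label = fit$candidates$labels[, ix]
    )
  })
  dplyr::bind_rows(out)
}

#' Posterior summary of the number of clusters
#'
#' Maps every sampled neighbourhood matrix to its cluster count `k`
#' and summarises per period: the modal `k` (smallest on ties), a 95%
#' equal-tailed credible interval, and a formatted `"mode (lo, hi)"`
#' label. Variant A repeats its single matrix across periods.
#'
#' @param fit an `stcar_fit`.
#' @return a tibble with columns `t`, `k_mode`, `lower`, `upper`,
#'   `label`.
#' @export
cluster_counts <- function(fit) {
  stopifnot(inherits(fit, "stcar_fit"))
  info <- fit$candidates$info
  w <- fit$samples$w
  Tn <- fit$dims$n_periods
  per_t <- fit$config$variant == "B"
  out <- purrr::map(seq_len(Tn), function(t) {
    ks <- info$k[w[, if (per_t) t else 1]]
    tab <- table(ks)
    kmode <- min(as.integer(names(tab)[tab == max(tab)]))
    ci <- quantile(ks, c(0.025, 0.975), type = 1)
    tibble::tibble(
      t = t, k_mode = kmode,
      lower = as.integer(ci[1]), upper = as.integer(ci[2]),
      label = sprintf("%d (%d, %d)", kmode, ci[1], ci[2])
    )
  })
  dplyr::bind_rows(out)
}

# mean deviance and plug-in deviance over a subset of retained samples;
# the plug-in evaluates the deviance at the posterior mean of the linear
# predictor eta (well-defined across W values)
dic_parts <- function(fit, rows = NULL) {
  dm <- count_matrices(fit$data, fit$config$covariates)
  risk <- fit$samples$risk
  dev <- fit$samples$deviance
  if (!is.null(rows)) {
    risk <- risk[rows, , drop = FALSE]
    dev <- dev[rows]
  }
  eta_bar <- colMeans(log(risk))
  mu <- as.numeric(dm$E) * exp(eta_bar) # columns of risk are (i, t) cells
  d_hat <- -2 * sum(stats::dpois(as.numeric(dm$Y), mu, log = TRUE))
  c(Dbar = mean(dev), Dhat = d_hat, pd = mean(dev) - d_hat)
}

#' Deviance information criterion
#'
#' `pd = mean(D) - D(posterior mean)` with the plug-in deviance
#' evaluated at the posterior mean of the linear predictor, and
#' `DIC = mean(D) + pd`.
#'
#' @param fit an `stcar_fit`.
#' @return a named numeric vector with `DIC`, `pd`, `Dbar`, `Dhat`.
#' @export
dic <- function(fit) {
  p <- dic_parts(fit)
  c(DIC = unname(p["Dbar"] + p["pd"]), pd = unname(p["pd"]), p[c("Dbar", "Dhat")])
}

#' DIC from deviance samples
#'
#' The arithmetic core of [dic()]: given posterior deviance samples and
#' a plug-in deviance, `pd = mean(D) - D_hat` and
#' `DIC = mean(D) + pd`.
#'
#' @param deviance_samples numeric vector of sampled deviances.
#' @param deviance_at_mean plug-in deviance at the posterior mean.
#' @return named vector with `DIC` and `pd`.
#' @export
dic_pd <- function(deviance_samples, deviance_at_mean) {
  if (!length(deviance_samples)) abort("no deviance samples")
  pd <- mean(deviance_samples) - deviance_at_mean
  c(DIC = mean(deviance_samples) + pd, pd = pd)
}

#' Tidy posterior parameter summaries
#'
#' Posterior medians, standard deviations and credible intervals for
#' the model parameters (regression coefficients, temporal trend,
#' variance and dependence parameters), one row per term.
#'
#' @param x an `stcar_fit`.
#' @param level credible level.
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy stcar_fit
#' @export
tidy.stcar_fit <- function(x, level = 0.95, ...) {
  a <- (1 - level) / 2
  sm <- x$samples
  Tn <- x$dims$n_periods
  draws <- c(
    setNames(
      lapply(seq_len(ncol(sm$beta)), function(q) sm$beta[, q]),
      paste0("beta", seq_len(ncol(sm$beta)) - 1)
    ),
    setNames(
      lapply(seq_len(Tn), function(t) sm$theta[, t]),
      paste0("theta[", seq_len(Tn), "]")
    ),
    setNames(
      lapply(seq_len(Tn), function(t) sm$tau2[, t]),
      paste0("tau2[", seq_len(Tn), "]")
    ),
    list(sigma2 = sm$sigma2, alpha = sm$alpha)
  )
  if (x$config$rho_mode == "estimated") {
    rn <- if (ncol(sm$rho) == 1) "rho" else paste0("rho[", seq_len(ncol(sm$rho)), "]")
    draws <- c(draws, setNames(
      lapply(seq_len(ncol(sm$rho)), function(q) sm$rho[, q]), rn
    ))
  }
  purrr::imap(draws, function(v, nm) {
    tibble::tibble(
      term = nm,
      estimate = median(v),
      std.error = sd(v),
      conf.low = unname(quantile(v, a)),
      conf.high = unname(quantile(v, 1 - a))
    )
  }) %>% dplyr::bind_rows()
}

#' One-row model fit summary
#'
#' Model variant, sample counts and the deviance information criterion
#' with its effective number of parameters.
#'
#' @param x an `stcar_fit`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance stcar_fit
#' @export
glance.stcar_fit <- function(x, ...) {
  p <- dic_parts(x)
  tibble::tibble(
    variant = x$config$variant,
    rho_mode = x$config$rho_mode,
    n_candidates = nrow(x$candidates$info),
    n_samples = nrow(x$samples$w),
    DIC = unname(p["Dbar"] + p["pd"]),
    pd = unname(p["pd"]),
    deviance = unname(p["Dbar"])
  )
}

#' Plot the posterior risk trend
#'
#' Boxplots of the posterior-median risk estimates over the areal units
#' for each time period.
#'
#' @param object an `stcar_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot stcar_fit
#' @export
autoplot.stcar_fit <- function(object, ...) {
  re <- risk_estimates(object)
  ggplot2::ggplot(re, ggplot2::aes(
    x = factor(.data$time),
    y = .data$estimate
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(
      x = "time period", y = "posterior median risk",
      title = "Estimated disease risk over time"
    )
}

#' Plot the posterior distribution of the cluster structure
#'
#' A (cluster count) x (clustering method) grid of posterior
#' probabilities of the candidate neighbourhood matrices; the `k = 1`
#' cell is the border-sharing, no-cluster solution.
#'
#' @param fit an `stcar_fit`.
#' @param t time period to display for variant B (default 1).
#' @return a ggplot.
#' @export
plot_w_posterior <- function(fit, t = 1) {
  wp <- w_posterior(fit)
  if (fit$config$variant == "B") wp <- dplyr::filter(wp, .data$t == !!t)
  wp <- dplyr::mutate(wp, method = ifelse(.data$k == 1, "kmeans", .data$method))
  ggplot2::ggplot(wp, ggplot2::aes(
    x = factor(.data$k),
    y = .data$method, fill = .data$prob
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4") +
    ggplot2::labs(
      x = "number of clusters k", y = "clustering method",
      fill = "posterior\nprobability"
    )
}
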