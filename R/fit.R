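#' Fit the clustering-adjacency spatio-temporal model
#'
#' Fits the Bayesian Poisson log-linear disease-mapping model
#' `Y_it ~ Poisson(E_it R_it)`,
#' `log R_it = x_it' beta + phi_it + theta_t`, with per-period Leroux
#' CAR priors on the spatial surfaces `phi_t` and an AR(1) prior on the
#' temporal trend `theta`, by MCMC. The neighbourhood matrix of the CAR
#' prior is treated as a discrete parameter with a uniform prior over
#' the stage-1 candidate set and updated with a two-move
#' Metropolis-Hastings step. Variants:
#'
#' * `"A"` -- one neighbourhood matrix, common to all periods (static
#'   clusters);
#' * `"B"` -- a separate matrix and spatial dependence parameter per
#'   period (evolving clusters);
#' * `"N"` -- the non-cluster reference model: the candidate set is
#'   just the border-sharing matrix.
#'
#' With `rho = "estimated"` the spatial dependence parameter(s) get a
#' Uniform(0, 1) prior and a logit-scale random-walk update; with
#' `rho = "fixed"` they are held at `rho_fixed` (0.99 by default,
#' strictly below 1 so candidates with singleton clusters stay proper).
#' In the naming of the accompanying simulation study, variant A with
#' fixed / estimated rho is ST-A / ST-A*, likewise ST-B / ST-B*, and
#' variant N is ST-N.
#'
#' @param data long-format count data (see [read_count_data()]).
#' @param graph an [area_graph()] with the border-sharing adjacency.
#' @param variant `"A"`, `"B"` or `"N"`.
#' @param candidates optional [candidate_matrices()] result; when
#'   omitted (variants A/B) stage 1 is run internally with `K` and
#'   `methods`.
#' @param rho `"estimated"` or `"fixed"`.
#' @param rho_fixed value used when `rho = "fixed"`.
#' @param covariates optional character vector of covariate columns;
#'   an intercept is always included.
#' @param K,methods stage-1 controls (see [cluster_partitions()]).
#' @param n_iter,burn_in,thin,n_chains MCMC controls. Retained samples
#'   are the post burn-in draws of every chain, thinned.
#' @param s window half-width of W move 1 (default 2).
#' @param prior_beta_var prior variance of the regression coefficients.
#' @param prior_tau2,prior_sigma2 Inverse-Gamma (shape, scale) priors
#'   for the variance parameters; default `c(1, 0.01)`, with
#'   `c(0.001, 0.001)` and `c(0.5, 0.0005)` the usual alternatives.
#' @param seed integer seed; chain `j` uses `seed + j - 1`.
#' @param verbose print progress?
#' @return an object of class `stcar_fit`.
#' @export
fit_stcar <- function(data, graph, variant = c("A", "B", "N"),
                      candidates = NULL,
                      rho = c("estimated", "fixed"), rho_fixed = 0.99,
                      covariates = NULL, K = 10,
                      methods = stage1_methods()$method,
                      n_iter = 10000, burn_in = 5000, thin = 10,
                      n_chains = 1, s = 2,
                      prior_beta_var = 1000,
                      prior_tau2 = c(1, 0.01), prior_sigma2 = c(1, 0.01),
                      seed = 1, verbose = FALSE) {
  variant <- match.arg(variant)
  rho <- match.arg(rho)
  stopifnot(burn_in < n_iter, s >= 1)
  dm <- count_matrices(data, covariates)
  if (!identical(sort(as.character(graph$ids)), sort(as.character(dm$areas)))) {
    abort("graph area ids do not match the count data")
  }
  ord <- match(dm$areas, graph$ids)
  if (!all(ord == seq_len(graph$n))) {
    abort("graph areas must be supplied in sorted id order")
  }

  if (variant == "N") {
    # single-candidate set: the border-sharing matrix
    cands <- border_only_candidates(graph)
  } else if (is.null(candidates)) {
    res <- estimate_residuals(data, covariates)
    parts <- cluster_partitions(res,
      variant = variant, K = K,
      methods = methods, seed = seed
    )
    cands <- candidate_matrices(graph, parts,
      variant = variant,
      n_periods = dm$n_periods
    )
  } else {
    cands <- candidates
    if (!inherits(cands, "candidate_set")) abort("invalid candidate set")
    if (cands$variant != variant) abort("candidate set variant mismatch")
  }
  if (variant == "B" && cands$n_periods != dm$n_periods &&
    nrow(cands$info) > 1) {
    abort("variant B candidate set does not cover every period")
  }

  n <- dm$n
  Tn <- dm$n_periods
  M <- if (variant == "N") 1L else cands$M
  Kc <- if (variant == "N") 1L else cands$K
  lookup <- build_lookup(M, Kc, if (variant == "B") Tn else 1L)

  init <- initial_state(dm)
  flags <- rep(TRUE, 8)
  chains <- vector("list", n_chains)
  t0 <- proc.time()[3]
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    chains[[ch]] <- .stcar_mcmc(
      dm$Y, dm$E, as.numeric(dm$X), dim(dm$X)[3],
      cands$graph$edges$i - 1L, cands$graph$edges$j - 1L,
      cands$keep, cands$rowsums, cands$eigenvalues,
      lookup, M, Kc, Tn,
      variant == "B", as.integer(s),
      rho == "estimated", if (rho == "fixed") rho_fixed else 0.5,
      prior_beta_var, prior_tau2[1], prior_tau2[2],
      prior_sigma2[1], prior_sigma2[2],
      as.integer(n_iter), as.integer(burn_in), as.integer(thin),
      init$beta, init$phi, init$theta, init$tau2,
      init$sigma2, init$alpha,
      rep(0L, Tn), rep(1L, Tn),
      flags, TRUE
    )
    if (verbose) {
      message(sprintf("chain %d of %d done", ch, n_chains))
    }
  }
  elapsed <- proc.time()[3] - t0

  samples <- pool_chains(chains)
  structure(
    list(
      samples = samples,
      candidates = cands,
      data = data,
      dims = dm[c("areas", "times", "n", "n_periods")],
      config = list(
        variant = variant, rho_mode = rho, rho_fixed = rho_fixed,
        covariates = covariates, K = K, s = s,
        n_iter = n_iter, burn_in = burn_in, thin = thin,
        n_chains = n_chains, seed = seed,
        prior_beta_var = prior_beta_var,
        prior_tau2 = prior_tau2, prior_sigma2 = prior_sigma2
      ),
      acceptance = chains[[1]]$acceptance,
      runtime = elapsed
    ),
    class = "stcar_fit"
  )
}

# degenerate candidate set holding only the border-sharing matrix
border_only_candidates <- function(graph) {
  n <- graph$n
  ei <- graph$edges$i
  ej <- graph$edges$j
  rs <- tabulate(c(ei, ej), nbins = n)
  L <- base::diag(rs)
  if (length(ei)) {
    L[cbind(ei, ej)] <- -1
    L[cbind(ej, ei)] <- -1
  }
  structure(
    list(
      graph = graph, variant = "A", M = 1L, K = 1L, n_periods = 1L,
      info = tibble::tibble(
        index = 1L, c = NA_integer_, k = 1L,
        t = NA_integer_, method = "border"
      ),
      keep = matrix(TRUE, length(ei), 1),
      labels = matrix(1L, n, 1),
      rowsums = matrix(rs, n, 1),
      eigenvalues = matrix(
        rev(eigen(L, symmetric = TRUE, only.values = TRUE)$values), n, 1
      )
    ),
    class = "candidate_set"
  )
}

# lookup array (c, k, t) -> 1-based candidate index; k = 1 -> border (1)
build_lookup <- function(M, K, TT) {
  lk <- array(1L, dim = c(M, K, TT))
  if (K >= 2) {
    for (tt in seq_len(TT)) {
      for (k in 2:K) {
        for (c in seq_len(M)) {
          lk[c, k, tt] <- 1L + (tt - 1L) * M * (K - 1L) + (k - 2L) * M + c
        }
      }
    }
  }
  as.integer(lk)
}

# crude empirical initial values on the log-risk scale
initial_state <- function(dm) {
  n <- dm$n
  Tn <- dm$n_periods
  ystar <- pmax(dm$Y, 0.5)
  raw <- log(ystar / dm$E)
  b0 <- mean(raw)
  theta <- colMeans(raw) - b0
  phi <- sweep(raw, 2, colMeans(raw), "-")
  p <- dim(dm$X)[3]
  list(
    beta = c(b0, rep(0, p - 1)),
    phi = phi,
    theta = theta,
    tau2 = pmax(apply(phi, 2, var), 1e-4),
    sigma2 = max(var(theta), 1e-3),
    alpha = 0.5
  )
}

pool_chains <- function(chains) {
  bind <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  list(
    beta = bind("beta"),
    theta = bind("theta"),
    tau2 = bind("tau2"),
    sigma2 = do.call(c, lapply(chains, `[[`, "sigma2")),
    alpha = do.call(c, lapply(chains, `[[`, "alpha")),
    rho = bind("rho"),
    w = bind("w"),
    risk = bind("risk"),
    deviance = do.call(c, lapply(chains, `[[`, "deviance")),
    chain = rep(
      seq_along(chains),
      vapply(chains, function(ch) length(ch$sigma2), integer(1))
    )
  )
}

#' @export
print.stcar_fit <- function(x, ...) {
  cat("<stcar_fit> variant ", x$config$variant,
    " (rho ", x$config$rho_mode, "), ",
    x$dims$n, " areas x ", x$dims$n_periods, " periods\n",
    "  ", nrow(x$samples$w), " retained samples from ",
    x$config$n_chains, " chain(s) (",
    x$config$n_iter, " iterations, ", x$config$burn_in, " burn-in, thin ",
    x$config$thin, ")\n",
    sep = ""
  )
  g <- glance(x)
  cat(sprintf("  DIC %.1f (pd %.1f)\n", g$DIC, g$pd))
  invisible(x)
}
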