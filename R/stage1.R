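#' Registry of stage-1 clustering methods
#'
#' The eight clustering methods used to elicit candidate cluster
#' structures, keyed by the method number `c`: k-means, k-medoids (PAM),
#' agglomerative hierarchical clustering with centroid, complete,
#' average and Ward linkage, divisive (DIANA) clustering, and Gaussian
#' mixture clustering fitted by expectation-maximisation. Single
#' linkage is deliberately excluded because of its chaining behaviour.
#' All methods operate on feature values only, never on the spatial
#' positions of the areas: the clusters represent distinct risk levels,
#' not spatially contiguous regions.
#'
#' @return a tibble with columns `c` and `method`.
#' @export
stage1_methods <- function() {
  tibble::tibble(
    c = 1:8,
    method = c(
      "kmeans", "kmedoids", "agg_centroid", "agg_complete",
      "agg_average", "agg_ward", "div", "EM"
    )
  )
}

#' Estimate spatial residuals for stage-1 clustering
#'
#' Approximates the spatial random-effect surface by
#' `phi_tilde_it = ln(Y*_it / E_it) - x_it' beta_hat`, where `beta_hat`
#' is the maximum-likelihood fit of a Poisson regression with offset
#' `ln(E)` assuming independence (intercept-only when no covariates are
#' given). The overall temporal trend does not vary over space and so
#' is irrelevant to the spatial cluster structure and is not removed.
#' Because `ln(Y/E)` is undefined at zero counts, `Y*` replaces zeros
#' by `zero_adjust` (default 0.5, a standard continuity correction) in
#' the log-ratio only; the regression itself uses the observed counts.
#'
#' @param data long-format count data: a data frame with columns
#'   `area_id`, `time`, `observed`, `expected` (see [read_count_data()]).
#' @param covariates optional character vector naming covariate columns
#'   of `data`.
#' @param zero_adjust value substituted for zero counts in the
#'   log-ratio.
#' @return a tibble with columns `area_id`, `time`, `phi_tilde`, with
#'   the fitted coefficients in attribute `beta_hat`.
#' @export
estimate_residuals <- function(data, covariates = NULL, zero_adjust = 0.5) {
  data <- validate_count_data(data, covariates)
  if (any(data$expected <= 0)) abort("expected counts must be positive")
  form <- if (length(covariates)) {
    stats::as.formula(paste("observed ~", paste(covariates, collapse = " + ")))
  } else {
    observed ~ 1
  }
  fit <- stats::glm(form,
    family = poisson(), data = data,
    offset = log(data$expected)
  )
  beta_hat <- coef(fit)
  ystar <- ifelse(data$observed == 0, zero_adjust, data$observed)
  xb <- as.numeric(stats::model.matrix(fit) %*% beta_hat)
  out <- tibble::tibble(
    area_id = data$area_id,
    time = data$time,
    phi_tilde = log(ystar / data$expected) - xb
  )
  attr(out, "beta_hat") <- beta_hat
  out
}

#' Run one clustering method
#'
#' Dispatches to the method registry of [stage1_methods()] and returns
#' hard cluster labels. Clustering uses Euclidean distances on the raw
#' feature matrix (residuals are already on the log-risk scale, so no
#' standardisation is applied by default); the Gaussian mixture uses a
#' full covariance for multivariate features with assignment by maximum
#' posterior responsibility. Methods with random initialisation
#' (k-means, EM) are seeded, so results are reproducible. If a method
#' returns fewer than `k` non-empty clusters (component collapse, ties)
#' the partition is kept as-is.
#'
#' @param x numeric feature matrix (rows = areas) or vector.
#' @param method method name or number per [stage1_methods()].
#' @param k target number of clusters, `1 <= k <= nrow(x)`.
#' @param seed integer seed.
#' @param standardise scale columns of `x` to unit variance first?
#' @return integer vector of cluster labels.
#' @export
run_clustering <- function(x, method, k, seed = 1, standardise = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) abort("k cannot exceed the number of areas")
  if (is.numeric(method)) method <- stage1_methods()$method[method]
  if (!method %in% stage1_methods()$method) {
    abort(paste0("unknown clustering method: ", method))
  }
  if (k == 1) return(rep(1L, n))
  if (standardise) {
    s <- apply(x, 2, sd)
    x <- sweep(x, 2, ifelse(s > 0, s, 1), "/")
  }
  # degenerate features: no structure to find
  if (all(apply(x, 2, function(col) max(col) - min(col)) < 1e-12)) {
    return(rep(1L, n))
  }
  set.seed(seed)
  labels <- switch(method,
    kmeans = kmeans(x, centers = k, nstart = 10, iter.max = 100)$cluster,
    kmedoids = cluster::pam(x, k = k, metric = "euclidean", cluster.only = TRUE),
    agg_centroid = cutree(hclust(dist(x)^2, method = "centroid"), k = k),
    agg_complete = cutree(hclust(dist(x), method = "complete"), k = k),
    agg_average = cutree(hclust(dist(x), method = "average"), k = k),
    agg_ward = cutree(hclust(dist(x), method = "ward.D2"), k = k),
    div = cutree(stats::as.hclust(cluster::diana(dist(x))), k = k),
    EM = em_cluster(x, k)
  )
  as.integer(labels)
}

# Gaussian mixture by EM with hard assignment; falls back through simpler
# covariance models if the requested one fails to fit, then to k-means.
em_cluster <- function(x, k) {
  models <- if (ncol(x) > 1) c("VVV", "EEE", "EII") else c("V", "E")
  for (mn in models) {
    fit <- tryCatch(
      suppressWarnings(
        mclust::Mclust(x, G = k, modelNames = mn, verbose = FALSE)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && !is.null(fit$classification)) {
      return(fit$classification)
    }
  }
  kmeans(x, centers = k, nstart = 10, iter.max = 100)$cluster
}

#' Stage-1 cluster partitions
#'
#' Applies every clustering method for every cluster count
#' `k = 2, ..., K` to the estimated residual surface, producing the
#' partitions behind the candidate neighbourhood matrices. Variant A
#' clusters each area's length-T residual profile (one partition per
#' `(c, k)`, constant over time); variant B clusters each period's
#' length-n residual vector separately (one partition per `(c, k, t)`).
#' The `k = 1` solution is the same all-one-cluster partition for every
#' method and is implied rather than stored.
#'
#' @param residuals tibble from [estimate_residuals()], or any data
#'   frame with columns `area_id`, `time` and `phi_tilde`.
#' @param variant `"A"` or `"B"`.
#' @param K maximum number of clusters (risk levels), default 10.
#' @param methods subset of method names (default: all eight).
#' @param seed integer seed; each `(c, k, t)` request is seeded
#'   deterministically from it.
#' @param standardise passed to [run_clustering()].
#' @return a tibble with columns `c`, `method`, `k`, `t` (`NA` for
#'   variant A), `area` (internal index), `area_id`, `label`.
#' @export
cluster_partitions <- function(residuals, variant = c("A", "B"), K = 10,
                               methods = stage1_methods()$method,
                               seed = 1, standardise = FALSE) {
  variant <- match.arg(variant)
  reg <- dplyr::filter(stage1_methods(), .data$method %in% methods)
  if (nrow(reg) == 0) abort("no valid clustering methods selected")
  wide <- residuals_matrix(residuals)
  areas <- sort(unique(residuals$area_id))
  n <- nrow(wide)
  n_periods <- ncol(wide)
  grid <- if (variant == "A") {
    expand.grid(c = reg$c, k = 2:K, t = NA_integer_)
  } else {
    expand.grid(c = reg$c, k = 2:K, t = seq_len(n_periods))
  }
  res <- purrr::pmap(grid, function(c, k, t) {
    feats <- if (is.na(t)) wide else wide[, t, drop = FALSE]
    sub_seed <- (seed + 7919L * c + 131L * k +
      ifelse(is.na(t), 0L, 17L * t)) %% .Machine$integer.max
    lab <- run_clustering(feats, c, k,
      seed = sub_seed,
      standardise = standardise
    )
    tibble::tibble(
      c = c, k = k, t = t, area = seq_len(n), area_id = areas,
      label = lab
    )
  })
  dplyr::bind_rows(res) %>%
    dplyr::left_join(stage1_methods(), by = "c") %>%
    dplyr::select(
      "c", "method", "k", "t", "area", "area_id", "label"
    )
}

# long residual tibble -> n x T matrix, areas in sorted-id order
residuals_matrix <- function(residuals) {
  areas <- sort(unique(residuals$area_id))
  times <- sort(unique(residuals$time))
  wide <- matrix(NA_real_, length(areas), length(times),
    dimnames = list(as.character(areas), as.character(times))
  )
  wide[cbind(
    match(residuals$area_id, areas),
    match(residuals$time, times)
  )] <- residuals$phi_tilde
  if (anyNA(wide)) abort("residual surface has missing (area, time) cells")
  wide
}
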