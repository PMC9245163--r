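#' Leroux CAR precision matrix
#'
#' Builds `Q(rho, W) = rho * (diag(W1) - W) + (1 - rho) * I`, the
#' precision of the Leroux conditional autoregressive prior. `rho = 0`
#' gives independence (the identity); `rho -> 1` approaches the
#' intrinsic CAR. `rho` must be strictly below 1 so that `Q` stays
#' positive definite even when the graph has isolated areas (a
#' singleton cluster has row sum zero and its diagonal entry is
#' `1 - rho`).
#'
#' @param rho spatial dependence parameter in `[0, 1)`.
#' @param W symmetric binary adjacency matrix (base or Matrix), or an
#'   [area_graph()].
#' @return a sparse symmetric matrix.
#' @export
#' @examples
#' g <- area_graph(data.frame(i = c(1, 2), j = c(2, 3)))
#' leroux_precision(0.5, g)
leroux_precision <- function(rho, W) {
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  if (inherits(W, "area_graph")) W <- W$W
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  n <- nrow(W)
  rs <- Matrix::rowSums(W)
  rho * (Matrix::Diagonal(n, rs) - W) + (1 - rho) * Matrix::Diagonal(n)
}

#' Log-density of a Leroux CAR surface
#'
#' Evaluates the log-density of `phi ~ N(0, tau2 * Q(rho, W)^-1)`. The
#' log-determinant uses the cached eigenvalues `lambda_i` of
#' `diag(W1) - W` when supplied, via
#' `log det Q = sum(log(rho * lambda_i + 1 - rho))`, so no factorisation
#' of `Q` is needed; the quadratic form is evaluated through the edge
#' list, exploiting `phi' (diag(W1) - W) phi = sum_edges (phi_i - phi_j)^2`.
#'
#' @param phi numeric vector of spatial random effects.
#' @param W adjacency matrix or [area_graph()].
#' @param rho dependence parameter in `[0, 1)`.
#' @param tau2 variance parameter (> 0).
#' @param eigenvalues optional precomputed eigenvalues of `diag(W1) - W`.
#' @return the log-density (a scalar).
#' @export
car_logdensity <- function(phi, W, rho, tau2, eigenvalues = NULL) {
  if (tau2 <= 0) abort("tau2 must be positive")
  if (inherits(W, "area_graph")) W <- W$W
  n <- length(phi)
  if (is.null(eigenvalues)) {
    L <- as.matrix(Matrix::Diagonal(n, Matrix::rowSums(W)) - W)
    eigenvalues <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  }
  Q <- leroux_precision(rho, W)
  quad <- as.numeric(phi %*% (Q %*% phi))
  -n / 2 * log(2 * pi * tau2) + sum(log(rho * eigenvalues + 1 - rho)) / 2 -
    quad / (2 * tau2)
}

#' Full conditional of one CAR random effect
#'
#' The Leroux prior is defined through its univariate full
#' conditionals: area `i` given the rest is Gaussian with mean
#' `rho * sum_j w_ij phi_j / (rho * sum_j w_ij + 1 - rho)` and variance
#' `tau2 / (rho * sum_j w_ij + 1 - rho)`. An isolated area (row sum 0)
#' has mean 0 and variance `tau2 / (1 - rho)`.
#'
#' @param i area index.
#' @param phi numeric vector of current values.
#' @inheritParams car_logdensity
#' @return a list with elements `mean` and `variance`.
#' @export
car_full_conditional <- function(i, phi, W, rho, tau2) {
  if (inherits(W, "area_graph")) W <- W$W
  wi <- as.numeric(W[i, ])
  d <- rho * sum(wi) + 1 - rho
  list(mean = rho * sum(wi * phi) / d, variance = tau2 / d)
}

#' Partial correlation implied by a CAR prior
#'
#' The partial correlation between `phi_i` and `phi_j` given the rest
#' under the Leroux prior is
#' `rho * w_ij / sqrt((rho * d_i + 1 - rho) * (rho * d_j + 1 - rho))`
#' with `d_i` the row sum of `W`; it is zero exactly when the areas are
#' not neighbours, which is how severing an edge encodes a risk
#' discontinuity.
#'
#' @param i,j distinct area indices.
#' @inheritParams car_logdensity
#' @return the partial correlation (a scalar).
#' @export
car_partial_correlation <- function(i, j, W, rho) {
  if (i == j) abort("i and j must differ")
  if (inherits(W, "area_graph")) W <- W$W
  rs <- Matrix::rowSums(W)
  rho * as.numeric(W[i, j]) /
    sqrt((rho * rs[i] + 1 - rho) * (rho * rs[j] + 1 - rho))
}
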