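#' Synthetic lattice geography
#'
#' Deterministic rook-adjacency lattice used as the synthetic study
#' region: the largest full `s x s` grid with `s = floor(sqrt(n))`, and
#' any remaining cells appended as a partial extra row below it (each
#' appended cell is adjacent to the cell above and to its horizontal
#' neighbour in the partial row). `n = 257` therefore gives a 16 x 16
#' grid plus one appended cell.
#'
#' @param n number of areas (>= 4).
#' @return an [area_graph()] with a `coords` element giving lattice
#'   row/column positions.
#' @export
make_geography <- function(n) {
  if (n < 4) abort("the lattice needs at least 4 areas")
  s <- floor(sqrt(n))
  extra <- n - s * s
  row <- c(rep(seq_len(s), each = s), rep(s + 1, extra))
  col <- c(rep(seq_len(s), times = s), seq_len(extra))
  ei <- integer(0)
  ej <- integer(0)
  idx <- function(r, cc) ifelse(r <= s, (r - 1) * s + cc, s * s + cc)
  for (a in seq_len(n)) {
    r <- row[a]
    cc <- col[a]
    # right neighbour
    b <- which(row == r & col == cc + 1)
    if (length(b)) {
      ei <- c(ei, a)
      ej <- c(ej, b)
    }
    # below neighbour
    b <- which(row == r + 1 & col == cc)
    if (length(b)) {
      ei <- c(ei, a)
      ej <- c(ej, b)
    }
  }
  g <- new_area_graph(n, seq_len(n), pmin(ei, ej), pmax(ei, ej))
  g$coords <- tibble::tibble(area = seq_len(n), row = row, col = col)
  g
}

#' Expected counts emulating an urban study region
#'
#' Draws per-area expected counts (constant over time) from a
#' split-lognormal centred at median 74.09 and calibrated so that at
#' `n = 257` the simulated range is close to 12.61--160.15, the spread
#' of yearly expected respiratory hospitalisation counts across the
#' intermediate zones of a city of about one million people. Dividing
#' by the scale factor `SF` in {1, 2, 4} yields progressively rarer
#' diseases.
#'
#' @param n number of areas.
#' @param n_periods number of time periods.
#' @param SF scale factor (1, 2 or 4).
#' @param seed integer seed.
#' @return an `n x n_periods` matrix of positive expected counts.
#' @export
make_expected_counts <- function(n, n_periods, SF = 1, seed = 1) {
  if (!SF %in% c(1, 2, 4)) abort("SF must be 1, 2 or 4")
  set.seed(seed)
  med <- 74.09
  lo <- 12.61
  hi <- 160.15
  zmax <- qnorm(257 / 258) # expected extreme of n = 257 draws
  s_lo <- log(med / lo) / zmax
  s_hi <- log(hi / med) / zmax
  z <- rnorm(n)
  e <- exp(log(med) + ifelse(z < 0, s_lo, s_hi) * z)
  matrix(e / SF, n, n_periods)
}

#' Piecewise-constant cluster mean surfaces
#'
#' Builds the `n x T` mean surface `mu` with entries in `{-Z, 0, Z}`
#' that induces clustering in the simulated spatial random effects.
#' The template partitions the lattice into three contiguous risk
#' levels -- roughly 20% of areas in a high-risk set grown from two
#' lattice seeds, 20% in a low-risk set, and the rest at baseline --
#' mimicking a city with pockets of elevated and reduced risk. Case 1
#' keeps the template fixed over time; case 2 lets it evolve by
#' re-assigning a small random fraction of areas to a different level
#' at each successive period.
#'
#' @param graph lattice from [make_geography()].
#' @param case `"1"` (static clusters) or `"2"` (evolving clusters).
#' @param Z cluster magnitude (>= 0); `Z = 0` gives no clusters.
#' @param n_periods number of time periods.
#' @param flip_frac fraction of areas changing level per period under
#'   case 2 (default 0.03).
#' @param seed integer seed (used by case 2 flips only).
#' @return a list with `mu` (`n x T` matrix) and `levels`
#'   (`n x T` integer matrix, 1 = low, 2 = baseline, 3 = high).
#' @export
make_cluster_means <- function(graph, case = c("1", "2"), Z = 1,
                               n_periods = 7, flip_frac = 0.03, seed = 1) {
  n <- graph$n
  if (Z == 0) {
    return(list(
      mu = matrix(0, n, n_periods),
      levels = matrix(2L, n, n_periods)
    ))
  }
  case <- match.arg(as.character(case), c("1", "2"))
  base <- template_levels(graph)
  levels <- matrix(base, n, n_periods)
  if (case == "2" && flip_frac > 0) {
    set.seed(seed)
    m <- max(1L, round(flip_frac * n))
    for (t in 2:n_periods) {
      levels[, t] <- levels[, t - 1]
      pick <- sample.int(n, m)
      for (a in pick) {
        levels[a, t] <- sample(setdiff(1:3, levels[a, t]), 1)
      }
    }
  }
  list(mu = Z * (levels - 2), levels = levels)
}

# deterministic contiguous template: high-risk blobs grown by
# breadth-first search from two lattice seeds (~20% of areas), low-risk
# blobs from two other seeds (~20%), remainder baseline
template_levels <- function(graph) {
  n <- graph$n
  nbr <- vector("list", n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[e]
    j <- graph$edges$j[e]
    nbr[[i]] <- c(nbr[[i]], j)
    nbr[[j]] <- c(nbr[[j]], i)
  }
  grow <- function(seeds, size, taken) {
    got <- integer(0)
    frontier <- seeds[!(seeds %in% taken)]
    while (length(got) < size && length(frontier)) {
      a <- frontier[1]
      frontier <- frontier[-1]
      if (a %in% c(got, taken)) next
      got <- c(got, a)
      frontier <- c(frontier, setdiff(nbr[[a]], c(got, taken, frontier)))
    }
    got
  }
  target <- round(0.2 * n)
  # seeds: opposite corners for the high set, mid-edges for the low set
  high <- grow(c(1L, n), target, integer(0))
  low <- grow(c(as.integer(round(n / 2)), as.integer(round(n / 4))), target, high)
  lev <- rep(2L, n)
  lev[high] <- 3L
  lev[low] <- 1L
  lev
}

#' Simulate a spatio-temporal count dataset
#'
#' Generates data from the Poisson log-linear model with a piecewise
#' constant cluster mean: the temporal trend `theta` follows the AR(1)
#' process (`theta_1 ~ N(0, sigma2)`,
#' `theta_t ~ N(alpha * theta_{t-1}, sigma2)`); each period's spatial
#' surface is drawn as `phi_t ~ N(mu_t, tau2 * Q(rho, W)^-1)` with the
#' Leroux precision on the *border-sharing* lattice graph; risks are
#' `R_it = exp(phi_it + theta_t)` and counts
#' `Y_it ~ Poisson(E_it * R_it)`. Defaults mirror a seven-year study of
#' 257 areas with strong temporal dependence (`alpha = 0.9`,
#' `sigma2 = 0.1`) and small residual spatial noise (`tau2 = 0.001`).
#'
#' @param case `"1"`, `"2"` or `"none"` (forced when `Z = 0`).
#' @param Z cluster magnitude, 0, 0.5 or 1.
#' @param SF expected-count scale factor, 1, 2 or 4.
#' @param rho true spatial dependence (0, 0.3, 0.6 or 0.9).
#' @param alpha,sigma2,tau2 generating parameters of the random
#'   effects.
#' @param n,n_periods panel dimensions.
#' @param flip_frac case-2 per-period flip fraction.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @param graph optional [area_graph()]; defaults to
#'   `make_geography(n)`.
#' @return an object of class `stcar_sim`: list with `data` (long count
#'   tibble), `graph`, `truth` (tibble of `mu`, `level`, `phi`,
#'   `theta`, `risk` per area and period) and `params`.
#' @export
simulate_st_data <- function(case = "1", Z = 1, SF = 1, rho = 0.9,
                             alpha = 0.9, sigma2 = 0.1, tau2 = 0.001,
                             n = 257, n_periods = 7, flip_frac = 0.03,
                             seed = 1, graph = NULL) {
  if (Z == 0) case <- "none"
  if (Z > 0 && identical(as.character(case), "none")) {
    abort("a cluster case must be given when Z > 0")
  }
  if (is.null(graph)) graph <- make_geography(n)
  n <- graph$n
  E <- make_expected_counts(n, n_periods, SF = SF, seed = seed)
  means <- if (identical(as.character(case), "none")) {
    list(mu = matrix(0, n, n_periods), levels = matrix(2L, n, n_periods))
  } else {
    make_cluster_means(graph, case, Z, n_periods, flip_frac, seed = seed)
  }
  set.seed(seed + 1L)
  theta <- numeric(n_periods)
  theta[1] <- rnorm(1, 0, sqrt(sigma2))
  for (t in seq_len(n_periods)[-1]) {
    theta[t] <- rnorm(1, alpha * theta[t - 1], sqrt(sigma2))
  }
  Q <- leroux_precision(rho, graph)
  U <- Matrix::chol(Q)
  phi <- sapply(seq_len(n_periods), function(t) {
    means$mu[, t] +
      sqrt(tau2) * as.numeric(Matrix::solve(U, rnorm(n)))
  })
  risk <- exp(sweep(phi, 2, theta, "+"))
  Y <- matrix(rpois(n * n_periods, lambda = E * risk), n, n_periods)
  grid <- expand.grid(time = seq_len(n_periods), area = seq_len(n))
  grid <- grid[order(grid$area, grid$time), ]
  data <- tibble::tibble(
    area_id = graph$ids[grid$area],
    time = grid$time,
    observed = Y[cbind(grid$area, grid$time)],
    expected = E[cbind(grid$area, grid$time)]
  )
  truth <- tibble::tibble(
    area_id = graph$ids[grid$area],
    time = grid$time,
    mu = means$mu[cbind(grid$area, grid$time)],
    level = means$levels[cbind(grid$area, grid$time)],
    phi = phi[cbind(grid$area, grid$time)],
    theta = theta[grid$time],
    risk = risk[cbind(grid$area, grid$time)]
  )
  structure(
    list(
      data = data, graph = graph, truth = truth,
      params = list(
        case = as.character(case), Z = Z, SF = SF, rho = rho,
        alpha = alpha, sigma2 = sigma2, tau2 = tau2,
        n = n, n_periods = n_periods, flip_frac = flip_frac, seed = seed
      )
    ),
    class = "stcar_sim"
  )
}

#' Simulate a model-free scenario
#'
#' Fixes the risks of the high, baseline and low template levels at the
#' constant values `exp(Z)`, 1 and `exp(-Z)` (no random effects at
#' all), and draws `Y_it ~ Poisson(E_it * R_it)`. This probes the
#' models away from their own generating assumptions.
#'
#' @inheritParams simulate_st_data
#' @return an `stcar_sim` object (with `phi`/`theta` zero in the
#'   truth table).
#' @export
simulate_model_free <- function(Z = 1, SF = 1, n = 257, n_periods = 7,
                                seed = 1, graph = NULL) {
  if (Z <= 0) abort("the model-free scenario needs Z > 0")
  if (is.null(graph)) graph <- make_geography(n)
  n <- graph$n
  E <- make_expected_counts(n, n_periods, SF = SF, seed = seed)
  lev <- template_levels(graph)
  levels <- matrix(lev, n, n_periods)
  risk <- matrix(exp(Z * (lev - 2)), n, n_periods)
  set.seed(seed + 1L)
  Y <- matrix(rpois(n * n_periods, lambda = E * risk), n, n_periods)
  grid <- expand.grid(time = seq_len(n_periods), area = seq_len(n))
  grid <- grid[order(grid$area, grid$time), ]
  structure(
    list(
      data = tibble::tibble(
        area_id = graph$ids[grid$area],
        time = grid$time,
        observed = Y[cbind(grid$area, grid$time)],
        expected = E[cbind(grid$area, grid$time)]
      ),
      graph = graph,
      truth = tibble::tibble(
        area_id = graph$ids[grid$area],
        time = grid$time,
        mu = Z * (levels[cbind(grid$area, grid$time)] - 2),
        level = levels[cbind(grid$area, grid$time)],
        phi = 0, theta = 0,
        risk = risk[cbind(grid$area, grid$time)]
      ),
      params = list(
        case = "model_free", Z = Z, SF = SF, n = n,
        n_periods = n_periods, seed = seed
      )
    ),
    class = "stcar_sim"
  )
}

#' The simulation-study scenario grid
#'
#' Enumerates the 30 sub-scenarios of the simulation design: both
#' cluster cases with `Z` in {1, 0.5} crossed with scale factors
#' {1, 2, 4} at strong dependence (`rho = 0.9`); the no-cluster
#' `Z = 0` row for each scale factor; and both cases (plus `Z = 0`)
#' crossed with `rho` in {0.6, 0.3, 0} at `SF = 1`.
#'
#' @return a tibble with columns `case`, `Z`, `SF`, `rho`.
#' @export
scenario_grid <- function() {
  dplyr::bind_rows(
    expand.grid(
      case = c("1", "2"), Z = c(1, 0.5), SF = c(1, 2, 4), rho = 0.9,
      stringsAsFactors = FALSE
    ),
    expand.grid(
      case = "none", Z = 0, SF = c(1, 2, 4), rho = 0.9,
      stringsAsFactors = FALSE
    ),
    expand.grid(
      case = c("1", "2"), Z = c(1, 0.5), SF = 1, rho = c(0.6, 0.3, 0),
      stringsAsFactors = FALSE
    ),
    expand.grid(
      case = "none", Z = 0, SF = 1, rho = c(0.6, 0.3, 0),
      stringsAsFactors = FALSE
    )
  ) %>% tibble::as_tibble()
}
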