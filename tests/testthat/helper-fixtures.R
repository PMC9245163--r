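# shared fixtures, built in code

path_graph <- function() {
  # 1 - 2 - 3
  area_graph(data.frame(from = c(1, 2), to = c(2, 3)))
}

grid2x2_graph <- function() {
  area_graph(data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4)))
}

random_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  area_graph(
    data.frame(from = pairs[1, keep], to = pairs[2, keep]),
    ids = seq_len(n)
  )
}

# a small partitions tibble covering c in 1..M, k in 2..K (and t for
# variant B), with deterministic pseudo-random labels
fake_partitions <- function(n, M, K, n_periods = NULL, seed = 1) {
  set.seed(seed)
  grid <- if (is.null(n_periods)) {
    expand.grid(c = seq_len(M), k = 2:K, t = NA_integer_)
  } else {
    expand.grid(c = seq_len(M), k = 2:K, t = seq_len(n_periods))
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$k[i]
    lab <- sample(rep_len(seq_len(k), n))
    tibble::tibble(
      c = grid$c[i], k = k, t = grid$t[i],
      area = seq_len(n), area_id = seq_len(n),
      label = lab
    )
  })
  dplyr::bind_rows(out) %>%
    dplyr::left_join(stage1_methods(), by = "c") %>%
    dplyr::select("c", "method", "k", "t", "area", "area_id", "label")
}

# small complete panel in long format
toy_counts <- function(Y, E) {
  n <- nrow(Y)
  Tn <- ncol(Y)
  grid <- expand.grid(time = seq_len(Tn), area = seq_len(n))
  grid <- grid[order(grid$area, grid$time), ]
  tibble::tibble(
    area_id = grid$area, time = grid$time,
    observed = Y[cbind(grid$area, grid$time)],
    expected = E[cbind(grid$area, grid$time)]
  )
}

# dense-matrix Leroux precision, the brute-force counterpart of
# leroux_precision()
dense_Q <- function(rho, W) {
  W <- as.matrix(W)
  rho * (diag(rowSums(W)) - W) + (1 - rho) * diag(nrow(W))
}

# brute-force adjusted Rand index by counting the four pair categories
pair_count_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      if (!sa && !sb) s00 <- s00 + 1
      if (sa && !sb) s10 <- s10 + 1
      if (!sa && sb) s01 <- s01 + 1
    }
  }
  num <- choose(n, 2) * (s11 + s00) -
    ((s11 + s10) * (s11 + s01) + (s00 + s10) * (s00 + s01))
  den <- choose(n, 2)^2 -
    ((s11 + s10) * (s11 + s01) + (s00 + s10) * (s00 + s01))
  if (den == 0) 1 else num / den
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, m) {
    i <- length(labels) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (l in seq_len(m + 1)) rec(c(labels, l), max(m, l))
  }
  rec(integer(0), 0)
  out
}

# small simulated dataset + fitted model, cached across test files
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    g <- make_geography(25)
    sim <- simulate_st_data(
      case = "1", Z = 1, SF = 1, rho = 0.9,
      n = 25, n_periods = 3, seed = 42, graph = g
    )
    fit <- fit_stcar(sim$data, g,
      variant = "A", rho = "estimated", K = 4,
      n_iter = 1500, burn_in = 700, thin = 4, seed = 7
    )
    tiny_fit_cache$sim <- sim
    tiny_fit_cache$fit <- fit
  }
  list(sim = tiny_fit_cache$sim, fit = tiny_fit_cache$fit)
}
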