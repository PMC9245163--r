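#' Read long-format areal count data
#'
#' Reads (or validates) a complete `n x T` panel of observed and
#' expected disease counts in long format. Required columns are
#' `area_id`, `time`, `observed` and `expected`; any further columns
#' named in `covariates` are kept. Every (area, time) cell must appear
#' exactly once; row order is irrelevant.
#'
#' @param x a file path to a CSV, or a data frame.
#' @param covariates optional character vector of covariate column
#'   names.
#' @return a tibble sorted by area then time, with attributes `n`
#'   (areas) and `n_periods`.
#' @export
read_count_data <- function(x, covariates = NULL) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(paste0("file not found: ", x))
    x <- read.csv(x)
  }
  validate_count_data(x, covariates)
}

validate_count_data <- function(data, covariates = NULL) {
  need <- c("area_id", "time", "observed", "expected", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("count data lacks columns: ", paste(miss, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[, need]
  if (any(data$expected <= 0)) abort("expected counts must be positive")
  if (any(data$observed < 0) ||
    any(data$observed != round(data$observed))) {
    abort("observed counts must be non-negative integers")
  }
  areas <- sort(unique(data$area_id))
  times <- sort(unique(data$time))
  if (nrow(data) != length(areas) * length(times)) {
    abort("count data is not a complete n x T panel")
  }
  if (anyDuplicated(data[, c("area_id", "time")])) {
    abort("duplicated (area_id, time) rows")
  }
  data <- dplyr::arrange(data, match(.data$area_id, areas), match(.data$time, times))
  attr(data, "n") <- length(areas)
  attr(data, "n_periods") <- length(times)
  data
}

# long data -> list of n x T matrices in sorted area/time order
count_matrices <- function(data, covariates = NULL) {
  data <- validate_count_data(data, covariates)
  areas <- sort(unique(data$area_id))
  times <- sort(unique(data$time))
  n <- length(areas)
  Tn <- length(times)
  # data is sorted by area then time -> fill row by row
  Y <- matrix(data$observed, n, Tn, byrow = TRUE)
  E <- matrix(data$expected, n, Tn, byrow = TRUE)
  X <- array(1, dim = c(n, Tn, 1 + length(covariates)))
  if (length(covariates)) {
    for (p in seq_along(covariates)) {
      X[, , p + 1] <- matrix(data[[covariates[p]]], n, Tn, byrow = TRUE)
    }
  }
  list(Y = Y, E = E, X = X, areas = areas, times = times, n = n, n_periods = Tn)
}

#' Write a simulated dataset to CSV files
#'
#' Writes the count panel, the adjacency edge list and the truth table
#' of a simulation from [simulate_st_data()] or
#' [simulate_model_free()] as plain CSV, so a simulated study can be
#' re-loaded with [read_count_data()] / [area_graph()].
#'
#' @param sim an `stcar_sim` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "stcar_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.csv", "adjacency.csv", "truth.csv"))
  write.csv(sim$data, paths[1], row.names = FALSE)
  write.csv(sim$graph$edges, paths[2], row.names = FALSE)
  write.csv(sim$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
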