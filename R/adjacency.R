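#' Areal adjacency graph
#'
#' Builds the symmetric binary neighbourhood structure of a set of `n`
#' areal units. Under the usual border-sharing specification `w_ij = 1`
#' when areas `i` and `j` share a common geographical border and 0
#' otherwise; the matrix has a zero diagonal. Disconnected graphs are
#' permitted (study regions split by rivers or islands are common).
#'
#' @param x one of: a data frame whose first two columns give pairs of
#'   neighbouring area ids (an edge list); a symmetric binary 0/1 matrix
#'   with zero diagonal; or a path to a file holding either format
#'   (`.gal` neighbour files, a two-column CSV edge list, or a dense CSV
#'   matrix).
#' @param ids optional vector of area ids fixing the ordering (and any
#'   isolated areas missing from an edge list). Defaults to the sorted
#'   unique ids seen in `x`.
#' @param n optional number of areas; when supplied with integer ids the
#'   id set is taken to be `1:n`.
#'
#' @return an object of class `area_graph`: a list with elements `n`,
#'   `ids`, `edges` (tibble of internal 1-based index pairs `i < j`) and
#'   `W` (sparse symmetric binary matrix).
#' @export
#' @examples
#' g <- area_graph(data.frame(from = c(1, 2), to = c(2, 3)))
#' g$n
area_graph <- function(x, ids = NULL, n = NULL) {
  if (is.character(x) && length(x) == 1) {
    return(read_adjacency(x, ids = ids, n = n))
  }
  if (is.matrix(x) || inherits(x, "Matrix")) {
    W <- as.matrix(x)
    if (nrow(W) != ncol(W)) abort("adjacency matrix must be square")
    if (any(W != t(W))) abort("adjacency matrix must be symmetric")
    if (any(base::diag(W) != 0)) abort("adjacency matrix must have zero diagonal")
    if (!all(W %in% c(0, 1))) abort("adjacency entries must be 0/1")
    if (is.null(ids)) ids <- if (!is.null(rownames(W))) rownames(W) else seq_len(nrow(W))
    idx <- which(upper.tri(W) & W == 1, arr.ind = TRUE)
    return(new_area_graph(nrow(W), ids, idx[, 1], idx[, 2]))
  }
  if (is.data.frame(x)) {
    a <- x[[1]]
    b <- x[[2]]
    if (any(a == b)) abort("self-pairs are not allowed in an edge list")
    if (is.null(ids)) {
      ids <- if (!is.null(n)) seq_len(n) else sort(unique(c(a, b)))
    }
    i <- match(a, ids)
    j <- match(b, ids)
    if (anyNA(i) || anyNA(j)) abort("edge list contains area ids outside the id set")
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    keep <- !duplicated(cbind(lo, hi))
    return(new_area_graph(length(ids), ids, lo[keep], hi[keep]))
  }
  abort("cannot interpret `x` as an adjacency specification")
}

new_area_graph <- function(n, ids, ei, ej) {
  stopifnot(length(ids) == n, all(ei >= 1), all(ej <= n), all(ei < ej))
  o <- order(ei, ej)
  ei <- as.integer(ei[o])
  ej <- as.integer(ej[o])
  W <- Matrix::sparseMatrix(
    i = c(ei, ej), j = c(ej, ei), x = 1,
    dims = c(n, n)
  )
  structure(
    list(
      n = as.integer(n),
      ids = ids,
      edges = tibble::tibble(i = ei, j = ej),
      W = W
    ),
    class = "area_graph"
  )
}

#' @export
print.area_graph <- function(x, ...) {
  cat("<area_graph> ", x$n, " areas, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Candidate neighbourhood matrix from a cluster partition
#'
#' Converts a partition of the areas into risk-level clusters into a
#' candidate neighbourhood matrix: an entry is 1 only when the two areas
#' both share a border *and* sit in the same cluster, so cluster
#' boundaries sever edges of the border-sharing graph and the random
#' effects either side of a boundary become conditionally independent.
#' A candidate is therefore always an (entrywise) subgraph of the
#' border-sharing matrix.
#'
#' @param graph an [area_graph()].
#' @param labels integer vector of cluster labels, one per area in
#'   internal order.
#' @return a sparse symmetric binary matrix.
#' @export
candidate_from_partition <- function(graph, labels) {
  stopifnot(inherits(graph, "area_graph"))
  if (length(labels) != graph$n) {
    abort("partition length does not match the number of areas")
  }
  keep <- labels[graph$edges$i] == labels[graph$edges$j]
  ei <- graph$edges$i[keep]
  ej <- graph$edges$j[keep]
  Matrix::sparseMatrix(
    i = c(ei, ej), j = c(ej, ei), x = rep(1, 2 * length(ei)),
    dims = c(graph$n, graph$n)
  )
}

#' Assemble the candidate neighbourhood-matrix set
#'
#' Collects the stage-1 partitions into the indexed family of candidate
#' neighbourhood matrices that forms the support of the discrete uniform
#' prior in stage 2. All `k = 1` solutions are identical to the
#' border-sharing matrix and are collapsed to a single shared entry, so
#' variant A has `(K - 1) * M + 1` candidates and variant B (one
#' partition per time period) has `(K - 1) * M * T + 1`. Duplicate
#' matrices arising at `k >= 2` from different methods are retained as
#' separate prior atoms. The eigenvalues of `diag(W1) - W` are computed
#' once per candidate and cached; they give the log-determinant of the
#' Leroux precision `Q(rho, W)` for any `rho` in O(n).
#'
#' @param graph an [area_graph()].
#' @param partitions tibble as produced by [cluster_partitions()]:
#'   columns `c` (method number), `method`, `k`, `t` (`NA` for variant
#'   A), `area` (internal index) and `label`.
#' @param variant `"A"` (one matrix for all periods) or `"B"` (one per
#'   period).
#' @param n_periods number of time periods (required for variant B).
#' @return an object of class `candidate_set`.
#' @export
candidate_matrices <- function(graph, partitions, variant = c("A", "B"),
                               n_periods = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(graph, "area_graph"))
  p <- dplyr::filter(partitions, .data$k >= 2)
  M <- max(partitions$c)
  K <- max(partitions$k)
  if (variant == "A") {
    p$t <- NA_integer_
    n_periods <- 1L
    combos <- expand.grid(c = seq_len(M), k = 2:K)
    combos$t <- NA_integer_
  } else {
    if (is.null(n_periods)) n_periods <- max(partitions$t, na.rm = TRUE)
    combos <- expand.grid(c = seq_len(M), k = 2:K, t = seq_len(n_periods))
  }
  key <- function(c, k, t) paste(c, k, ifelse(is.na(t), 0L, t), sep = "_")
  have <- unique(key(p$c, p$k, p$t))
  need <- key(combos$c, combos$k, combos$t)
  if (!all(need %in% have)) {
    abort(paste0(
      "missing partitions for ",
      sum(!(need %in% have)), " (method, k[, t]) combinations"
    ))
  }

  n <- graph$n
  ei <- graph$edges$i
  ej <- graph$edges$j
  nE <- length(ei)
  ncand <- 1L + nrow(combos)

  keep <- matrix(FALSE, nE, ncand)
  labs <- matrix(1L, n, ncand)
  keep[, 1] <- TRUE # border-sharing matrix: the single shared k = 1 entry

  methods <- partitions %>%
    dplyr::distinct(.data$c, .data$method) %>%
    dplyr::arrange(.data$c)
  plist <- split(p, key(p$c, p$k, p$t))
  for (m in seq_len(nrow(combos))) {
    pm <- plist[[need[m]]]
    pm <- pm[order(pm$area), ]
    lab <- pm$label
    labs[, m + 1L] <- lab
    keep[, m + 1L] <- lab[ei] == lab[ej]
  }

  info <- tibble::tibble(
    index = seq_len(ncand),
    c = c(NA_integer_, combos$c),
    k = c(1L, combos$k),
    t = c(NA_integer_, if (variant == "A") rep(NA_integer_, nrow(combos)) else combos$t)
  ) %>%
    dplyr::left_join(methods, by = "c") %>%
    dplyr::mutate(method = ifelse(.data$k == 1L, "border", .data$method))

  # cached spectra of diag(W1) - W per candidate
  rowsums <- matrix(0, n, ncand)
  eig <- matrix(0, n, ncand)
  for (m in seq_len(ncand)) {
    kp <- keep[, m]
    rs <- tabulate(c(ei[kp], ej[kp]), nbins = n)
    rowsums[, m] <- rs
    L <- base::diag(rs)
    if (any(kp)) {
      ii <- ei[kp]
      jj <- ej[kp]
      L[cbind(ii, jj)] <- -1
      L[cbind(jj, ii)] <- -1
    }
    eig[, m] <- rev(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  }

  structure(
    list(
      graph = graph, variant = variant,
      M = as.integer(M), K = as.integer(K),
      n_periods = as.integer(n_periods),
      info = info, keep = keep, labels = labs,
      rowsums = rowsums, eigenvalues = eig
    ),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> variant ", x$variant, ": ", nrow(x$info),
    " candidate neighbourhood matrices (M = ", x$M, ", K = ", x$K,
    if (x$variant == "B") paste0(", T = ", x$n_periods) else "", ")\n",
    sep = ""
  )
  invisible(x)
}

#' Number of candidates in a candidate set
#' @param x a `candidate_set`.
#' @return integer count of candidate neighbourhood matrices.
#' @export
n_candidates <- function(x) {
  stopifnot(inherits(x, "candidate_set"))
  nrow(x$info)
}

# dense matrix of candidate m (used by tests and small-problem oracles)
candidate_matrix <- function(cands, m) {
  g <- cands$graph
  kp <- cands$keep[, m]
  W <- matrix(0, g$n, g$n)
  if (any(kp)) {
    ii <- g$edges$i[kp]
    jj <- g$edges$j[kp]
    W[cbind(ii, jj)] <- 1
    W[cbind(jj, ii)] <- 1
  }
  W
}

#' Read an adjacency file
#'
#' Supports GAL neighbour files, two-column CSV edge lists and dense
#' CSV 0/1 matrices.
#'
#' @inheritParams area_graph
#' @param path file path.
#' @return an [area_graph()].
#' @export
read_adjacency <- function(path, ids = NULL, n = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (grepl("\\.gal$", path, ignore.case = TRUE)) {
    return(read_gal(path))
  }
  first <- read.csv(path, nrows = 2, header = TRUE, check.names = FALSE)
  if (ncol(first) > 2) {
    W <- as.matrix(read.csv(path, header = TRUE, check.names = FALSE))
    rownames(W) <- colnames(W)
    return(area_graph(W, ids = ids, n = n))
  }
  area_graph(read.csv(path, header = TRUE), ids = ids, n = n)
}

# GAL format: a header line whose last-but-one or only numeric token is n,
# then for each area a record "id n_neighbours" followed by n_neighbours
# neighbour ids. Token-stream parsing keeps us independent of line wrapping.
read_gal <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(lines[1], "\\s+")[[1]]
  n <- as.integer(hdr[if (length(hdr) >= 2) 2 else 1])
  toks <- unlist(strsplit(lines[-1], "\\s+"))
  ids <- character(n)
  nbrs <- vector("list", n)
  pos <- 1
  for (a in seq_len(n)) {
    ids[a] <- toks[pos]
    cnt <- as.integer(toks[pos + 1])
    nbrs[[a]] <- if (cnt > 0) toks[pos + 2:(cnt + 1)] else character(0)
    pos <- pos + 2 + cnt
  }
  from <- rep(ids, lengths(nbrs))
  to <- unlist(nbrs)
  if (length(from) == 0) {
    return(new_area_graph(n, ids, integer(0), integer(0)))
  }
  area_graph(data.frame(from = from, to = to, stringsAsFactors = FALSE), ids = ids)
}
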