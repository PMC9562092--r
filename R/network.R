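#' Percolation-threshold sparsification
#'
#' Scans candidate thresholds (the sorted unique positive weights,
#' ascending). For each threshold, edges below it are removed and the size
#' of the largest weakly connected component is measured. The percolation
#' threshold `tau*` is the largest threshold at which that size still equals
#' its value with all positive edges present, i.e. the last point before the
#' giant component begins to fragment. Edges with weight `>= tau*` are kept.
#'
#' @param W Nonnegative directed weight matrix (zero diagonal).
#' @return List: `tau` (the threshold), `W` (sparsified matrix),
#'   `giant_size`.
#' @export
percolation_threshold <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) rlang::abort("Weights must be nonnegative.")
  diag(W) <- 0
  weights <- sort(unique(W[W > 0]))
  if (length(weights) == 0) {
    return(list(tau = 0, W = W, giant_size = 0))
  }
  giant <- function(thr) {
    A <- W >= thr
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    max(igraph::components(g, mode = "weak")$csize)
  }
  baseline <- giant(weights[1])
  # giant-component size is nonincreasing in the threshold, so the largest
  # threshold preserving the baseline size can be found by bisection
  lo <- 1L
  hi <- length(weights)
  if (giant(weights[hi]) >= baseline) {
    lo <- hi
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (giant(weights[mid]) >= baseline) lo <- mid else hi <- mid
    }
  }
  tau <- weights[lo]
  Ws <- W
  Ws[Ws < tau] <- 0
  list(tau = tau, W = Ws, giant_size = baseline)
}

#' Edge lengths from connection weights
#'
#' The standard inverse mapping: `d_ij = 1 / W_ij` for positive weights,
#' infinite otherwise, so stronger connections are shorter.
#'
#' @param W Nonnegative weight matrix.
#' @return Direct-edge length matrix (Inf where no edge).
#' @export
weights_to_lengths <- function(W) {
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- Inf
  D
}

#' All-pairs directed shortest paths
#'
#' Dijkstra per source on the direct-edge lengths (infinite entries mean no
#' edge). Unreachable pairs stay infinite; the diagonal is zero.
#'
#' @param D0 Direct-edge length matrix from [weights_to_lengths()].
#' @return Distance matrix `D`.
#' @export
shortest_paths_matrix <- function(D0) {
  n <- nrow(D0)
  edges <- which(is.finite(D0) & row(D0) != col(D0), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges[, c(1, 2), drop = FALSE]))
    igraph::E(g)$weight <- D0[edges]
  }
  D <- igraph::distances(g, mode = "out",
                         weights = if (nrow(edges) > 0) igraph::E(g)$weight else NULL,
                         algorithm = "dijkstra")
  dimnames(D) <- dimnames(D0)
  D
}

#' Characteristic path length
#'
#' Mean shortest-path distance over ordered node pairs `i != j`. Only
#' finite (connected) pairs enter the average; the number of finite pairs
#' is attached as attribute `"n_finite"` since sparse directed graphs are
#' rarely strongly connected.
#'
#' @param D Distance matrix from [shortest_paths_matrix()].
#' @return CPL value.
#' @export
cpl <- function(D) {
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) rlang::abort("No finite node pair; CPL undefined.")
  structure(mean(fin), n_finite = length(fin))
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over ordered pairs `i != j`, with
#' `1/Inf = 0`, so disconnected pairs count as zero efficiency.
#'
#' @param D Distance matrix.
#' @return GE value.
#' @export
global_efficiency <- function(D) {
  off <- D[row(D) != col(D)]
  if (length(off) == 0) return(0)
  inv <- ifelse(is.finite(off) & off > 0, 1 / off, 0)
  mean(inv)
}

#' Directed weighted clustering coefficient (Fagiolo)
#'
#' Per-node triangle intensity over possible triangles:
#' `t_i = (1/2) * [(W^(1/3) + t(W)^(1/3))^3]_ii` and
#' `CC_i = t_i / ((k_tot)(k_tot - 1) - 2 k_reciprocal)`, where degrees come
#' from the binarized graph and reciprocal edges are removed from the
#' denominator (the `a_ij a_ji` correction). Nodes with a non-positive
#' denominator get `CC_i = 0`.
#'
#' @param W Nonnegative directed weight matrix, zero diagonal.
#' @return Numeric vector of per-node clustering coefficients.
#' @export
clustering_directed <- function(W) {
  W <- as.matrix(W)
  diag(W) <- 0
  cu <- W^(1 / 3)
  M <- cu + t(cu)
  t_i <- diag(M %*% M %*% M) / 2
  A <- (W > 0) * 1
  k_tot <- rowSums(A) + colSums(A)
  recip <- diag(A %*% A)
  denom <- k_tot * (k_tot - 1) - 2 * recip
  out <- ifelse(denom > 0, t_i / denom, 0)
  names(out) <- rownames(W)
  out
}

#' Directed local efficiency
#'
#' For each node i, shortest paths are computed on the subgraph induced by
#' i's neighbors (i removed; lengths `1/w`), and
#' `LE_i = (1/2) * sum over ordered neighbor pairs (j, h) of
#' (a_ij + a_ji)(a_ih + a_hi)(1/d_jh + 1/d_hj)` divided by the same
#' reciprocal-corrected degree denominator as the clustering coefficient.
#' Isolated or single-neighbor nodes get 0.
#'
#' @param W Nonnegative directed weight matrix, zero diagonal.
#' @return Numeric vector of per-node local efficiencies.
#' @export
local_efficiency_directed <- function(W) {
  W <- as.matrix(W)
  diag(W) <- 0
  A <- (W > 0) * 1
  n <- nrow(W)
  k_tot <- rowSums(A) + colSums(A)
  recip <- diag(A %*% A)
  denom <- k_tot * (k_tot - 1) - 2 * recip
  out <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- which((A[i, ] + A[, i]) > 0)
    if (length(nbrs) < 2 || denom[i] <= 0) next
    Dsub <- shortest_paths_matrix(weights_to_lengths(W[nbrs, nbrs, drop = FALSE]))
    Dinv <- ifelse(is.finite(Dsub) & Dsub > 0, 1 / Dsub, 0)
    wgt <- A[i, nbrs] + A[nbrs, i]
    s <- as.numeric(t(wgt) %*% (Dinv + t(Dinv)) %*% wgt)
    out[i] <- 0.5 * s / denom[i]
  }
  names(out) <- rownames(W)
  out
}

#' All graph metrics of one adjacency matrix
#'
#' Percolation sparsification followed by characteristic path length, global
#' efficiency, directed clustering and directed local efficiency.
#'
#' @param W Nonnegative directed weight matrix.
#' @param sparsify Apply [percolation_threshold()] first (default TRUE).
#' @return A `graph_metrics` list: `tau`, `cpl`, `ge`, `cc`, `le` (per-node),
#'   `cc_mean`, `le_mean`, `n_finite_pairs`.
#' @export
graph_metrics <- function(W, sparsify = TRUE) {
  tau <- 0
  if (sparsify) {
    perc <- percolation_threshold(W)
    W <- perc$W
    tau <- perc$tau
  }
  D <- shortest_paths_matrix(weights_to_lengths(W))
  cpl_v <- tryCatch(cpl(D), error = function(e) NA_real_)
  cc <- clustering_directed(W)
  le <- local_efficiency_directed(W)
  structure(
    list(tau = tau, cpl = as.numeric(cpl_v), ge = global_efficiency(D),
         cc = cc, le = le, cc_mean = mean(cc), le_mean = mean(le),
         n_finite_pairs = attr(cpl_v, "n_finite") %||% 0L),
    class = "graph_metrics"
  )
}

#' Long-format metrics table over blocks and bands
#'
#' @param adjacency_list Nested list: `adjacency_list[[block]][[band]]` is a
#'   weight matrix; block entries may carry `subject`/`block` attributes, or
#'   a `keys` tibble is supplied.
#' @param keys Optional tibble with one row per block (e.g. subject, block,
#'   condition) to bind onto the output.
#' @param sparsify Percolation-sparsify each graph first.
#' @return Tibble keyed by (block row, band) with tau, cpl, ge, cc_mean,
#'   le_mean, and the per-node vectors as list-columns.
#' @export
summarize_graph_metrics <- function(adjacency_list, keys = NULL, sparsify = TRUE) {
  rows <- list()
  for (b in seq_along(adjacency_list)) {
    for (band in names(adjacency_list[[b]])) {
      m <- graph_metrics(adjacency_list[[b]][[band]], sparsify = sparsify)
      row <- tibble::tibble(
        block_index = b, band = band, tau = m$tau, cpl = m$cpl, ge = m$ge,
        cc_mean = m$cc_mean, le_mean = m$le_mean,
        cc = list(m$cc), le = list(m$le)
      )
      if (!is.null(keys)) row <- dplyr::bind_cols(keys[b, ], row)
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
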