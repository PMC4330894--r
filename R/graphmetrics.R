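#' Weighted graph from a thresholded SL matrix
#'
#' `as_weighted_graph()` wraps a weight matrix as-is (SL values are
#' already in `[0, 1]`, the scale on which the network measures are
#' reported); `normalize_weights()` additionally rescales by the
#' maximum weight, the convention that makes the topology measures
#' scale-invariant.
#'
#' @param t a `thresholded_sl`, or a symmetric non-negative matrix with
#'   zero diagonal.
#' @return object of class `weighted_graph`: list with `W` (weight
#'   matrix), `n`, `degree` (per-node count of incident edges).
#' @export
as_weighted_graph <- function(t) {
  v <- if (inherits(t, "thresholded_sl")) t$values else as.matrix(t)
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  if (any(v < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (all(v == 0)) stop("empty network: no edges", call. = FALSE)
  diag(v) <- 0
  structure(list(W = v, n = nrow(v), degree = rowSums(v > 0)),
            class = "weighted_graph")
}

#' @rdname as_weighted_graph
#' @export
normalize_weights <- function(t) {
  g <- as_weighted_graph(t)
  g$W <- g$W / max(g$W)
  g
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges\n", x$n,
              sum(x$W[upper.tri(x$W)] > 0)))
  invisible(x)
}

#' Mean weighted clustering coefficient
#'
#' Nodal clustering is the geometric-mean triangle intensity around
#' each node: `c_i = 2 t_i / (k_i (k_i - 1))` with
#' `t_i = 1/2 * sum_{j,h} (W_ij W_ih W_jh)^{1/3}`; nodes with fewer
#' than two edges contribute 0.  Returns the network mean.
#'
#' @param g a [normalize_weights()] `weighted_graph`.
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (g$n < 3L) stop("clustering needs at least 3 nodes", call. = FALSE)
  w13 <- g$W^(1 / 3)
  t_i <- diag(w13 %*% w13 %*% w13) / 2
  k <- g$degree
  c_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  mean(c_i)
}

#' Weighted shortest-path distance matrix
#'
#' Edge lengths are reciprocal weights (`1 / W_ij`; strong functional
#' connections are short), and distances are minimal total path lengths
#' (Dijkstra).  Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param g a `weighted_graph`.
#' @return n x n distance matrix.
#' @export
shortest_path_matrix <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  len <- ifelse(g$W > 0, 1 / g$W, 0)
  ig <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(ig, algorithm = "dijkstra")
  dimnames(d) <- dimnames(g$W)
  d
}

#' Characteristic path length
#'
#' Mean weighted shortest-path distance over all ordered node pairs with
#' a finite path; the fraction of disconnected (infinite) pairs is
#' reported alongside rather than silently absorbed.
#'
#' @param d distance matrix from [shortest_path_matrix()].
#' @return list with `L` (mean finite distance) and
#'   `disconnected_pair_fraction`.
#' @export
char_path_length <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  if (!any(fin)) stop("disconnected graph: no finite path", call. = FALSE)
  list(L = mean(off[fin]),
       disconnected_pair_fraction = mean(!fin))
}

#' Global efficiency
#'
#' Average inverse shortest-path length over ordered node pairs, with
#' disconnected pairs contributing 0.
#'
#' @param d distance matrix from [shortest_path_matrix()].
#' @return scalar in `[0, 1]` for max-normalized weights.
#' @export
global_efficiency <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(d)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node i with at least two neighbours, the efficiency of its
#' neighbourhood subgraph:
#' `e_i = sum_{j != h in N_i} (W_ij W_ih / d_jh(N_i))^{1/3} / (k_i (k_i - 1))`,
#' where `d_jh(N_i)` is the shortest path between j and h restricted to
#' the subgraph induced by the neighbours of i (i itself removed).
#' Nodes with `k_i < 2` contribute 0; the network value is the mean.
#'
#' @param g a `weighted_graph`.
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (g$n < 3L) stop("local efficiency needs at least 3 nodes",
                     call. = FALSE)
  e <- numeric(g$n)
  for (i in seq_len(g$n)) {
    nbrs <- which(g$W[i, ] > 0)
    k <- length(nbrs)
    if (k < 2L) next
    sub <- structure(list(W = g$W[nbrs, nbrs, drop = FALSE], n = k,
                          degree = rowSums(g$W[nbrs, nbrs, drop = FALSE] > 0)),
                     class = "weighted_graph")
    dsub <- shortest_path_matrix(sub)
    inv <- 1 / dsub
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sw <- g$W[i, nbrs]^(1 / 3)
    e[i] <- sum(outer(sw, sw) * inv^(1 / 3)) / (k * (k - 1))
  }
  mean(e)
}

#' All network measures for a thresholded SL matrix
#'
#' Assembles the connectivity and topology summaries of one condition
#' network: mean retained SL, weighted clustering coefficient C, local
#' efficiency E_loc, characteristic path length L, global efficiency
#' E_glob, edge count, and the fraction of disconnected node pairs.
#'
#' By default the measures are computed on the raw retained SL weights
#' (already in `[0, 1]`), so that connectivity strength carries into the
#' topology measures — stronger synchronization means shorter weighted
#' paths and higher efficiencies.  With `normalize = TRUE` weights are
#' first divided by their maximum, making C, E_loc scale-invariant.
#'
#' @param t a `thresholded_sl`.
#' @param normalize max-normalize the weights first (default FALSE).
#' @return object of class `network_metrics` (a named list).
#' @export
network_metrics <- function(t, normalize = FALSE) {
  stopifnot(inherits(t, "thresholded_sl"))
  g <- if (normalize) normalize_weights(t) else as_weighted_graph(t)
  d <- shortest_path_matrix(g)
  pl <- char_path_length(d)
  structure(list(SL_MEAN = sl_mean(t),
                 C = clustering_coefficient(g),
                 E_loc = local_efficiency(g),
                 L = pl$L,
                 E_glob = global_efficiency(d),
                 edge_count = t$edge_count,
                 disconnected_pair_fraction = pl$disconnected_pair_fraction),
            class = "network_metrics")
}

#' Network measures for both conditions of one subject
#'
#' @param rest,preh `thresholded_sl` matrices for the rest and
#'   prehension conditions.
#' @param normalize max-normalize weights first (default FALSE).
#' @return list with elements `rest` and `prehension`, each a
#'   [network_metrics()] record.
#' @export
compute_all <- function(rest, preh, normalize = FALSE) {
  list(rest = network_metrics(rest, normalize = normalize),
       prehension = network_metrics(preh, normalize = normalize))
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> SL_MEAN %.3f C %.3f E_loc %.3f L %.3f E_glob %.3f (%d edges)\n",
    x$SL_MEAN, x$C, x$E_loc, x$L, x$E_glob, x$edge_count))
  invisible(x)
}
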