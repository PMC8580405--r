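# Graph-theoretic network measures under proportional thresholding.
#
# Convention (parameterized, see the switches below): node strength is
# computed on the full weighted connectivity matrix; clustering, the
# characteristic path length, and betweenness centrality are computed on the
# binarized graph obtained by retaining the strongest fraction p of edges
# (p = 0.30 by default). The binary formulas are
#   C_i = 2 t_i / (K_i (K_i - 1)),  C_i = 0 for K_i < 2,   C = mean_i C_i
#   L   = mean_i l_i, with l_i the mean shortest-path distance from node i
#         over the finite distances only (isolated nodes contribute l_i = 0
#         and are flagged).

check_weight_matrix <- function(W, nonneg = TRUE) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (nonneg && any(W < 0)) stop("negative weights are not allowed (icoh is non-negative)")
  invisible(TRUE)
}

round_half_up <- function(x) floor(x + 0.5)

#' Proportional threshold of a connectivity matrix
#'
#' Retains the `round(p * E)` largest-weight edges (E = K(K-1)/2 possible
#' undirected edges) and binarizes them. Ties at the cutoff are broken by
#' ascending (row, column) index so the result is deterministic. Because only
#' the rank order of the weights matters, the thresholded graph is invariant
#' under any strictly monotone transform of the weights.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal
#'   (typically a `coherence_matrix`).
#' @param p Fraction of edges to retain, in `(0, 1]`. Default 0.30.
#' @return Binary adjacency matrix of class `thresholded_graph` with
#'   attributes `p` and `n_edges`.
#' @examples
#' W <- matrix(0, 4, 4); W[upper.tri(W)] <- c(.1, .5, .2, .6, .3, .4)
#' W <- W + t(W)
#' sum(proportional_threshold(W, 0.3)) / 2  # round(0.3 * 6) = 2 edges
#' @export
proportional_threshold <- function(W, p = 0.30) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("p must lie in (0, 1]")
  check_weight_matrix(unclass(W))
  K <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  E <- nrow(ut)
  m <- round_half_up(p * E)
  ord <- order(-W[ut], ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(0L, K, K, dimnames = dimnames(W))
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(A, p = p, n_edges = m, class = c("thresholded_graph", "matrix"))
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(unclass(A) > 0, mode = "undirected", diag = FALSE)
}

#' Node strength
#'
#' Sum of the weights of all links connected to each node, computed on the
#' full weighted matrix (not the thresholded graph).
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(W) {
  check_weight_matrix(unclass(W))
  rowSums(unclass(W))
}

#' Clustering coefficients (binary)
#'
#' Fraction of triangles around each node: `C_i = 2 t_i / (K_i (K_i - 1))`,
#' set to 0 for nodes of degree below 2. The global clustering coefficient is
#' the mean of `C_i` over all nodes (isolated nodes included).
#'
#' @param graph Binary symmetric adjacency matrix (a `thresholded_graph`).
#' @return List with `local` (named C_i vector), `global` (mean C),
#'   `triangles` (t_i counts), `degree` (K_i).
#' @export
clustering_coef <- function(graph) {
  A <- unclass(graph)
  check_weight_matrix(A)
  g <- as_igraph(A)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  ci[is.na(ci)] <- 0
  ki <- igraph::degree(g)
  names(ci) <- rownames(A)
  list(local = ci, global = mean(ci),
       triangles = round(ci * ki * (ki - 1) / 2), degree = ki)
}

#' Characteristic path length
#'
#' Unweighted shortest-path distances on the binary graph; `l_i` is the mean
#' of the finite distances from node i to the other nodes, and the
#' characteristic path length L is the mean of the `l_i`. A fully isolated
#' node contributes `l_i = 0` and is flagged in the result. A graph with no
#' edges has no defined path length and is rejected.
#'
#' @param graph Binary symmetric adjacency matrix (a `thresholded_graph`).
#' @return List with `L`, `l_i` (named vector), `isolated` (logical vector),
#'   and `disconnected` (TRUE if any pair had infinite distance).
#' @export
characteristic_path_length <- function(graph) {
  A <- unclass(graph)
  check_weight_matrix(A)
  if (sum(A) == 0) stop("graph has no edges: characteristic path length undefined")
  D <- igraph::distances(as_igraph(A))
  diag(D) <- NA
  li <- apply(D, 1, function(row) {
    fin <- row[is.finite(row) & !is.na(row)]
    if (length(fin) == 0) 0 else mean(fin)
  })
  names(li) <- rownames(A)
  isolated <- rowSums(A) == 0
  list(L = mean(li), l_i = li, isolated = isolated,
       disconnected = any(is.infinite(D[!is.na(D)])))
}

#' Betweenness centrality
#'
#' Standard shortest-path betweenness on the binary graph: for each node v,
#' the sum over pairs s != t != v of the fraction of s-t shortest paths
#' passing through v (each unordered pair counted once). Reported
#' unnormalized by default; `normalized = TRUE` divides by
#' `(n - 1)(n - 2) / 2`.
#'
#' @param graph Binary symmetric adjacency matrix (a `thresholded_graph`).
#' @param normalized Divide by the number of possible pairs. Default `FALSE`.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(graph, normalized = FALSE) {
  A <- unclass(graph)
  check_weight_matrix(A)
  b <- igraph::betweenness(as_igraph(A), directed = FALSE, normalized = FALSE)
  if (normalized) {
    n <- nrow(A)
    b <- b / ((n - 1) * (n - 2) / 2)
  }
  names(b) <- rownames(A)
  b
}

#' All node-level and global graph metrics of a connectivity matrix
#'
#' Applies the package's convention in one call: strength on the weighted
#' matrix; clustering, path length, and betweenness on the proportionally
#' thresholded binary graph.
#'
#' @param W Weighted connectivity matrix.
#' @param p Retained edge fraction for thresholding. Default 0.30.
#' @return List with `node` (data frame: region, strength, degree,
#'   clustering, betweenness) and `global` (list: C, L, p, n_edges,
#'   disconnected).
#' @export
graph_metrics <- function(W, p = 0.30) {
  g <- proportional_threshold(W, p)
  cl <- clustering_coef(g)
  pl <- characteristic_path_length(g)
  bt <- betweenness_centrality(g)
  regions <- rownames(W)
  if (is.null(regions)) regions <- paste0("n", seq_len(nrow(W)))
  list(
    node = data.frame(region = regions, strength = node_strength(W),
                      degree = cl$degree, clustering = cl$local,
                      betweenness = bt, row.names = NULL),
    global = list(C = cl$global, L = pl$L, p = p,
                  n_edges = attr(g, "n_edges"), disconnected = pl$disconnected)
  )
}
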