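#' Per-node sociometric cohesion metrics
#'
#' Computes, for every child in one wave's network: in-degree (nominations
#' received), out-degree (nominations made), degree (their sum), the local
#' clustering coefficient, and closeness centrality.
#'
#' Clustering follows the undirected convention: ties in either direction are
#' symmetrized, and a node's coefficient is the fraction of its neighbour
#' pairs that are themselves connected (0 when the node has fewer than two
#' neighbours). Closeness is computed on directed shortest paths; because
#' classroom digraphs are routinely disconnected, the default applies the
#' Wasserman-Faust correction
#' \deqn{C(i) = \frac{r_i}{n-1} \cdot \frac{r_i}{\sum_{j \in R(i)} d(i,j)}}
#' where \eqn{R(i)} is the set of \eqn{r_i} nodes reachable from i (0 for a
#' node reaching no one). `closeness = "harmonic"` instead averages
#' reciprocal distances, \eqn{\sum_{j \ne i} d(i,j)^{-1} / (n-1)}.
#'
#' @param net a `directed_network`.
#' @param closeness `"wasserman_faust"` (default) or `"harmonic"`.
#' @return data.frame with columns `node_id`, `in_degree`, `out_degree`,
#'   `degree`, `clustering`, `closeness`.
#' @examples
#' net <- directed_network(c("A", "B", "C"), rbind(c("A", "B"), c("A", "C")), "T0")
#' node_metrics(net)
#' @export
node_metrics <- function(net, closeness = c("wasserman_faust", "harmonic")) {
  stopifnot(inherits(net, "directed_network"))
  closeness <- match.arg(closeness)
  A <- as_adjacency(net)
  n <- nrow(A)
  indeg <- colSums(A)
  outdeg <- rowSums(A)

  # local clustering on the undirected reduction
  U <- (A + t(A)) > 0
  k <- rowSums(U)
  clus <- numeric(n)
  if (n > 0 && any(k >= 2)) {
    Un <- U * 1
    tri <- diag(Un %*% Un %*% Un) / 2   # closed neighbour pairs per node
    pairs <- k * (k - 1) / 2
    clus <- ifelse(k >= 2, tri / pairs, 0)
  }

  clo <- numeric(n)
  if (n > 1) {
    g <- as_igraph(net)
    d <- igraph::distances(g, mode = "out", algorithm = "unweighted")
    diag(d) <- Inf
    if (closeness == "wasserman_faust") {
      for (i in seq_len(n)) {
        reach <- is.finite(d[i, ])
        r <- sum(reach)
        clo[i] <- if (r == 0) 0 else (r / (n - 1)) * (r / sum(d[i, reach]))
      }
    } else {
      clo <- rowSums(1 / d) / (n - 1)
    }
  }

  data.frame(node_id = net$node_ids,
             in_degree = as.integer(indeg),
             out_degree = as.integer(outdeg),
             degree = as.integer(indeg + outdeg),
             clustering = as.numeric(clus),
             closeness = as.numeric(clo),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Network-level summary of cohesion metrics
#'
#' Unweighted node means of the [node_metrics()] columns, plus counts.
#'
#' @inheritParams node_metrics
#' @return one-row data.frame with `n_nodes`, `n_ties`, `avg_degree`,
#'   `avg_in_degree`, `avg_out_degree`, `avg_clustering`, `avg_closeness`.
#' @export
network_summary <- function(net, closeness = c("wasserman_faust", "harmonic")) {
  m <- node_metrics(net, closeness)
  data.frame(n_nodes = length(net$node_ids),
             n_ties = nrow(net$edges),
             avg_degree = if (nrow(m)) mean(m$degree) else 0,
             avg_in_degree = if (nrow(m)) mean(m$in_degree) else 0,
             avg_out_degree = if (nrow(m)) mean(m$out_degree) else 0,
             avg_clustering = if (nrow(m)) mean(m$clustering) else 0,
             avg_closeness = if (nrow(m)) mean(m$closeness) else 0)
}
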