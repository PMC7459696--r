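# Brute-force oracles, written independently of the package internals:
# metrics by triple/BFS enumeration, statistics by direct counting over the
# adjacency matrix, logistic regression via glm's IRLS.

rand_digraph <- function(n, p = 0.3, ids = sprintf("n%02d", seq_len(n)),
                         wave = "T0") {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  idx <- which(A == 1, arr.ind = TRUE)
  directed_network(ids, cbind(ids[idx[, 1]], ids[idx[, 2]]), wave)
}

rand_panel <- function(n, p0 = 0.3, p1 = 0.3, rewire = NULL) {
  ids <- sprintf("n%02d", seq_len(n))
  t0 <- rand_digraph(n, p0, ids, "T0")
  t1 <- rand_digraph(n, p1, ids, "T1")
  network_panel(t0, t1, data.frame(node_id = ids), "fuzz")
}

# BFS shortest-path distances from one source (adjacency matrix, out-ties)
bfs_dist <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] == 1 & !is.finite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_metrics <- function(net) {
  A <- as_adjacency(net)
  n <- nrow(A)
  indeg <- colSums(A)
  outdeg <- rowSums(A)
  U <- (A + t(A)) > 0
  clus <- numeric(n)
  clo <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(U[i, ])
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      closed <- sum(apply(pairs, 2, function(pr) U[pr[1], pr[2]]))
      clus[i] <- closed / ncol(pairs)
    }
    if (n > 1) {
      d <- bfs_dist(A, i)[-i]
      reach <- is.finite(d)
      r <- sum(reach)
      clo[i] <- if (r == 0) 0 else (r / (n - 1)) * (r / sum(d[reach]))
    }
  }
  data.frame(node_id = net$node_ids, in_degree = as.integer(indeg),
             out_degree = as.integer(outdeg),
             degree = as.integer(indeg + outdeg),
             clustering = clus, closeness = clo,
             stringsAsFactors = FALSE)
}

gw <- function(tau, s) ifelse(s <= 0, 0, exp(tau) * (1 - (1 - exp(-tau))^s))

oracle_stats <- function(net, tau, attrs = NULL, match_attr = NULL,
                         diff_attr = NULL) {
  A <- as_adjacency(net)
  n <- nrow(A)
  ties <- which(A == 1, arr.ind = TRUE)
  edges <- nrow(ties)
  gwid <- sum(gw(tau, colSums(A)))
  gwesp <- 0
  if (edges > 0)
    for (r in seq_len(edges)) {
      i <- ties[r, 1]; j <- ties[r, 2]
      sp <- sum(A[i, ] == 1 & A[, j] == 1)   # transitive two-paths i->k->j
      gwesp <- gwesp + gw(tau, sp)
    }
  out <- c(edges = edges, gwidegree = gwid, gwesp = gwesp)
  if (!is.null(match_attr)) {
    v <- attrs[[match_attr]][match(net$node_ids, attrs$node_id)]
    out["nodematch"] <- if (edges == 0) 0 else
      sum(v[ties[, 1]] == v[ties[, 2]])
  }
  if (!is.null(diff_attr)) {
    v <- attrs[[diff_attr]][match(net$node_ids, attrs$node_id)]
    out["absdiff"] <- if (edges == 0) 0 else
      sum(abs(v[ties[, 1]] - v[ties[, 2]]))
  }
  out
}

oracle_jaccard <- function(panel) {
  A0 <- as_adjacency(panel$t0)
  A1 <- as_adjacency(panel$t1)
  sum(A0 & A1) / sum(A0 | A1)
}

# small fixed panel used across tests
fixture_panel <- function() {
  ids <- c("A", "B", "C", "D")
  t0 <- directed_network(ids, rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                                    c("D", "A")), "T0")
  t1 <- directed_network(ids, rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                                    c("D", "C")), "T1")
  attrs <- data.frame(node_id = ids, sex = c("F", "F", "M", "M"),
                      age = c(10, 11, 12, 9), mvpa = c(30, 50, 45, 70),
                      stringsAsFactors = FALSE)
  network_panel(t0, t1, attrs, "fixture")
}
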