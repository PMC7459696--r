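#' Construct a directed friendship network
#'
#' Nodes are children identified by opaque strings; a directed tie (i, j)
#' means child i nominated child j as a friend. Ties are unweighted: repeated
#' nominations are collapsed, and nomination ranks (best friend = 1, ...) are
#' accepted upstream but carry no weight here. Self-nominations are invalid.
#'
#' @param node_ids character vector of unique node identifiers.
#' @param edges two-column matrix or data.frame of ties (from, to); may have
#'   zero rows.
#' @param wave wave label, `"T0"` (baseline) or `"T1"` (follow-up).
#' @return a `directed_network` object.
#' @examples
#' directed_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")), "T0")
#' @export
directed_network <- function(node_ids, edges = NULL, wave = "T0") {
  node_ids <- as.character(node_ids)
  if (anyNA(node_ids) || any(!nzchar(node_ids)))
    stop("node_ids must be non-missing, non-empty strings", call. = FALSE)
  if (anyDuplicated(node_ids))
    stop("duplicated node_ids: ",
         paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "),
         call. = FALSE)
  if (!wave %in% c("T0", "T1"))
    stop("wave label must be 'T0' or 'T1', got '", wave, "'", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(0), 0, 2)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    if (any(em[, 1] == em[, 2]))
      stop("self-tie not allowed: ", paste(unique(em[em[, 1] == em[, 2], 1]),
                                           collapse = ", "), call. = FALSE)
    bad <- setdiff(c(em), node_ids)
    if (length(bad))
      stop("tie endpoint(s) not in node_ids: ", paste(bad, collapse = ", "),
           call. = FALSE)
    em <- em[!duplicated(paste(em[, 1], em[, 2], sep = "\r")), , drop = FALSE]
  }
  dimnames(em) <- list(NULL, c("from", "to"))
  structure(list(node_ids = node_ids, edges = em, wave = wave),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed friendship network (%s): %d nodes, %d ties\n",
              x$wave, length(x$node_ids), nrow(x$edges)))
  invisible(x)
}

#' Adjacency matrix of a directed network
#'
#' @param net a `directed_network`.
#' @return integer 0/1 matrix with node ids as dimnames; `[i, j] = 1` means
#'   i nominated j.
#' @export
as_adjacency <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- length(net$node_ids)
  A <- matrix(0L, n, n, dimnames = list(net$node_ids, net$node_ids))
  if (nrow(net$edges))
    A[cbind(match(net$edges[, 1], net$node_ids),
            match(net$edges[, 2], net$node_ids))] <- 1L
  A
}

# inverse of as_adjacency
network_from_adjacency <- function(A, node_ids, wave) {
  idx <- which(A != 0, arr.ind = TRUE)
  directed_network(node_ids,
                   cbind(node_ids[idx[, 1]], node_ids[idx[, 2]]),
                   wave)
}

edge_keys <- function(net) {
  if (inherits(net, "directed_network")) e <- net$edges else e <- net
  if (NROW(e) == 0) return(character(0))
  paste(e[, 1], e[, 2], sep = "\r")
}

keys_to_edges <- function(keys) {
  if (length(keys) == 0) return(matrix(character(0), 0, 2,
                                       dimnames = list(NULL, c("from", "to"))))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  m <- cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
  dimnames(m) <- list(NULL, c("from", "to"))
  m
}

#' Construct a two-wave classroom network panel
#'
#' A panel pairs one classroom's baseline (T0) and follow-up (T1) friendship
#' networks over an identical node set, together with the node attribute
#' table. Only children observed at both waves belong in a panel.
#'
#' @param net_t0,net_t1 `directed_network` objects with waves `"T0"` and
#'   `"T1"` and identical node sets.
#' @param attrs data.frame of node attributes with a `node_id` column covering
#'   every node; missing values are allowed in attribute columns.
#' @param classroom_id label for the classroom.
#' @return a `network_panel` object.
#' @export
network_panel <- function(net_t0, net_t1, attrs = NULL, classroom_id = "classroom") {
  stopifnot(inherits(net_t0, "directed_network"), inherits(net_t1, "directed_network"))
  if (net_t0$wave != "T0" || net_t1$wave != "T1")
    stop("panel waves must be labelled T0 and T1", call. = FALSE)
  if (!setequal(net_t0$node_ids, net_t1$node_ids))
    stop("panel waves must share an identical node set", call. = FALSE)
  if (is.null(attrs)) attrs <- data.frame(node_id = net_t0$node_ids)
  if (!"node_id" %in% names(attrs))
    stop("attrs must contain a node_id column", call. = FALSE)
  attrs$node_id <- as.character(attrs$node_id)
  if (anyNA(attrs$node_id) || anyDuplicated(attrs$node_id))
    stop("attrs node_id must be unique and non-missing", call. = FALSE)
  missing_attr <- setdiff(net_t0$node_ids, attrs$node_id)
  if (length(missing_attr))
    stop("nodes without attribute rows: ", paste(missing_attr, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(attrs$node_id, net_t0$node_ids)
  if (length(extra))
    stop("attribute row without matching panel node: ",
         paste(extra, collapse = ", "), call. = FALSE)
  attrs <- attrs[match(net_t0$node_ids, attrs$node_id), , drop = FALSE]
  rownames(attrs) <- NULL
  structure(list(t0 = net_t0, t1 = net_t1, attrs = attrs,
                 classroom_id = classroom_id),
            class = "network_panel")
}

#' @export
print.network_panel <- function(x, ...) {
  cat(sprintf("network panel '%s': %d nodes, %d ties (T0), %d ties (T1)\n",
              x$classroom_id, length(x$t0$node_ids),
              nrow(x$t0$edges), nrow(x$t1$edges)))
  invisible(x)
}

#' Read a classroom panel from edge-list and attribute CSV files
#'
#' The edge CSV must have columns `source`, `target`, `wave` (labels `T0` /
#' `T1`) and may carry a `rank` column (nomination ranks 1-4), which is
#' ignored: ties are collapsed to presence/absence. The attribute CSV has one
#' row per child with a `node_id` column; its roster defines the panel's node
#' set. Edges whose endpoints are not on the roster (e.g. a child observed in
#' only one wave) are dropped with a warning.
#'
#' @param edges_path path to the edge-list CSV.
#' @param attrs_path path to the node-attribute CSV.
#' @param classroom_id label for the classroom.
#' @return a `network_panel`.
#' @export
read_panel <- function(edges_path, attrs_path, classroom_id = "classroom") {
  ed <- read.csv(edges_path, stringsAsFactors = FALSE)
  need <- c("source", "target", "wave")
  if (!all(need %in% names(ed)))
    stop("edge CSV must have columns source, target, wave (got: ",
         paste(names(ed), collapse = ", "), ")", call. = FALSE)
  bad_wave <- setdiff(unique(ed$wave), c("T0", "T1"))
  if (length(bad_wave))
    stop("unknown wave label(s) in edge CSV: ", paste(bad_wave, collapse = ", "),
         call. = FALSE)
  self <- ed$source == ed$target
  if (any(self))
    stop("self-tie in edge CSV at line(s) ",
         paste(which(self) + 1L, collapse = ", "), call. = FALSE)
  at <- read.csv(attrs_path, stringsAsFactors = FALSE)
  if (!"node_id" %in% names(at))
    stop("attribute CSV must have a node_id column", call. = FALSE)
  roster <- as.character(at$node_id)
  off <- !(ed$source %in% roster & ed$target %in% roster)
  if (any(off)) {
    dropped <- setdiff(unique(c(ed$source[off], ed$target[off])), roster)
    warning(sum(off), " tie(s) dropped: node(s) not on both-wave roster: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    ed <- ed[!off, , drop = FALSE]
  }
  mk <- function(w) {
    e <- ed[ed$wave == w, c("source", "target"), drop = FALSE]
    directed_network(roster, as.matrix(e), w)
  }
  network_panel(mk("T0"), mk("T1"), at, classroom_id)
}

#' Write a classroom panel to edge-list and attribute CSV files
#'
#' Inverse of [read_panel()].
#'
#' @param panel a `network_panel`.
#' @param edges_path,attrs_path output CSV paths.
#' @return invisibly, the panel.
#' @export
write_panel <- function(panel, edges_path, attrs_path) {
  stopifnot(inherits(panel, "network_panel"))
  ed <- rbind(
    data.frame(source = panel$t0$edges[, 1], target = panel$t0$edges[, 2],
               wave = rep("T0", nrow(panel$t0$edges))),
    data.frame(source = panel$t1$edges[, 1], target = panel$t1$edges[, 2],
               wave = rep("T1", nrow(panel$t1$edges))))
  write.csv(ed, edges_path, row.names = FALSE)
  write.csv(panel$attrs, attrs_path, row.names = FALSE)
  invisible(panel)
}

#' Export a network (with node attributes) to GraphML
#'
#' @param net a `directed_network`.
#' @param attrs optional node-attribute data.frame with a `node_id` column.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_graphml <- function(net, attrs = NULL, path) {
  g <- as_igraph(net, attrs)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path GraphML file path.
#' @param wave wave label to assign.
#' @return list with elements `net` (`directed_network`) and `attrs`
#'   (data.frame of vertex attributes).
#' @export
read_graphml <- function(path, wave = "T0") {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g, names = TRUE)
  net <- directed_network(ids, el, wave)
  an <- setdiff(igraph::vertex_attr_names(g), c("name", "id"))
  attrs <- data.frame(node_id = ids, stringsAsFactors = FALSE)
  for (a in an) attrs[[a]] <- igraph::vertex_attr(g, a)
  list(net = net, attrs = attrs)
}

# directed_network (+ attribute table) -> igraph graph
as_igraph <- function(net, attrs = NULL) {
  stopifnot(inherits(net, "directed_network"))
  g <- igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$node_ids, stringsAsFactors = FALSE))
  if (!is.null(attrs)) {
    ord <- match(net$node_ids, attrs$node_id)
    for (a in setdiff(names(attrs), "node_id")) {
      v <- attrs[[a]][ord]
      if (is.factor(v)) v <- as.character(v)
      g <- igraph::set_vertex_attr(g, a, value = v)
    }
  }
  g
}
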