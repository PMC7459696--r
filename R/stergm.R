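#' Separable formation/dissolution decomposition of a two-wave panel
#'
#' The transition from the baseline network y0 to the follow-up y1 is split
#' into two constrained networks: the formation network `y_plus = y0 U y1`
#' (ties that existed or appeared; formation may only add to y0) and the
#' dissolution network `y_minus = y0 n y1` (baseline ties that survived;
#' dissolution may only delete from y0).
#'
#' @param panel a `network_panel`.
#' @return list with `formation`, `dissolution` (both `directed_network`,
#'   labelled T1) and `base` (the T0 network).
#' @export
stergm_decompose <- function(panel) {
  stopifnot(inherits(panel, "network_panel"))
  k0 <- edge_keys(panel$t0)
  k1 <- edge_keys(panel$t1)
  ids <- panel$t0$node_ids
  list(formation = directed_network(ids, keys_to_edges(union(k0, k1)), "T1"),
       dissolution = directed_network(ids, keys_to_edges(intersect(k0, k1)), "T1"),
       base = panel$t0)
}

#' Reconstruct the follow-up tie set from a separable decomposition
#'
#' The algebraic inverse of [stergm_decompose()]: given the baseline tie set
#' and valid formation/dissolution networks, the follow-up network is
#' `(y_plus \ y0) U y_minus`. Violated containment invariants raise an error.
#'
#' @param y0,y_plus,y_minus `directed_network` objects (or two-column edge
#'   matrices over the same node set as `y0`).
#' @return a `directed_network` labelled T1 (when `y0` is a network), else an
#'   edge matrix.
#' @export
reconstruct_t1 <- function(y0, y_plus, y_minus) {
  k0 <- edge_keys(y0)
  kp <- edge_keys(y_plus)
  km <- edge_keys(y_minus)
  if (length(setdiff(k0, kp)))
    stop("decomposition error: formation network must contain every baseline tie",
         call. = FALSE)
  if (length(setdiff(km, k0)))
    stop("decomposition error: dissolution network must be a subset of baseline ties",
         call. = FALSE)
  k1 <- union(setdiff(kp, k0), km)
  if (inherits(y0, "directed_network"))
    directed_network(y0$node_ids, keys_to_edges(k1), "T1")
  else keys_to_edges(k1)
}

#' Evaluate network statistics on a network
#'
#' Computes the exponential-family statistic vector g(y) for a set of model
#' terms: `edges`, `gwidegree(decay)`, `gwesp(decay)` (transitive /
#' outgoing-two-path shared partners), `absdiff(attr)`, `nodematch(attr)`.
#' Geometric terms use a fixed decay; at decay 0 the gwesp statistic reduces
#' to the number of ties with at least one shared partner.
#'
#' @param net a `directed_network`.
#' @param terms term vector, see [parse_terms()].
#' @param attrs node-attribute data.frame (needed by `absdiff`/`nodematch`).
#' @return named numeric statistic vector.
#' @examples
#' net <- directed_network(c("A", "B", "C"),
#'                         rbind(c("A", "B"), c("B", "C"), c("A", "C")), "T0")
#' network_stats(net, c("edges", "gwesp(0.25)"))
#' @export
network_stats <- function(net, terms, attrs = NULL) {
  stopifnot(inherits(net, "directed_network"))
  enc <- encode_terms(terms, attrs, net$node_ids)
  g <- .cpp_stats(as_adjacency(net), enc$type, enc$decay, enc$attr)
  setNames(as.numeric(g), enc$label)
}

#' MCMC control settings for STERGM sampling and estimation
#'
#' @param burnin toggles discarded before the first draw.
#' @param interval toggles between retained draws.
#' @param samplesize retained draws per MCMC-MLE iteration.
#' @param maxit maximum MCMC-MLE iterations.
#' @param exact_max_free largest free-dyad count for which the conditional
#'   MLE is computed by exact enumeration instead of MCMC.
#' @param method `"auto"` (dyad-independent models solved in closed form,
#'   small spaces enumerated, MCMC otherwise), or force `"mple"`, `"exact"`,
#'   `"mcmc"`.
#' @param ztol Mahalanobis convergence tolerance for the mean-value equation.
#' @param step_max largest coefficient move per MCMC-MLE iteration.
#' @return list of settings.
#' @export
stergm_control <- function(burnin = 10000, interval = 100, samplesize = 1000,
                           maxit = 20, exact_max_free = 20,
                           method = c("auto", "mple", "exact", "mcmc"),
                           ztol = 0.25, step_max = 1.0) {
  list(burnin = burnin, interval = interval, samplesize = samplesize,
       maxit = maxit, exact_max_free = exact_max_free,
       method = match.arg(method), ztol = ztol, step_max = step_max)
}

# free dyads of a constrained transition space, as 0-based index vectors
free_dyads <- function(A_base, which) {
  n <- nrow(A_base)
  if (which == "formation") idx <- which(A_base == 0L & diag(n) == 0L, arr.ind = TRUE)
  else idx <- which(A_base == 1L, arr.ind = TRUE)
  list(i = as.integer(idx[, 1] - 1L), j = as.integer(idx[, 2] - 1L))
}

#' Simulate a constrained network transition by Metropolis sampling
#'
#' Draws formation networks (supersets of the baseline tie set) or
#' dissolution networks (subsets of it) from the exponential-family model
#' `P(y) ~ exp(theta . g(y))` restricted to the corresponding space, using
#' single-dyad Metropolis toggles over the free dyads.
#'
#' @param base a `directed_network`: the baseline (T0) network.
#' @param which `"formation"` or `"dissolution"`.
#' @param theta coefficient vector, one entry per term.
#' @param terms model terms (see [parse_terms()]).
#' @param attrs node-attribute data.frame.
#' @param nsim number of draws.
#' @param control [stergm_control()] list (burnin/interval used here).
#' @param seed optional integer seed.
#' @param return_stats if `TRUE`, also return the statistic matrix and
#'   acceptance rate.
#' @return a `directed_network` (`nsim = 1`) or list of them; with
#'   `return_stats`, a list with `networks`, `stats`, `accept_rate`.
#' @export
simulate_transition <- function(base, which = c("formation", "dissolution"),
                                theta, terms, attrs = NULL, nsim = 1,
                                control = stergm_control(), seed = NULL,
                                return_stats = FALSE) {
  stopifnot(inherits(base, "directed_network"))
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  if (any(!is.finite(theta))) stop("theta must be finite", call. = FALSE)
  enc <- encode_terms(terms, attrs, base$node_ids)
  if (length(theta) != length(enc$type))
    stop("theta length must match the number of terms", call. = FALSE)
  A <- as_adjacency(base)
  fd <- free_dyads(A, which)
  if (length(fd$i) == 0)
    warning("degenerate transition space: no toggleable dyads; returning base",
            call. = FALSE)
  s <- .cpp_sample(A, fd$i, fd$j, as.numeric(theta), enc$type, enc$decay,
                   enc$attr, control$burnin, control$interval, as.integer(nsim),
                   TRUE)
  nets <- lapply(s$networks, network_from_adjacency,
                 node_ids = base$node_ids, wave = "T1")
  if (return_stats) {
    colnames(s$stats) <- enc$label
    return(list(networks = nets, stats = s$stats, accept_rate = s$accept_rate))
  }
  if (nsim == 1) nets[[1]] else nets
}
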