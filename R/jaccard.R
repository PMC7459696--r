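#' Tie-turnover counts between two waves
#'
#' Classifies every ordered dyad that is tied in at least one wave: `e11`
#' ties present in both waves (persisting), `e10` ties present only at
#' baseline (dissolved), `e01` ties present only at follow-up (newly formed).
#'
#' @param panel a `network_panel`.
#' @return a `turnover_counts` object (list with `e11`, `e10`, `e01`).
#' @export
turnover_counts <- function(panel) {
  stopifnot(inherits(panel, "network_panel"))
  k0 <- edge_keys(panel$t0)
  k1 <- edge_keys(panel$t1)
  structure(list(e11 = length(intersect(k0, k1)),
                 e10 = length(setdiff(k0, k1)),
                 e01 = length(setdiff(k1, k0))),
            class = "turnover_counts")
}

#' @export
print.turnover_counts <- function(x, ...) {
  cat(sprintf("tie turnover: %d persisting, %d dissolved, %d new\n",
              x$e11, x$e10, x$e01))
  invisible(x)
}

#' Jaccard index of tie turnover
#'
#' The Jaccard index of a classroom panel,
#' \deqn{J = \frac{E_{11}}{E_{10} + E_{01} + E_{11}},}
#' measures how much of the ever-present tie set persisted across waves.
#' Values below 0.3 indicate dissolution-dominated change, values above 0.6
#' formation-dominated change, and values in the closed band \[0.3, 0.6\]
#' indicate a meaningful but analyzable amount of turnover (the regime in
#' which longitudinal network modelling is considered appropriate).
#'
#' @param x a `network_panel` or a `turnover_counts` object.
#' @return a `jaccard_index` object: list with `j`, `regime` (one of
#'   `"dissolution_dominant"`, `"meaningful"`, `"formation_dominant"`), and
#'   `counts`.
#' @examples
#' t0 <- directed_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")), "T0")
#' t1 <- directed_network(c("A", "B", "C"), rbind(c("A", "B"), c("C", "A")), "T1")
#' jaccard(network_panel(t0, t1))
#' @export
jaccard <- function(x) {
  counts <- if (inherits(x, "network_panel")) turnover_counts(x)
            else if (inherits(x, "turnover_counts")) x
            else stop("x must be a network_panel or turnover_counts", call. = FALSE)
  tot <- counts$e11 + counts$e10 + counts$e01
  if (tot == 0)
    stop("Jaccard index undefined: no ties in either wave", call. = FALSE)
  j <- counts$e11 / tot
  regime <- if (j < 0.3) "dissolution_dominant"
            else if (j > 0.6) "formation_dominant"
            else "meaningful"
  structure(list(j = j, regime = regime, counts = counts),
            class = "jaccard_index")
}

#' @export
print.jaccard_index <- function(x, digits = 3, ...) {
  cat(sprintf("Jaccard tie-turnover index: %.*f (%s)\n", digits, x$j, x$regime))
  cat(sprintf("  persisting %d / dissolved %d / new %d\n",
              x$counts$e11, x$counts$e10, x$counts$e01))
  invisible(x)
}
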