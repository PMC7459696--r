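#' Build the ordered-dyad design for a dyadic homophily regression
#'
#' One row per ordered dyad (i, j), i != j. The response `y` indicates a
#' directed tie i -> j. Each requested attribute contributes one regressor:
#' a categorical attribute yields a match indicator (Kronecker delta, 1 when
#' i and j share the value), and a continuous attribute yields the absolute
#' difference |x_i - x_j|. Ordered categories used as continuous terms enter
#' through their ordinal level codes. Dyads with a missing regressor are
#' excluded with a warning (count kept in attribute `n_dropped`).
#'
#' @param net a `directed_network`.
#' @param attrs node-attribute data.frame with `node_id`.
#' @param terms named character vector mapping attribute names to
#'   `"categorical"` or `"continuous"`, e.g.
#'   `c(sex = "categorical", age = "continuous")`.
#' @return data.frame with columns `i`, `j`, `y`, then one column per term,
#'   of `n (n - 1)` rows before missing-data exclusion.
#' @export
dyad_design <- function(net, attrs, terms) {
  stopifnot(inherits(net, "directed_network"))
  if (length(net$node_ids) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (length(terms) < 1 || is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("terms must be a named vector: c(attribute = 'categorical'|'continuous')",
         call. = FALSE)
  if (!all(terms %in% c("categorical", "continuous")))
    stop("term kinds must be 'categorical' or 'continuous'", call. = FALSE)
  ids <- net$node_ids
  n <- length(ids)
  A <- as_adjacency(net)
  ij <- which(diag(n) == 0, arr.ind = TRUE)  # all ordered dyads
  des <- data.frame(i = ids[ij[, 1]], j = ids[ij[, 2]],
                    y = A[ij], stringsAsFactors = FALSE)
  ord <- match(ids, attrs$node_id)
  for (a in names(terms)) {
    if (!a %in% names(attrs))
      stop("term references unknown attribute: '", a, "'", call. = FALSE)
    v <- attrs[[a]][ord]
    if (all(is.na(v)))
      stop("attribute '", a, "' is entirely missing", call. = FALSE)
    if (terms[[a]] == "continuous") {
      if (is.ordered(v) || is.factor(v)) v <- as.numeric(v)
      if (!is.numeric(v))
        stop("attribute '", a, "' is not numeric; use kind 'categorical'",
             call. = FALSE)
      des[[a]] <- abs(v[ij[, 1]] - v[ij[, 2]])
    } else {
      vc <- as.character(v)
      des[[a]] <- as.numeric(!is.na(vc[ij[, 1]]) & !is.na(vc[ij[, 2]]) &
                               vc[ij[, 1]] == vc[ij[, 2]])
      des[[a]][is.na(vc[ij[, 1]]) | is.na(vc[ij[, 2]])] <- NA
    }
  }
  keep <- complete.cases(des)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " dyad(s) excluded for missing regressor values",
            call. = FALSE)
    des <- des[keep, , drop = FALSE]
    rownames(des) <- NULL
  }
  attr(des, "n_dropped") <- n_dropped
  attr(des, "wave") <- net$wave
  des
}

#' Fit a dyadic logistic regression by Newton-Raphson maximum likelihood
#'
#' Plain MLE of the tie-probability logit model on a dyadic design (no
#' permutation inference; see [qap()] for that). Convergence requires the
#' largest score component to fall below `tol` within `maxit` iterations;
#' coefficient paths escaping past +/-25 are reported as separation.
#'
#' @param design output of [dyad_design()].
#' @param tol score convergence tolerance.
#' @param maxit maximum Newton-Raphson iterations.
#' @return list with `coefficients` (named, `(intercept)` first), `loglik`,
#'   `converged`.
#' @export
fit_logistic <- function(design, tol = 1e-8, maxit = 100) {
  tcols <- setdiff(names(design), c("i", "j", "y"))
  y <- as.integer(design$y)
  if (length(unique(y)) < 2)
    stop("degenerate model: response is constant", call. = FALSE)
  X <- cbind(`(intercept)` = 1, as.matrix(design[tcols]))
  f <- .cpp_logit(X, y, tol, maxit)
  if (isTRUE(f$separated) || (!f$converged && any(abs(f$coef) > 10)))
    stop("separation detected: a term perfectly predicts ties; ",
         "remove the offending term", call. = FALSE)
  if (!f$converged)
    stop("logistic fit did not converge in ", maxit, " iterations", call. = FALSE)
  list(coefficients = setNames(as.numeric(f$coef), colnames(X)),
       loglik = f$loglik, converged = TRUE)
}

#' QAP logistic regression of dyadic homophily
#'
#' Fits the logistic regression of tie presence on attribute-similarity
#' terms (match indicators for categorical attributes, absolute differences
#' for continuous ones) and assesses each coefficient against a
#' quadratic-assignment permutation null: the adjacency matrix's rows and
#' columns are relabelled by a common uniformly random node permutation
#' (Y-permutation), which preserves every structural property of the
#' observed network while breaking its alignment with the attributes; the
#' design is rebuilt and the model refit for each permutation. The two-sided
#' permutation p-value for a term is
#' `(1 + #permutations with |beta*| >= |beta_obs|) / (n_perm + 1)`.
#'
#' Zero-variance regressors (attribute constant across children) are dropped
#' with a warning. Permutations whose refit fails are redrawn.
#'
#' @inheritParams dyad_design
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; required, so every run is reproducible.
#' @param conf confidence level used to flag significance (default 0.90).
#' @return a `qap_fit` object; its `table` is a data.frame with one row per
#'   coefficient: `estimate` (log-odds), `odds_ratio`, `p_value`,
#'   `significant`.
#' @export
qap <- function(net, attrs, terms, n_perm = 1000, seed = NULL, conf = 0.90) {
  if (is.null(seed))
    stop("seed is required for reproducible permutation inference", call. = FALSE)
  stopifnot(n_perm >= 1)
  # drop zero-variance terms up front
  ord <- match(net$node_ids, attrs$node_id)
  keep <- vapply(names(terms), function(a) {
    v <- attrs[[a]][ord]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  if (any(!keep)) {
    warning("dropping zero-variance term(s): ",
            paste(names(terms)[!keep], collapse = ", "), call. = FALSE)
    terms <- terms[keep]
  }
  if (length(terms) == 0)
    stop("no terms with variation remain", call. = FALSE)
  des <- dyad_design(net, attrs, terms)
  obs <- fit_logistic(des)
  set.seed(seed)
  A <- as_adjacency(net)
  X <- cbind(1, as.matrix(des[names(terms)]))
  di <- match(des$i, net$node_ids) - 1L
  dj <- match(des$j, net$node_ids) - 1L
  pr <- .cpp_qap_perm(A, X, di, dj, as.integer(n_perm))
  b <- obs$coefficients
  pvals <- vapply(seq_along(b), function(c) {
    (1 + sum(abs(pr$coef[, c]) >= abs(b[c]))) / (n_perm + 1)
  }, numeric(1))
  alpha <- 1 - conf
  tab <- data.frame(term = names(b),
                    estimate = as.numeric(b),
                    odds_ratio = exp(as.numeric(b)),
                    p_value = pvals,
                    significant = pvals < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, wave = net$wave, n_perm = n_perm, seed = seed,
                 conf = conf, n_redrawn = pr$n_redrawn, loglik = obs$loglik,
                 n_dyads = nrow(des), n_dropped = attr(des, "n_dropped")),
            class = "qap_fit")
}

#' @export
print.qap_fit <- function(x, digits = 3, ...) {
  cat(sprintf("QAP logistic regression of dyadic homophily (wave %s)\n", x$wave))
  cat(sprintf("  %d ordered dyads, %d permutations, seed %d\n",
              x$n_dyads, x$n_perm, x$seed))
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$odds_ratio <- round(tab$odds_ratio, digits)
  tab$p_value <- round(tab$p_value, digits)
  tab$significant <- ifelse(tab$significant, "*", "")
  print(tab, row.names = FALSE)
  cat(sprintf("  * permutation p < %.2f (%.0f%% confidence); no multiplicity correction\n",
              1 - x$conf, 100 * x$conf))
  invisible(x)
}

#' @export
summary.qap_fit <- function(object, ...) {
  print(object, ...)
  if (object$n_redrawn > 0)
    cat(sprintf("  %d failed permutation fit(s) redrawn\n", object$n_redrawn))
  invisible(object$table)
}

#' @export
coef.qap_fit <- function(object, ...) {
  setNames(object$table$estimate, object$table$term)
}
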