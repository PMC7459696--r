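## Conditional maximum-likelihood estimation of separable temporal ERGMs.
##
## The two-wave transition is modelled as two independent exponential-family
## processes on constrained spaces: formation (y+ ranges over supersets of
## y0) and dissolution (y- over subsets of y0). Each side is estimated
## separately. Three routes, auto-selected:
##   * dyad-independent terms (edges/absdiff/nodematch): the conditional
##     likelihood factorizes over free dyads, so the MLE is an exact logistic
##     regression on change statistics;
##   * small spaces (free dyads <= exact_max_free): exact MLE by Gray-code
##     enumeration of all configurations;
##   * otherwise MCMC-MLE (Geyer-Thompson importance sampling with Newton
##     steps, step-halving and a Mahalanobis stopping rule), initialized at
##     the maximum pseudolikelihood estimate.

degeneracy_error <- function(term, detail) {
  stop(errorCondition(
    paste0("model degeneracy involving term '", term, "': ", detail,
           "; consider removing the term"),
    class = c("classnet_degeneracy", "error", "condition")))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

mple_fit <- function(A_obs, fd, enc) {
  D <- .cpp_mple_design(A_obs, fd$i, fd$j, enc$type, enc$decay, enc$attr)
  y <- as.integer(A_obs[cbind(fd$i + 1L, fd$j + 1L)])
  if (length(unique(y)) < 2) {
    state <- if (y[1] == 1) "every free dyad is on" else "every free dyad is off"
    degeneracy_error(enc$label[1], paste0("observed network is at the boundary (",
                                          state, ")"))
  }
  f <- .cpp_logit(D, y, 1e-8, 100)
  if (isTRUE(f$separated) || !f$converged)
    degeneracy_error(enc$label[which.max(abs(f$coef))],
                     "pseudolikelihood separation (coefficients diverge)")
  mu <- 1 / (1 + exp(-drop(D %*% f$coef)))
  H <- crossprod(D * (mu * (1 - mu)), D)
  se <- sqrt(diag(solve(H)))
  list(estimate = as.numeric(f$coef), se = as.numeric(se),
       method = "cmle_logistic", diagnostics = list(loglik = f$loglik))
}

exact_fit <- function(A_base_cfg, A_obs, fd, enc) {
  G <- .cpp_enumerate(A_base_cfg, fd$i, fd$j, enc$type, enc$decay, enc$attr)
  g_obs <- as.numeric(.cpp_stats(A_obs, enc$type, enc$decay, enc$attr))
  p <- length(enc$type)
  nll <- function(th) -(sum(th * g_obs) - log_sum_exp(drop(G %*% th)))
  gr <- function(th) {
    lp <- drop(G %*% th)
    w <- exp(lp - log_sum_exp(lp))
    -(g_obs - drop(crossprod(G, w)))
  }
  init <- tryCatch(mple_fit(A_obs, fd, enc)$estimate,
                   classnet_degeneracy = function(e) stop(e),
                   error = function(e) rep(0, p))
  opt <- optim(init, nll, gr, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  th <- opt$par
  if (any(abs(th) > 25))
    degeneracy_error(enc$label[which.max(abs(th))],
                     "conditional MLE diverges (observed statistic on the hull boundary)")
  lp <- drop(G %*% th)
  w <- exp(lp - log_sum_exp(lp))
  mu <- drop(crossprod(G, w))
  Gc <- sweep(G, 2, mu)
  V <- crossprod(Gc * w, Gc)  # Fisher information = Cov_theta(g)
  se <- sqrt(diag(solve(V)))
  list(estimate = th, se = as.numeric(se), method = "cmle_exact",
       diagnostics = list(loglik = -opt$value, g_obs = g_obs, mean_stats = mu))
}

mcmc_fit <- function(A_base, A_obs, fd, which, enc, control) {
  g_obs <- as.numeric(.cpp_stats(A_obs, enc$type, enc$decay, enc$attr))
  p <- length(enc$type)
  theta <- tryCatch(mple_fit(A_obs, fd, enc)$estimate,
                    classnet_degeneracy = function(e) stop(e),
                    error = function(e) rep(0, p))
  converged <- FALSE
  z <- NA_real_
  trace <- list()
  G <- NULL
  accept <- NA_real_
  for (it in seq_len(control$maxit)) {
    s <- .cpp_sample(A_obs, fd$i, fd$j, theta, enc$type, enc$decay, enc$attr,
                     control$burnin, control$interval,
                     as.integer(control$samplesize), FALSE)
    G <- s$stats
    accept <- s$accept_rate
    mu <- colMeans(G)
    V <- cov(G)
    vars <- diag(V)
    flat <- vars < 1e-10
    if (any(flat) && any(abs(g_obs - mu)[flat] > 1e-8))
      degeneracy_error(enc$label[which(flat)[1]],
                       "sampled statistics collapse to a boundary value")
    Vr <- V + diag(1e-8 * pmax(vars, 1), p)
    z <- sqrt(max(0, mahalanobis(g_obs, mu, Vr)))
    trace[[it]] <- c(theta = theta, z = z)
    if (z < control$ztol) { converged <- TRUE; break }
    dt <- drop(solve(Vr, g_obs - mu))
    if (max(abs(dt)) > control$step_max)
      dt <- dt * control$step_max / max(abs(dt))
    # importance-sampled log-likelihood gain; step-halve when not improving
    obj <- function(d) sum(d * g_obs) - log_sum_exp(drop(G %*% d)) + log(nrow(G))
    h <- 0
    while (obj(dt) < 0 && h < 10) { dt <- dt / 2; h <- h + 1 }
    theta <- theta + dt
    if (any(abs(theta) > 25))
      degeneracy_error(enc$label[which.max(abs(theta))],
                       "MCMC-MLE coefficients diverge")
  }
  if (!converged)
    warning("MCMC-MLE did not reach the mean-value convergence tolerance in ",
            control$maxit, " iterations (final z = ", signif(z, 3), ")",
            call. = FALSE)
  V <- cov(G) + diag(1e-8, p)
  se <- sqrt(diag(solve(V)))
  list(estimate = theta, se = as.numeric(se), method = "cmle_mcmc",
       diagnostics = list(accept_rate = accept, iterations = length(trace),
                          mahalanobis_z = z, converged = converged,
                          g_obs = g_obs, mean_stats = colMeans(G),
                          trace = do.call(rbind, trace)))
}

fit_side <- function(A_base, A_obs, which, terms, attrs, node_ids, control) {
  enc <- encode_terms(terms, attrs, node_ids)
  fd <- free_dyads(A_base, which)
  if (length(fd$i) == 0)
    stop("no free dyads on the ", which, " side: nothing to estimate",
         call. = FALSE)
  dyad_indep <- all(enc$type %in% c(0L, 3L, 4L))
  method <- control$method
  if (method == "auto") {
    method <- if (dyad_indep) "mple"
              else if (length(fd$i) <= control$exact_max_free) "exact"
              else "mcmc"
  }
  fit <- switch(method,
    mple = mple_fit(A_obs, fd, enc),
    exact = exact_fit(A_base, A_obs, fd, enc),
    mcmc = mcmc_fit(A_base, A_obs, fd, which, enc, control))
  fit$labels <- enc$label
  fit$n_free <- length(fd$i)
  fit
}

side_table <- function(fit, conf) {
  zq <- qnorm(1 - (1 - conf) / 2)
  est <- fit$estimate
  se <- fit$se
  zst <- est / se
  pv <- 2 * pnorm(-abs(zst))
  data.frame(term = fit$labels, estimate = est, se = se,
             ci_lo = est - zq * se, ci_hi = est + zq * se,
             z = zst, p_value = pv, significant = pv < (1 - conf),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a separable temporal ERGM to a two-wave classroom panel
#'
#' Estimates formation coefficients theta+ and dissolution coefficients
#' theta- by conditional maximum likelihood, treating tie formation and tie
#' dissolution between the two waves as independent exponential-family
#' processes on their constrained spaces (see [stergm_decompose()]).
#' Dissolution coefficients parameterize tie persistence: a positive
#' dissolution coefficient means ties with that feature are preferentially
#' preserved, a negative one that they are preferentially dissolved.
#'
#' Dyad-independent models are solved in closed form; small transition
#' spaces by exact enumeration; all others by MCMC maximum likelihood with
#' standard errors from the inverse estimated Fisher information (the MCMC
#' covariance of the statistics). Model degeneracy (sampled statistics
#' collapsing to a boundary, or a diverging coefficient) raises an error of
#' class `classnet_degeneracy` naming the offending term, which callers such
#' as [run_study()] record rather than propagate.
#'
#' @param panel a `network_panel`.
#' @param formation,dissolution term vectors for the two sides (see
#'   [parse_terms()]).
#' @param control a [stergm_control()] list.
#' @param seed optional integer seed governing all MCMC randomness.
#' @param conf confidence level for intervals and significance flags
#'   (default 0.90).
#' @return a `stergm_fit` object with `formation` and `dissolution`
#'   coefficient tables (estimate, SE, CI, z, p), methods used, and MCMC
#'   diagnostics.
#' @export
stergm <- function(panel, formation = "edges", dissolution = "edges",
                   control = stergm_control(), seed = NULL, conf = 0.90) {
  stopifnot(inherits(panel, "network_panel"))
  if (!is.null(seed)) set.seed(seed)
  dec <- stergm_decompose(panel)
  A0 <- as_adjacency(dec$base)
  Af <- as_adjacency(dec$formation)
  Ad <- as_adjacency(dec$dissolution)
  ids <- panel$t0$node_ids
  ff <- fit_side(A0, Af, "formation", formation, panel$attrs, ids, control)
  fd <- fit_side(A0, Ad, "dissolution", dissolution, panel$attrs, ids, control)
  structure(list(
    formation = side_table(ff, conf),
    dissolution = side_table(fd, conf),
    conf = conf,
    classroom_id = panel$classroom_id,
    method = c(formation = ff$method, dissolution = fd$method),
    n_free = c(formation = ff$n_free, dissolution = fd$n_free),
    converged = !isFALSE(ff$diagnostics$converged) &&
                !isFALSE(fd$diagnostics$converged),
    diagnostics = list(formation = ff$diagnostics, dissolution = fd$diagnostics),
    seed = seed),
    class = "stergm_fit")
}

#' @export
print.stergm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("separable temporal ERGM fit ('%s'), %.0f%% confidence level\n",
              x$classroom_id, 100 * x$conf))
  for (side in c("formation", "dissolution")) {
    cat(sprintf("\n%s model (%s, %d free dyads):\n", side, x$method[[side]],
                x$n_free[[side]]))
    tab <- x$table_rounded <- x[[side]]
    for (cn in c("estimate", "se", "ci_lo", "ci_hi", "z"))
      tab[[cn]] <- round(tab[[cn]], digits)
    tab$p_value <- round(tab$p_value, digits)
    tab$significant <- ifelse(tab$significant, "*", "")
    print(tab, row.names = FALSE)
  }
  if (!x$converged) cat("\nwarning: fit did not converge\n")
  invisible(x)
}

#' @export
summary.stergm_fit <- function(object, ...) {
  print(object, ...)
  cat("\n")
  print(interpret_stergm(object))
  invisible(object)
}

#' @export
coef.stergm_fit <- function(object, ...) {
  list(formation = setNames(object$formation$estimate, object$formation$term),
       dissolution = setNames(object$dissolution$estimate, object$dissolution$term))
}

#' Sign-based interpretation of a fitted STERGM
#'
#' Maps each coefficient significant at the fit's confidence level to its
#' substantive reading: on the formation side a positive coefficient raises
#' the probability of forming ties carrying the feature, on the dissolution
#' side a positive coefficient raises the probability of preserving them and
#' a negative one the probability of dissolving them.
#'
#' @param fit a `stergm_fit`.
#' @return data.frame with `side`, `term`, `estimate`, `p_value`,
#'   `interpretation`.
#' @export
interpret_stergm <- function(fit) {
  stopifnot(inherits(fit, "stergm_fit"))
  lvl <- sprintf("%.0f%%", 100 * fit$conf)
  one <- function(side) {
    tab <- fit[[side]]
    msg <- vapply(seq_len(nrow(tab)), function(r) {
      if (!tab$significant[r]) return(paste("not significant at", lvl))
      if (side == "formation") {
        if (tab$estimate[r] > 0) "increase in the probability of forming ties"
        else "decrease in the probability of forming ties"
      } else {
        if (tab$estimate[r] > 0) "increase in the probability of preserving ties"
        else "increase in the probability of dissolving ties"
      }
    }, character(1))
    data.frame(side = side, term = tab$term, estimate = tab$estimate,
               p_value = tab$p_value, interpretation = msg,
               stringsAsFactors = FALSE)
  }
  rbind(one("formation"), one("dissolution"))
}
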