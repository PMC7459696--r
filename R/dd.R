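#' Build a node-wave long panel for difference-in-differences estimation
#'
#' Stacks one cohesion metric per node per wave across the classrooms of a
#' treatment group and a control group. Each node contributes exactly two
#' rows (T0, T1); its treatment indicator is constant. Nodes missing a
#' requested covariate are excluded with a warning.
#'
#' @param panels list of `network_panel` objects whose attribute tables
#'   carry a `group` column (constant within classroom).
#' @param treat_group,control_group group labels selecting the two arms
#'   (classrooms in other groups are excluded entirely).
#' @param metric one of `"closeness"`, `"degree"`, `"in_degree"`,
#'   `"out_degree"`, `"clustering"`.
#' @param covariates character vector of attribute columns to carry along.
#' @param closeness closeness convention passed to [node_metrics()].
#' @return a `dd_panel` data.frame: `classroom`, `node`, `y`, `treat`,
#'   `time`, plus covariates; attributes `metric` and `contrast`.
#' @export
dd_panel <- function(panels, treat_group, control_group, metric = "degree",
                     covariates = character(0),
                     closeness = c("wasserman_faust", "harmonic")) {
  metric <- match.arg(metric, c("closeness", "degree", "in_degree",
                                "out_degree", "clustering"))
  closeness <- match.arg(closeness)
  groups <- vapply(panels, function(p) as.character(p$attrs$group[1]), character(1))
  sel_t <- panels[groups == treat_group]
  sel_c <- panels[groups == control_group]
  if (length(sel_t) == 0) stop("empty treatment group: '", treat_group, "'",
                               call. = FALSE)
  if (length(sel_c) == 0) stop("empty control group: '", control_group, "'",
                               call. = FALSE)
  rows <- list()
  for (p in c(sel_t, sel_c)) {
    tr <- as.integer(as.character(p$attrs$group[1]) == treat_group)
    for (w in c("T0", "T1")) {
      net <- if (w == "T0") p$t0 else p$t1
      m <- node_metrics(net, closeness)
      d <- data.frame(classroom = p$classroom_id,
                      node = paste(p$classroom_id, m$node_id, sep = ":"),
                      y = m[[metric]], treat = tr,
                      time = as.integer(w == "T1"),
                      stringsAsFactors = FALSE)
      for (cv in covariates) {
        if (!cv %in% names(p$attrs))
          stop("covariate '", cv, "' not found in attributes of classroom '",
               p$classroom_id, "'", call. = FALSE)
        d[[cv]] <- p$attrs[[cv]][match(m$node_id, p$attrs$node_id)]
      }
      rows[[length(rows) + 1]] <- d
    }
  }
  out <- do.call(rbind, rows)
  if (length(covariates)) {
    keep_node <- tapply(complete.cases(out[covariates]), out$node, all)
    drop <- names(keep_node)[!keep_node]
    if (length(drop)) {
      warning(length(drop), " node(s) excluded for missing covariate values",
              call. = FALSE)
      out <- out[!out$node %in% drop, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "contrast") <- paste(treat_group, "vs", control_group)
  class(out) <- c("dd_panel", "data.frame")
  out
}

#' Difference-in-differences estimation of an intervention effect
#'
#' Fits the two-period interaction model
#' \deqn{y_i = \beta_0 + \beta_1 t_i + \beta_2 T_i + \beta_3 t_i T_i + \gamma' z_i}
#' by ordinary least squares, where \eqn{t_i} indicates treatment and
#' \eqn{T_i} the follow-up wave. \eqn{\beta_3} is the treated group's change
#' net of the control group's change — on a covariate-free balanced panel it
#' equals the 2x2 difference of group-by-wave means exactly. Classical OLS
#' standard errors are the default; `se = "cluster"` uses node-clustered
#' robust (CR1) standard errors, which respect the dependence between a
#' node's two observations.
#'
#' @param panel a `dd_panel` from [dd_panel()].
#' @param covariates covariate columns of the panel to adjust for.
#' @param se `"classical"` or `"cluster"` (robust, clustered on `cluster_by`).
#' @param cluster_by `"node"` (default: a node's two waves are dependent) or
#'   `"classroom"` (also absorbs the dependence between nodes who share a
#'   network, e.g. through common ties; needs several classrooms per arm).
#' @param conf confidence level used to flag significance (default 0.90).
#' @return a `dd_fit` object; its `table` has rows `(intercept)`, `treat`,
#'   `time`, `treat:time`, then covariates, with columns `estimate`, `se`,
#'   `t`, `p_value`, `significant`.
#' @export
dd <- function(panel, covariates = character(0),
               se = c("classical", "cluster"),
               cluster_by = c("node", "classroom"), conf = 0.90) {
  se <- match.arg(se)
  cluster_by <- match.arg(cluster_by)
  stopifnot(is.data.frame(panel), all(c("y", "treat", "time", "node") %in% names(panel)))
  if (length(unique(panel$treat)) < 2)
    stop("panel must contain both a treated and a control arm", call. = FALSE)
  for (g in 0:1)
    if (length(unique(panel$node[panel$treat == g])) < 2)
      stop("need at least 2 nodes per group", call. = FALSE)
  rhs <- "treat * time"
  if (length(covariates)) {
    miss <- setdiff(covariates, names(panel))
    if (length(miss)) stop("covariate(s) not in panel: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    rhs <- paste(rhs, "+", paste(covariates, collapse = " + "))
  }
  fit <- lm(as.formula(paste("y ~", rhs)), data = panel)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (se == "cluster") {
    cl <- if (cluster_by == "classroom") {
      if (!"classroom" %in% names(panel))
        stop("cluster_by = 'classroom' needs a classroom column", call. = FALSE)
      panel$classroom
    } else panel$node
    V <- sandwich::vcovCL(fit, cluster = cl)
    dfree <- length(unique(cl)) - 1
  } else {
    V <- vcov(fit)
    dfree <- fit$df.residual
  }
  b <- coef(fit)
  s <- sqrt(diag(V))
  tstat <- b / s
  pv <- 2 * pt(-abs(tstat), dfree)
  nm <- names(b)
  nm[nm == "(Intercept)"] <- "(intercept)"
  tab <- data.frame(term = nm, estimate = as.numeric(b), se = as.numeric(s),
                    t = as.numeric(tstat), p_value = as.numeric(pv),
                    significant = pv < (1 - conf),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, metric = attr(panel, "metric"),
                 contrast = attr(panel, "contrast"), n_obs = nrow(panel),
                 n_nodes = length(unique(panel$node)),
                 se_type = if (se == "cluster") paste0("cluster_", cluster_by) else se,
                 conf = conf, lm = fit),
            class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, digits = 4, ...) {
  cat(sprintf("difference-in-differences: %s, metric %s\n",
              x$contrast %||% "(unlabelled contrast)", x$metric %||% "?"))
  cat(sprintf("  %d observations (%d nodes x 2 waves), %s SEs\n",
              x$n_obs, x$n_nodes, x$se_type))
  tab <- x$table
  for (cn in c("estimate", "se", "t", "p_value"))
    tab[[cn]] <- round(tab[[cn]], digits)
  tab$significant <- ifelse(tab$significant, "*", "")
  print(tab, row.names = FALSE)
  cat(sprintf("  * p < %.2f (%.0f%% confidence)\n", 1 - x$conf, 100 * x$conf))
  invisible(x)
}

#' @export
coef.dd_fit <- function(object, ...) {
  setNames(object$table$estimate, object$table$term)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full grid of intervention contrasts and cohesion metrics
#'
#' Estimates the difference-in-differences model for the three group
#' contrasts (MARA vs control, MARA+SMS vs control, MARA+SMS vs MARA) and
#' the five cohesion metrics.
#'
#' @param panels list of `network_panel` objects with `group` attributes
#'   drawn from `MARA_SMS`, `MARA`, `CONTROL`.
#' @param metrics metrics to analyse (default all five).
#' @param covariates,se,conf passed to [dd()].
#' @return list with `table` (one row per contrast x metric, reporting the
#'   interaction coefficient beta3) and `fits` (the `dd_fit` objects).
#' @export
dd_contrasts <- function(panels,
                         metrics = c("closeness", "degree", "in_degree",
                                     "out_degree", "clustering"),
                         covariates = character(0),
                         se = c("classical", "cluster"), conf = 0.90) {
  se <- match.arg(se)
  contrasts <- list(c("MARA", "CONTROL"),
                    c("MARA_SMS", "CONTROL"),
                    c("MARA_SMS", "MARA"))
  fits <- list()
  rows <- list()
  for (ct in contrasts) {
    for (m in metrics) {
      pan <- dd_panel(panels, ct[1], ct[2], metric = m, covariates = covariates)
      f <- dd(pan, covariates = covariates, se = se, conf = conf)
      key <- paste(ct[1], "vs", ct[2], m, sep = ".")
      fits[[key]] <- f
      r <- f$table[f$table$term == "treat:time", ]
      rows[[key]] <- data.frame(contrast = paste(ct[1], "vs", ct[2]),
                                metric = m, beta3 = r$estimate, se = r$se,
                                t = r$t, p_value = r$p_value,
                                significant = r$significant,
                                stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
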