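#' Run the four-stage analysis over a study
#'
#' Executes, per classroom, the enabled stages of the pipeline: (1) tie
#' turnover (Jaccard index and regime, plus per-wave cohesion summaries),
#' (2) QAP homophily regressions per wave, (3) separable temporal ERGMs of
#' formation and dissolution, and (4) the difference-in-differences grid of
#' three group contrasts by five cohesion metrics. A classroom whose STERGM
#' is degenerate is recorded as such and does not abort the others. The
#' whole run is deterministic given `seed`.
#'
#' @param study a `classnet_study` or a list of `network_panel` objects.
#' @param stages subset of `1:4` to run.
#' @param qap_terms homophily terms for stage 2 (see [dyad_design()]).
#' @param n_perm QAP permutations.
#' @param formation,dissolution STERGM term vectors for stage 3.
#' @param stergm_ctrl a [stergm_control()] list.
#' @param dd_metrics,dd_covariates,dd_se stage-4 settings (see
#'   [dd_contrasts()]).
#' @param conf confidence level used throughout (default 0.90).
#' @param seed integer seed; mandatory when any stochastic stage is enabled.
#' @return a `study_report` list: `jaccard`, `summaries`, `qap`, `stergm`,
#'   `stergm_status`, `dd`, and `meta` (seed and the conventions in force:
#'   closeness variant, clustering convention, permutation scheme, decays).
#' @export
run_study <- function(study, stages = 1:4,
                      qap_terms = c(sex = "categorical", age = "continuous",
                                    bmi = "continuous", mvpa = "continuous"),
                      n_perm = 1000,
                      formation = c("edges", "gwesp(0.25)", "absdiff(mvpa)"),
                      dissolution = c("edges", "absdiff(mvpa)"),
                      stergm_ctrl = stergm_control(),
                      dd_metrics = c("closeness", "degree", "in_degree",
                                     "out_degree", "clustering"),
                      dd_covariates = character(0),
                      dd_se = "classical",
                      conf = 0.90, seed = NULL) {
  panels <- if (inherits(study, "classnet_study")) study$panels else study
  stopifnot(length(panels) >= 1,
            all(vapply(panels, inherits, logical(1), "network_panel")))
  if (is.null(seed) && any(c(2, 3) %in% stages))
    stop("seed is required when stochastic stages (2, 3) are enabled",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cls <- vapply(panels, function(p) p$classroom_id, character(1))
  grp <- vapply(panels, function(p) {
    if ("group" %in% names(p$attrs)) as.character(p$attrs$group[1]) else NA_character_
  }, character(1))
  report <- list(meta = list(
    seed = seed, conf = conf, n_perm = n_perm,
    closeness = "wasserman_faust (directed paths)",
    clustering = "undirected reduction",
    permutation_scheme = "y_permutation",
    formation_terms = formation, dissolution_terms = dissolution,
    qap_terms = qap_terms))

  if (1 %in% stages) {
    report$jaccard <- do.call(rbind, lapply(seq_along(panels), function(k) {
      jc <- jaccard(panels[[k]])
      data.frame(classroom = cls[k], group = grp[k],
                 e11 = jc$counts$e11, e10 = jc$counts$e10, e01 = jc$counts$e01,
                 jaccard = jc$j, regime = jc$regime, stringsAsFactors = FALSE)
    }))
    report$summaries <- do.call(rbind, lapply(seq_along(panels), function(k) {
      p <- panels[[k]]
      rbind(cbind(classroom = cls[k], group = grp[k], wave = "T0",
                  network_summary(p$t0)),
            cbind(classroom = cls[k], group = grp[k], wave = "T1",
                  network_summary(p$t1)))
    }))
    rownames(report$summaries) <- NULL
  }

  if (2 %in% stages) {
    qap_seeds <- sample.int(.Machine$integer.max, 2 * length(panels))
    rows <- list()
    for (k in seq_along(panels)) {
      p <- panels[[k]]
      for (w in c("T0", "T1")) {
        net <- if (w == "T0") p$t0 else p$t1
        f <- qap(net, p$attrs, qap_terms, n_perm = n_perm,
                 seed = qap_seeds[2 * (k - 1) + (w == "T1") + 1], conf = conf)
        rows[[paste(cls[k], w)]] <- cbind(classroom = cls[k], group = grp[k],
                                          wave = w, f$table)
      }
    }
    report$qap <- do.call(rbind, rows)
    rownames(report$qap) <- NULL
  }

  if (3 %in% stages) {
    st_seeds <- sample.int(.Machine$integer.max, length(panels))
    rows <- list()
    status <- list()
    for (k in seq_along(panels)) {
      res <- tryCatch({
        f <- stergm(panels[[k]], formation = formation,
                    dissolution = dissolution, control = stergm_ctrl,
                    seed = st_seeds[k], conf = conf)
        interp <- interpret_stergm(f)
        tab <- rbind(cbind(side = "formation", f$formation),
                     cbind(side = "dissolution", f$dissolution))
        tab$interpretation <- interp$interpretation[
          match(paste(tab$side, tab$term), paste(interp$side, interp$term))]
        list(tab = cbind(classroom = cls[k], group = grp[k], tab),
             status = if (f$converged) "ok" else "not_converged")
      },
      classnet_degeneracy = function(e) list(tab = NULL,
                                             status = paste("degenerate:",
                                                            conditionMessage(e))),
      error = function(e) list(tab = NULL,
                               status = paste("error:", conditionMessage(e))))
      if (!is.null(res$tab)) rows[[cls[k]]] <- res$tab
      status[[cls[k]]] <- data.frame(classroom = cls[k], group = grp[k],
                                     status = res$status,
                                     stringsAsFactors = FALSE)
    }
    report$stergm <- if (length(rows)) do.call(rbind, rows) else NULL
    if (!is.null(report$stergm)) rownames(report$stergm) <- NULL
    report$stergm_status <- do.call(rbind, status)
    rownames(report$stergm_status) <- NULL
  }

  if (4 %in% stages) {
    dc <- dd_contrasts(panels, metrics = dd_metrics,
                       covariates = dd_covariates, se = dd_se, conf = conf)
    report$dd <- dc$table
    report$dd_fits <- dc$fits
  }

  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat("study report (seed", x$meta$seed %||% "none", ")\n")
  if (!is.null(x$jaccard)) {
    cat("\ntie turnover (Jaccard):\n")
    tj <- x$jaccard
    tj$jaccard <- round(tj$jaccard, digits)
    print(tj, row.names = FALSE)
  }
  if (!is.null(x$qap)) {
    nsig <- sum(x$qap$significant & x$qap$term != "(intercept)")
    cat(sprintf("\nQAP homophily: %d significant term(s) at %.0f%% across %d model(s)\n",
                nsig, 100 * x$meta$conf, length(unique(paste(x$qap$classroom, x$qap$wave)))))
  }
  if (!is.null(x$stergm_status)) {
    cat("\nSTERGM status:\n")
    print(x$stergm_status, row.names = FALSE)
  }
  if (!is.null(x$dd)) {
    cat("\ndifference-in-differences (beta3 per contrast x metric):\n")
    td <- x$dd
    for (cn in c("beta3", "se", "t", "p_value")) td[[cn]] <- round(td[[cn]], digits)
    td$significant <- ifelse(td$significant, "*", "")
    print(td, row.names = FALSE)
  }
  cat(sprintf("\nconventions: closeness = %s; clustering = %s; QAP = %s; %.0f%% confidence\n",
              x$meta$closeness, x$meta$clustering, x$meta$permutation_scheme,
              100 * x$meta$conf))
  invisible(x)
}

#' Count classrooms per group whose cohesion rose between waves
#'
#' Produces "k/m" pattern strings: of the m classrooms in a group, k showed
#' an increase in the average of the chosen metric from T0 to T1.
#'
#' @param report a `study_report` with stage-1 output.
#' @param metrics summary columns to tally (default average clustering and
#'   average degree).
#' @return data.frame with `group`, `metric`, `increased`, `total`,
#'   `pattern`.
#' @export
summarize_group_pattern <- function(report,
                                    metrics = c("avg_clustering", "avg_degree")) {
  stopifnot(inherits(report, "study_report"), !is.null(report$summaries))
  s <- report$summaries
  rows <- list()
  for (g in unique(s$group)) {
    sg <- s[s$group == g, ]
    for (m in metrics) {
      wide <- merge(sg[sg$wave == "T0", c("classroom", m)],
                    sg[sg$wave == "T1", c("classroom", m)],
                    by = "classroom", suffixes = c("_t0", "_t1"))
      inc <- sum(wide[[paste0(m, "_t1")]] > wide[[paste0(m, "_t0")]])
      rows[[paste(g, m)]] <- data.frame(
        group = g, metric = m, increased = inc, total = nrow(wide),
        pattern = sprintf("%d/%d", inc, nrow(wide)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
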