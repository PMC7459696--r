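## Synthetic classroom-panel generator.
##
## Baseline networks are drawn from an exponential-family model (edges +
## sex-match + gwesp) by long-run Metropolis sampling; the T0 -> T1
## transition is drawn from the same separable formation/dissolution family
## the estimator fits, so every stage of the pipeline can be checked by
## parameter recovery against recorded ground truth. Attribute envelopes
## (sex ratio, age 9-13 y, BMI 13.3-27.75 kg/m^2, MVPA 19.92-143.9 min/day)
## follow the descriptive ranges of the study population the generator
## emulates; the distributions within those envelopes are the package's own
## choices and are documented as such.

rtrunc <- function(n, rfun, lo, hi, max_tries = 1000) {
  out <- rfun(n)
  for (k in seq_len(max_tries)) {
    bad <- out < lo | out > hi
    if (!any(bad)) return(out)
    out[bad] <- rfun(sum(bad))
  }
  stop("impossible envelope: rejection sampling failed for [", lo, ", ", hi, "]",
       call. = FALSE)
}

#' Configuration of one synthetic classroom panel
#'
#' Defaults emulate the study conditions the generator targets: classrooms
#' of about 20 children, sex-homophilous and transitively closed baseline
#' networks, and a two-wave transition whose turnover lands the Jaccard
#' index in the meaningful 0.3-0.6 band.
#'
#' @param n_nodes children per classroom (observed classrooms held 11-25).
#' @param group `"MARA_SMS"`, `"MARA"` or `"CONTROL"`.
#' @param t0_terms,t0_theta baseline network model and truth coefficients.
#' @param form_terms,form_theta formation model and truth coefficients.
#' @param diss_terms,diss_theta dissolution model and truth coefficients
#'   (persistence parameterization).
#' @param added_degree planted intervention effect: extra mean degree added
#'   to the classroom at T1 (0 = no effect). `added_degree * n / 2` extra
#'   directed ties are placed uniformly at random among absent T1 dyads.
#' @param sex_p_female probability a child is female.
#' @param age_range,bmi_range,mvpa_range attribute envelopes (rejection
#'   sampled).
#' @param bmi_mean,bmi_sd,mvpa_meanlog,mvpa_sdlog attribute distribution
#'   parameters.
#' @param satisfaction_p probability each satisfaction indicator is 1
#'   (intervened groups only; control has no satisfaction data).
#' @param burnin_per_dyad Metropolis toggles per dyad for network draws.
#' @return a `classroom_config` list.
#' @export
classroom_config <- function(n_nodes = 20, group = "CONTROL",
                             t0_terms = c("edges", "nodematch(sex)", "gwesp(0.25)"),
                             t0_theta = c(-2.2, 0.8, 0.5),
                             form_terms = c("edges", "gwesp(0.25)"),
                             form_theta = c(-2, 0.8),
                             diss_terms = "edges",
                             diss_theta = 1,
                             added_degree = 0,
                             sex_p_female = 71 / 125,
                             age_range = c(9, 13),
                             bmi_mean = 18.5, bmi_sd = 2.8,
                             bmi_range = c(13.3, 27.75),
                             mvpa_meanlog = log(55), mvpa_sdlog = 0.45,
                             mvpa_range = c(19.92, 143.9),
                             satisfaction_p = 0.8,
                             burnin_per_dyad = 400) {
  stopifnot(n_nodes >= 2, group %in% c("MARA_SMS", "MARA", "CONTROL"),
            length(t0_theta) == length(t0_terms),
            length(form_theta) == length(form_terms),
            length(diss_theta) == length(diss_terms),
            added_degree >= 0)
  if (age_range[1] > age_range[2] || bmi_range[1] > bmi_range[2] ||
      mvpa_range[1] > mvpa_range[2])
    stop("impossible envelope: range limits reversed", call. = FALSE)
  structure(as.list(environment()), class = "classroom_config")
}

#' Generate a synthetic node-attribute table
#'
#' Draws one classroom's attribute table from the configured distributions.
#' Satisfaction indicator columns are present only for intervened groups.
#' Uses the current RNG state; call `set.seed()` (or go through
#' [generate_panel()] / [generate_study()]) for reproducibility.
#'
#' @param cfg a [classroom_config()].
#' @param prefix node-id prefix.
#' @return node-attribute data.frame.
#' @export
generate_attributes <- function(cfg = classroom_config(), prefix = "c") {
  n <- cfg$n_nodes
  bmi <- rtrunc(n, function(k) rnorm(k, cfg$bmi_mean, cfg$bmi_sd),
                cfg$bmi_range[1], cfg$bmi_range[2])
  mvpa <- rtrunc(n, function(k) rlnorm(k, cfg$mvpa_meanlog, cfg$mvpa_sdlog),
                 cfg$mvpa_range[1], cfg$mvpa_range[2])
  at <- data.frame(
    node_id = sprintf("%s%02d", prefix, seq_len(n)),
    sex = sample(c("F", "M"), n, replace = TRUE,
                 prob = c(cfg$sex_p_female, 1 - cfg$sex_p_female)),
    age = runif(n, cfg$age_range[1], cfg$age_range[2]),
    maternal_education = factor(
      sample(c("less_than_hs", "incomplete_hs", "complete_hs", "university"),
             n, replace = TRUE, prob = c(0.25, 0.30, 0.30, 0.15)),
      levels = c("less_than_hs", "incomplete_hs", "complete_hs", "university"),
      ordered = TRUE),
    household_income = factor(
      sample(c("low", "low_middle", "middle"), n, replace = TRUE,
             prob = c(0.50, 0.35, 0.15)),
      levels = c("low", "low_middle", "middle"), ordered = TRUE),
    bmi = bmi,
    mvpa = mvpa,
    group = cfg$group,
    stringsAsFactors = FALSE)
  at$bmi_category <- cut(at$bmi, c(-Inf, 14.5, 21, Inf),
                         labels = c("underweight", "normal", "overweight"))
  at$meets_pa_guideline <- as.integer(at$mvpa >= 60)
  if (cfg$group != "CONTROL") {
    for (s in c("participation", "enjoying_time", "do_pa",
                "recreation_safety", "healthy_experience"))
      at[[s]] <- rbinom(n, 1, cfg$satisfaction_p)
  }
  at
}

# one network draw from an exponential-family model over all dyads
draw_network <- function(attrs, terms, theta, wave, burnin_per_dyad = 400) {
  ids <- attrs$node_id
  n <- length(ids)
  enc <- encode_terms(terms, attrs, ids)
  A0 <- matrix(0L, n, n)
  fd <- free_dyads(A0, "formation")  # all off-diagonal dyads
  s <- .cpp_sample(A0, fd$i, fd$j, as.numeric(theta), enc$type, enc$decay,
                   enc$attr, as.integer(burnin_per_dyad * n * (n - 1)), 1L, 1L,
                   TRUE)
  network_from_adjacency(s$networks[[1]], ids, wave)
}

#' Generate a baseline (T0) classroom network
#'
#' Long-run Metropolis draw from the configured exponential-family model
#' (default: edges + sex match + gwesp), so homophily and transitivity
#' ground truths are known exactly.
#'
#' @param attrs attribute table from [generate_attributes()].
#' @param cfg a [classroom_config()].
#' @return a `directed_network` labelled T0.
#' @export
generate_t0_network <- function(attrs, cfg = classroom_config()) {
  draw_network(attrs, cfg$t0_terms, cfg$t0_theta, "T0", cfg$burnin_per_dyad)
}

#' Generate a follow-up (T1) network from the separable transition model
#'
#' Draws a formation network and a dissolution network from the configured
#' models (via [simulate_transition()]) and recombines them with
#' [reconstruct_t1()]. In the limits: dissolution coefficients -> +Inf keep
#' every baseline tie; formation coefficients -> -Inf add none.
#'
#' @param net_t0 baseline `directed_network`.
#' @param attrs attribute table.
#' @param cfg a [classroom_config()].
#' @return a `directed_network` labelled T1.
#' @export
generate_transition <- function(net_t0, attrs, cfg = classroom_config()) {
  ctrl <- stergm_control(burnin = cfg$burnin_per_dyad * length(net_t0$node_ids)^2,
                         interval = 1, samplesize = 1)
  yp <- simulate_transition(net_t0, "formation", cfg$form_theta, cfg$form_terms,
                            attrs, control = ctrl)
  ym <- simulate_transition(net_t0, "dissolution", cfg$diss_theta, cfg$diss_terms,
                            attrs, control = ctrl)
  reconstruct_t1(net_t0, yp, ym)
}

#' Generate one synthetic classroom panel with ground truth
#'
#' @param cfg a [classroom_config()].
#' @param classroom_id classroom label.
#' @param seed optional integer seed (otherwise the current RNG state is used).
#' @return list with `panel` (a `network_panel`) and `truth` (the generating
#'   parameter values, including the planted intervention effect).
#' @export
generate_panel <- function(cfg = classroom_config(), classroom_id = "classroom",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  attrs <- generate_attributes(cfg, prefix = "c")
  t0 <- generate_t0_network(attrs, cfg)
  t1 <- generate_transition(t0, attrs, cfg)
  if (cfg$added_degree > 0) {
    n <- cfg$n_nodes
    A1 <- as_adjacency(t1)
    open <- which(A1 == 0L & diag(n) == 0L)
    k <- min(round(cfg$added_degree * n / 2), length(open))
    if (k > 0) {
      A1[sample(open, k)] <- 1L
      t1 <- network_from_adjacency(A1, t1$node_ids %||% attrs$node_id, "T1")
    }
  }
  panel <- network_panel(t0, t1, attrs, classroom_id)
  truth <- list(classroom_id = classroom_id, group = cfg$group,
                n_nodes = cfg$n_nodes,
                t0_terms = cfg$t0_terms, t0_theta = cfg$t0_theta,
                form_terms = cfg$form_terms, form_theta = cfg$form_theta,
                diss_terms = cfg$diss_terms, diss_theta = cfg$diss_theta,
                added_degree = cfg$added_degree)
  list(panel = panel, truth = truth)
}

#' Configuration of a synthetic multi-classroom study
#'
#' The default layout mirrors the study design the pipeline targets: seven
#' classrooms of 16-19 children (125 in total) randomized as two MARA+SMS,
#' two MARA, and three control classrooms, with planted mean-degree
#' intervention effects of 0.5 (MARA) and 4.3 (MARA+SMS) so that the
#' MARA+SMS-vs-MARA contrast carries a 3.8-friendship effect.
#'
#' @param sizes classroom sizes.
#' @param groups group label per classroom.
#' @param added_degree named vector of planted mean-degree effects per group.
#' @param classroom template [classroom_config()] supplying all remaining
#'   parameters.
#' @return a `study_config` list.
#' @export
study_config <- function(sizes = c(19, 17, 18, 19, 16, 18, 18),
                         groups = c("MARA_SMS", "MARA_SMS", "MARA", "MARA",
                                    "CONTROL", "CONTROL", "CONTROL"),
                         added_degree = c(MARA_SMS = 4.3, MARA = 0.5,
                                          CONTROL = 0),
                         classroom = classroom_config()) {
  stopifnot(length(sizes) == length(groups),
            all(groups %in% c("MARA_SMS", "MARA", "CONTROL")),
            all(groups %in% names(added_degree) | added_degree[groups] >= 0))
  structure(list(sizes = sizes, groups = groups, added_degree = added_degree,
                 classroom = classroom),
            class = "study_config")
}

#' Generate a synthetic multi-classroom study
#'
#' @param cfg a [study_config()].
#' @param seed integer seed; mandatory for a reproducible study.
#' @return a `classnet_study`: list with `panels` (named list of
#'   `network_panel`) and `truth` (per-classroom generating parameters plus
#'   the study layout).
#' @export
generate_study <- function(cfg = study_config(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  panels <- list()
  truths <- list()
  for (k in seq_along(cfg$sizes)) {
    id <- sprintf("network%d", k)
    ccfg <- cfg$classroom
    ccfg$n_nodes <- cfg$sizes[k]
    ccfg$group <- cfg$groups[k]
    ccfg$added_degree <- unname(cfg$added_degree[[cfg$groups[k]]])
    gp <- generate_panel(ccfg, classroom_id = id)
    panels[[id]] <- gp$panel
    truths[[id]] <- gp$truth
  }
  structure(list(panels = panels,
                 truth = list(seed = seed, sizes = cfg$sizes,
                              groups = cfg$groups,
                              added_degree = as.list(cfg$added_degree),
                              classrooms = truths)),
            class = "classnet_study")
}

#' @export
print.classnet_study <- function(x, ...) {
  cat(sprintf("synthetic study: %d classrooms (%s), %d children\n",
              length(x$panels),
              paste(x$truth$groups, collapse = ", "),
              sum(x$truth$sizes)))
  invisible(x)
}

#' Write a synthetic study to CSV + JSON files
#'
#' Writes per-classroom edge-list and attribute CSVs (readable by
#' [read_panel()]) and a `ground_truth.json` file.
#'
#' @param study a `classnet_study`.
#' @param dir output directory (created if absent).
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "classnet_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(study$panels))
    write_panel(study$panels[[id]],
                file.path(dir, paste0(id, "_edges.csv")),
                file.path(dir, paste0(id, "_attrs.csv")))
  jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a study written by [write_study()]
#'
#' @param dir directory containing the study files.
#' @return a `classnet_study`.
#' @export
read_study <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  ids <- sprintf("network%d", seq_along(truth$sizes))
  panels <- lapply(ids, function(id)
    read_panel(file.path(dir, paste0(id, "_edges.csv")),
               file.path(dir, paste0(id, "_attrs.csv")), id))
  names(panels) <- ids
  structure(list(panels = panels, truth = truth), class = "classnet_study")
}
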