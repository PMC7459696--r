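test_that("attribute generation respects envelopes, determinism, and group structure", {
  cfg <- classroom_config(n_nodes = 125, group = "MARA_SMS")
  set.seed(421)
  at <- generate_attributes(cfg)
  expect_equal(nrow(at), 125)
  expect_true(all(at$age >= 9 & at$age <= 13))
  expect_true(all(at$bmi >= 13.3 & at$bmi <= 27.75))
  expect_true(all(at$mvpa >= 19.92 & at$mvpa <= 143.9))
  expect_true(all(at$sex %in% c("F", "M")))
  expect_equal(at$meets_pa_guideline, as.integer(at$mvpa >= 60))
  expect_true(all(c("participation", "enjoying_time", "do_pa",
                    "recreation_safety", "healthy_experience") %in% names(at)))

  # control group: satisfaction columns absent
  set.seed(421)
  atc <- generate_attributes(classroom_config(n_nodes = 20, group = "CONTROL"))
  expect_false(any(c("participation", "enjoying_time") %in% names(atc)))

  # same seed twice -> identical tables
  set.seed(7); a1 <- generate_attributes(cfg)
  set.seed(7); a2 <- generate_attributes(cfg)
  expect_identical(a1, a2)

  expect_error(classroom_config(age_range = c(13, 9)), "impossible envelope")
})

test_that("baseline generator responds to its edges and homophily truths", {
  set.seed(422)
  # edges-only config: density matches logistic(beta) within binomial bounds
  beta <- -1.5
  cfg <- classroom_config(n_nodes = 16, t0_terms = "edges", t0_theta = beta)
  dens <- replicate(60, {
    at <- generate_attributes(cfg)
    net <- generate_t0_network(at, cfg)
    nrow(net$edges) / (16 * 15)
  })
  p_true <- plogis(beta)
  se <- sqrt(p_true * (1 - p_true) / (60 * 16 * 15))
  expect_lt(abs(mean(dens) - p_true), 5 * se)

  # zero homophily -> same-sex tie fraction at chance level
  cfg0 <- classroom_config(n_nodes = 16,
                           t0_terms = c("edges", "nodematch(sex)"),
                           t0_theta = c(-1.5, 0))
  frac <- replicate(60, {
    at <- generate_attributes(cfg0)
    net <- generate_t0_network(at, cfg0)
    if (nrow(net$edges) == 0) return(NA)
    v <- at$sex[match(net$edges[, 1], at$node_id)] ==
         at$sex[match(net$edges[, 2], at$node_id)]
    A <- as_adjacency(net)
    same <- outer(at$sex, at$sex, "==")
    mean(v) - mean(same[row(same) != col(same)])  # observed minus chance
  })
  expect_lt(abs(mean(frac, na.rm = TRUE)), 0.03)
})

test_that("transition limits behave as the persistence/formation extremes", {
  set.seed(423)
  cfg <- classroom_config(n_nodes = 12)
  at <- generate_attributes(cfg)
  t0 <- generate_t0_network(at, cfg)

  cfg_keep <- cfg; cfg_keep$diss_theta <- 30   # no ties dissolve
  t1k <- generate_transition(t0, at, cfg_keep)
  tc <- turnover_counts(network_panel(t0, t1k, at))
  expect_equal(tc$e10, 0)

  cfg_none <- cfg; cfg_none$form_theta <- c(-30, 0)  # no ties form
  t1n <- generate_transition(t0, at, cfg_none)
  tcn <- turnover_counts(network_panel(t0, t1n, at))
  expect_equal(tcn$e01, 0)
})

test_that("default panels land the Jaccard index in the meaningful band", {
  set.seed(424)
  js <- replicate(40, jaccard(generate_panel(classroom_config(n_nodes = 18))$panel)$j)
  expect_gte(median(js), 0.3)
  expect_lte(median(js), 0.6)
})

test_that("generated panels satisfy the core network invariants", {
  set.seed(425)
  for (r in 1:10) {
    gp <- generate_panel(classroom_config(n_nodes = sample(11:25, 1)))
    p <- gp$panel
    expect_identical(p$t0$node_ids, p$t1$node_ids)
    for (net in list(p$t0, p$t1)) {
      expect_false(any(net$edges[, 1] == net$edges[, 2]))
      m <- node_metrics(net)
      expect_equal(sum(m$in_degree), nrow(net$edges))
      expect_equal(sum(m$out_degree), nrow(net$edges))
    }
  }
})

test_that("study generation matches the 2/2/3 layout and round-trips through files", {
  study <- generate_study(seed = 426)
  expect_length(study$panels, 7)
  groups <- vapply(study$panels, function(p) as.character(p$attrs$group[1]),
                   character(1))
  expect_equal(unname(table(groups)[c("MARA_SMS", "MARA", "CONTROL")]),
               c(2L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(sum(vapply(study$panels, function(p) length(p$t0$node_ids), 1)), 125)

  # determinism under seed
  study2 <- generate_study(seed = 426)
  expect_identical(classnet:::edge_keys(study$panels[[1]]$t1),
                   classnet:::edge_keys(study2$panels[[1]]$t1))

  # serialization round trip, ground truth included
  dir <- tempfile()
  write_study(study, dir)
  suppressWarnings(back <- read_study(dir))
  expect_equal(back$truth$groups, study$truth$groups)
  expect_equal(back$truth$classrooms$network1$form_theta,
               study$truth$classrooms$network1$form_theta)
  for (id in names(study$panels)) {
    expect_setequal(classnet:::edge_keys(back$panels[[id]]$t0),
                    classnet:::edge_keys(study$panels[[id]]$t0))
    expect_equal(back$panels[[id]]$attrs$sex, study$panels[[id]]$attrs$sex)
  }
})

test_that("the planted mean-degree effect raises T1 degree by its nominal size", {
  n <- 20
  cfg0 <- classroom_config(n_nodes = n, added_degree = 0)
  cfg1 <- classroom_config(n_nodes = n, added_degree = 3.8)
  for (s in 428:430) {
    # identical seed: the two draws share every tie except the planted ones
    g0 <- generate_panel(cfg0, seed = s)
    g1 <- generate_panel(cfg1, seed = s)
    d_eff <- mean(node_metrics(g1$panel$t1)$degree) -
      mean(node_metrics(g0$panel$t1)$degree)
    expect_equal(d_eff, 3.8, tolerance = 1e-10)
  }
})
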