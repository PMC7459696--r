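test_that("decomposition builds union/intersection networks with the right invariants", {
  ids <- c("A", "B", "C")
  t0 <- directed_network(ids, rbind(c("A", "B")), "T0")
  t1 <- directed_network(ids, rbind(c("A", "B"), c("B", "C")), "T1")
  d <- stergm_decompose(network_panel(t0, t1))
  expect_setequal(classnet:::edge_keys(d$formation), c("A\rB", "B\rC"))
  expect_setequal(classnet:::edge_keys(d$dissolution), "A\rB")

  same <- network_panel(t0, directed_network(ids, t0$edges, "T1"))
  ds <- stergm_decompose(same)
  expect_setequal(classnet:::edge_keys(ds$formation), classnet:::edge_keys(t0))
  expect_setequal(classnet:::edge_keys(ds$dissolution), classnet:::edge_keys(t0))

  disj <- network_panel(t0, directed_network(ids, rbind(c("C", "A")), "T1"))
  expect_equal(nrow(stergm_decompose(disj)$dissolution$edges), 0)
})

test_that("reconstruct_t1 inverts the decomposition and enforces containment", {
  set.seed(409)
  for (r in 1:100) {
    p <- rand_panel(sample(3:10, 1), runif(1, 0.1, 0.5), runif(1, 0.1, 0.5))
    d <- stergm_decompose(p)
    t1 <- reconstruct_t1(d$base, d$formation, d$dissolution)
    expect_setequal(classnet:::edge_keys(t1), classnet:::edge_keys(p$t1))
  }
  # y_plus = y_minus = y0 returns y0
  ids <- c("A", "B", "C")
  y0 <- directed_network(ids, rbind(c("A", "B"), c("B", "C")), "T0")
  y0_t1 <- directed_network(ids, y0$edges, "T1")
  expect_setequal(classnet:::edge_keys(reconstruct_t1(y0, y0_t1, y0_t1)),
                  classnet:::edge_keys(y0))
  # invariant violations raise decomposition errors
  yp_bad <- directed_network(ids, rbind(c("B", "C")), "T1")  # missing baseline tie
  expect_error(reconstruct_t1(y0, yp_bad, y0_t1), "decomposition error")
  ym_bad <- directed_network(ids, rbind(c("C", "A")), "T1")  # not a baseline tie
  expect_error(reconstruct_t1(y0, y0_t1, ym_bad), "decomposition error")
})

test_that("change statistics match the enumeration oracle, incl. the decay-0 limit", {
  set.seed(410)
  attrs4 <- data.frame(node_id = sprintf("n%d", 1:5), sex = c("F", "F", "M", "M", "F"),
                       mvpa = c(30, 50, 45, 70, 55))
  for (r in 1:60) {
    n <- sample(3:5, 1)
    net <- rand_digraph(n, runif(1, 0.2, 0.7), attrs4$node_id[1:n])
    for (tau in c(0, 0.25, 0.5)) {
      g <- network_stats(net, c("edges", sprintf("gwidegree(%g)", tau),
                                sprintf("gwesp(%g)", tau),
                                "nodematch(sex)", "absdiff(mvpa)"), attrs4)
      o <- oracle_stats(net, tau, attrs4, match_attr = "sex", diff_attr = "mvpa")
      expect_equal(unname(g), unname(o[c("edges", "gwidegree", "gwesp",
                                         "nodematch", "absdiff")]),
                   tolerance = 1e-10)
    }
    # tau = 0: gwesp counts ties with at least one shared partner
    g0 <- network_stats(net, "gwesp(0)")
    A <- as_adjacency(net)
    ties <- which(A == 1, arr.ind = TRUE)
    nsp <- if (nrow(ties)) sum(vapply(seq_len(nrow(ties)), function(k)
      any(A[ties[k, 1], ] == 1 & A[, ties[k, 2]] == 1), logical(1))) else 0
    expect_equal(unname(g0), nsp)
  }
  # empty tie set -> all statistics zero
  empty <- directed_network(attrs4$node_id, NULL, "T0")
  expect_equal(unname(network_stats(empty, c("edges", "gwidegree(0.25)",
                                             "gwesp(0.25)", "absdiff(mvpa)"),
                                    attrs4)),
               rep(0, 4))
  # absdiff on a single tie
  one <- directed_network(attrs4$node_id, rbind(c("n1", "n2")), "T0")
  expect_equal(unname(network_stats(one, "absdiff(mvpa)", attrs4)), 20)
  # missing attribute values are rejected with the node named
  attrs_na <- attrs4; attrs_na$mvpa[2] <- NA
  expect_error(network_stats(one, "absdiff(mvpa)", attrs_na), "n2")
})

test_that("gwesp/gwidegree are monotone non-decreasing under tie addition", {
  set.seed(411)
  for (r in 1:30) {
    n <- 6
    ids <- sprintf("n%d", 1:n)
    net <- rand_digraph(n, 0.3, ids)
    A <- as_adjacency(net)
    open <- which(A == 0 & diag(n) == 0, arr.ind = TRUE)
    if (nrow(open) == 0) next
    pick <- open[sample(nrow(open), 1), ]
    A2 <- A; A2[pick[1], pick[2]] <- 1L
    net2 <- classnet:::network_from_adjacency(A2, ids, "T0")
    for (tm in c("gwesp(0.25)", "gwidegree(0.5)")) {
      expect_gte(unname(network_stats(net2, tm)), unname(network_stats(net, tm)))
    }
  }
})

test_that("the transition sampler respects its constrained space", {
  set.seed(412)
  base <- rand_digraph(8, 0.35)
  k0 <- classnet:::edge_keys(base)
  draws_f <- simulate_transition(base, "formation", theta = 0.2, terms = "edges",
                                 nsim = 20, control = stergm_control(burnin = 500,
                                                                     interval = 20))
  for (d in draws_f) expect_length(setdiff(k0, classnet:::edge_keys(d)), 0)
  draws_d <- simulate_transition(base, "dissolution", theta = -0.2, terms = "edges",
                                 nsim = 20, control = stergm_control(burnin = 500,
                                                                     interval = 20))
  for (d in draws_d) expect_length(setdiff(classnet:::edge_keys(d), k0), 0)

  # formation from a complete graph has no free dyads
  ids <- c("A", "B", "C")
  all_d <- subset(expand.grid(from = ids, to = ids), from != to)
  full <- directed_network(ids, as.matrix(all_d), "T0")
  expect_warning(out <- simulate_transition(full, "formation", 0, "edges"),
                 "degenerate")
  expect_setequal(classnet:::edge_keys(out), classnet:::edge_keys(full))
})

test_that("at theta = 0 the sampler is uniform over the constrained space", {
  set.seed(413)
  ids <- c("A", "B", "C")
  base <- directed_network(ids, NULL, "T0")   # formation space = all 2^6 digraphs
  draws <- simulate_transition(base, "formation", theta = 0, terms = "edges",
                               nsim = 10000,
                               control = stergm_control(burnin = 200, interval = 25))
  code <- vapply(draws, function(d) {
    A <- as_adjacency(d)
    sum(A[row(A) != col(A)] * 2^(seq_len(6) - 1))
  }, numeric(1))
  tab <- tabulate(code + 1, nbins = 64)
  chi <- sum((tab - 10000 / 64)^2 / (10000 / 64))
  expect_gt(pchisq(chi, df = 63, lower.tail = FALSE), 0.001)
})

test_that("edges-only sampling matches the closed-form Bernoulli reference", {
  set.seed(414)
  base <- rand_digraph(7, 0.3)
  beta <- -0.7
  p_tie <- exp(beta) / (1 + exp(beta))
  out <- simulate_transition(base, "formation", beta, "edges", nsim = 400,
                             control = stergm_control(burnin = 2000, interval = 50),
                             return_stats = TRUE)
  n_free <- sum(as_adjacency(base) == 0) - 7
  added <- out$stats[, "edges"] - nrow(base$edges)
  phat <- mean(added) / n_free
  se <- sqrt(p_tie * (1 - p_tie) / (400 * n_free))  # upper bound ignoring autocorr.
  expect_lt(abs(phat - p_tie), 6 * se)
})

test_that("edges-only conditional MLE hits the closed form; dissolution signs read as persistence", {
  set.seed(415)
  p <- rand_panel(12, 0.3, 0.3)
  d <- stergm_decompose(p)
  f <- stergm(p, formation = "edges", dissolution = "edges")
  A0 <- as_adjacency(p$t0)
  n_addable <- sum(A0 == 0) - 12
  n_added <- nrow(d$formation$edges) - nrow(p$t0$edges)
  expect_equal(f$formation$estimate, qlogis(n_added / n_addable), tolerance = 1e-6)
  n_kept <- nrow(d$dissolution$edges)
  expect_equal(f$dissolution$estimate, qlogis(n_kept / nrow(p$t0$edges)),
               tolerance = 1e-6)
  expect_equal(unname(f$method), c("cmle_logistic", "cmle_logistic"))
})

test_that("exact enumeration and MCMC agree with each other on a small instance", {
  set.seed(416)
  ids <- sprintf("n%02d", 1:5)
  attrs <- data.frame(node_id = ids, mvpa = c(30, 60, 45, 80, 50))
  repeat {  # need a non-boundary transition
    p <- rand_panel(5, 0.4, 0.45)
    p <- network_panel(p$t0, p$t1, attrs, "small")
    d <- stergm_decompose(p)
    n_added <- nrow(d$formation$edges) - nrow(p$t0$edges)
    n_kept <- nrow(d$dissolution$edges)
    n_free_f <- 20 - nrow(p$t0$edges)
    if (n_added > 1 && n_added < n_free_f - 1 && n_kept > 1 &&
        n_kept < nrow(p$t0$edges) - 1) break
  }
  fe <- stergm(p, c("edges", "gwesp(0.25)"), c("edges"),
               control = stergm_control(method = "exact"))
  fm <- stergm(p, c("edges", "gwesp(0.25)"), c("edges"),
               control = stergm_control(method = "mcmc", samplesize = 8000,
                                        ztol = 0.02, maxit = 60), seed = 3)
  expect_lt(max(abs(fe$formation$estimate - fm$formation$estimate)), 0.05)
  expect_lt(max(abs(fe$dissolution$estimate - fm$dissolution$estimate)), 0.05)
})

test_that("boundary transitions raise structured degeneracy errors", {
  ids <- sprintf("n%d", 1:6)
  set.seed(417)
  t0 <- rand_digraph(6, 0.4, ids)
  t1_same <- directed_network(ids, t0$edges, "T1")  # nothing dissolves, nothing forms
  p <- network_panel(t0, t1_same, data.frame(node_id = ids), "b")
  expect_error(stergm(p, "edges", "edges"), class = "classnet_degeneracy")
})

test_that("interpretation strings follow the formation/dissolution sign rules", {
  mk_fit <- function(est_f, p_f, est_d, p_d) {
    tab <- function(e, p) data.frame(term = "edges", estimate = e, se = 1,
                                     ci_lo = e - 1.6, ci_hi = e + 1.6, z = e,
                                     p_value = p, significant = p < 0.1)
    structure(list(formation = tab(est_f, p_f), dissolution = tab(est_d, p_d),
                   conf = 0.9), class = "stergm_fit")
  }
  i1 <- interpret_stergm(mk_fit(1.2, 0.01, -0.8, 0.05))
  expect_match(i1$interpretation[i1$side == "formation"], "forming ties")
  expect_match(i1$interpretation[i1$side == "dissolution"], "dissolving ties")
  i2 <- interpret_stergm(mk_fit(-1.2, 0.02, 0.8, 0.03))
  expect_match(i2$interpretation[i2$side == "formation"],
               "decrease in the probability of forming")
  expect_match(i2$interpretation[i2$side == "dissolution"], "preserving ties")
  i3 <- interpret_stergm(mk_fit(1.2, 0.5, 0.8, 0.2))
  expect_true(all(grepl("not significant", i3$interpretation)))
})
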