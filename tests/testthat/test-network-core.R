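test_that("network construction enforces sociometric invariants", {
  net <- directed_network(c("A", "B"), rbind(c("A", "B"), c("B", "A"), c("A", "B")), "T0")
  expect_equal(nrow(net$edges), 2)  # duplicate nominations collapse

  expect_error(directed_network(c("A", "B"), rbind(c("A", "A")), "T0"), "self-tie")
  expect_error(directed_network(c("A", "B"), rbind(c("A", "C")), "T0"), "not in node_ids")
  expect_error(directed_network(c("A", "A"), NULL, "T0"), "duplicated")
  expect_error(directed_network(c("A", "B"), NULL, "T2"), "wave")
})

test_that("panels require matched waves and an identical node set", {
  t0 <- directed_network(c("A", "B"), rbind(c("A", "B")), "T0")
  t1 <- directed_network(c("A", "B"), NULL, "T1")
  p <- network_panel(t0, t1, data.frame(node_id = c("A", "B")), "c1")
  expect_s3_class(p, "network_panel")

  t1_extra <- directed_network(c("A", "B", "C"), NULL, "T1")
  expect_error(network_panel(t0, t1_extra), "identical node set")
  expect_error(network_panel(t0, t1, data.frame(node_id = c("A", "B", "Z"))),
               "attribute row without matching")
  expect_error(network_panel(t1, t0), "T0 and T1")
})

test_that("read_panel round-trips CSVs, drops off-roster ties, rejects bad input", {
  ed <- data.frame(source = c("A", "B", "A", "C"), target = c("B", "A", "B", "A"),
                   wave = c("T0", "T0", "T1", "T1"))
  at <- data.frame(node_id = c("A", "B"), sex = c("F", "M"))
  ef <- tempfile(fileext = ".csv"); af <- tempfile(fileext = ".csv")
  write.csv(ed, ef, row.names = FALSE); write.csv(at, af, row.names = FALSE)

  expect_warning(p <- read_panel(ef, af, "c1"), "not on both-wave roster")
  expect_equal(sort(p$t0$node_ids), c("A", "B"))
  expect_equal(nrow(p$t0$edges), 2)
  expect_equal(nrow(p$t1$edges), 1)   # C's tie dropped

  # self-tie and unknown wave labels are rejected
  write.csv(data.frame(source = "A", target = "A", wave = "T0"), ef, row.names = FALSE)
  expect_error(read_panel(ef, af), "self-tie")
  write.csv(data.frame(source = "A", target = "B", wave = "T9"), ef, row.names = FALSE)
  expect_error(read_panel(ef, af), "wave label")

  # write_panel / read_panel identity
  p2 <- fixture_panel()
  write_panel(p2, ef, af)
  p3 <- read_panel(ef, af, "fixture")
  expect_setequal(classnet:::edge_keys(p3$t0), classnet:::edge_keys(p2$t0))
  expect_setequal(classnet:::edge_keys(p3$t1), classnet:::edge_keys(p2$t1))
})

test_that("node metrics match hand counts on canonical fixtures", {
  ids <- c("A", "B", "C")
  tri <- directed_network(ids, rbind(c("A", "B"), c("B", "C"), c("A", "C")), "T0")
  m <- node_metrics(tri)
  expect_equal(m$out_degree[m$node_id == "A"], 2)
  expect_equal(m$in_degree[m$node_id == "C"], 2)
  expect_equal(m$degree[m$node_id == "B"], 2)
  expect_equal(m$clustering, rep(1, 3))  # undirected reduction closes the triangle

  star <- directed_network(ids, rbind(c("A", "B"), c("A", "C")), "T0")
  expect_equal(node_metrics(star)$clustering[1], 0)

  empty <- directed_network(sprintf("n%d", 1:5), NULL, "T0")
  s <- network_summary(empty)
  expect_equal(s$avg_degree, 0)
  expect_equal(s$avg_clustering, 0)

  # complete mutual digraph on 4 nodes
  ids4 <- c("A", "B", "C", "D")
  all_dyads <- subset(expand.grid(from = ids4, to = ids4), from != to)
  full <- directed_network(ids4, as.matrix(all_dyads), "T0")
  sf <- network_summary(full)
  expect_equal(sf$avg_degree, 6)
  expect_equal(sf$avg_clustering, 1)
})

test_that("metrics agree with the BFS/triple-enumeration oracle on random digraphs", {
  set.seed(401)
  for (r in 1:40) {
    n <- sample(2:10, 1)
    net <- rand_digraph(n, runif(1, 0.1, 0.6))
    expect_equal(node_metrics(net), oracle_metrics(net), tolerance = 1e-12)
    s <- network_summary(net)
    om <- oracle_metrics(net)
    expect_equal(s$avg_degree, mean(om$degree))
    expect_equal(s$avg_clustering, mean(om$clustering))
  }
})

test_that("handshake identity and relabeling invariance hold", {
  set.seed(402)
  for (r in 1:20) {
    net <- rand_digraph(sample(3:12, 1), runif(1, 0.1, 0.5))
    m <- node_metrics(net)
    expect_equal(sum(m$in_degree), nrow(net$edges))
    expect_equal(sum(m$out_degree), nrow(net$edges))
    expect_true(all(m$clustering >= 0 & m$clustering <= 1))
    expect_true(all(m$closeness >= 0))

    # relabel nodes: metrics follow the labels
    perm <- sample(net$node_ids)
    map <- setNames(perm, net$node_ids)
    net2 <- directed_network(perm, cbind(map[net$edges[, 1]], map[net$edges[, 2]]),
                             net$wave)
    m2 <- node_metrics(net2)
    m2 <- m2[match(map[m$node_id], m2$node_id), ]
    expect_equal(m$degree, m2$degree)
    expect_equal(m$clustering, m2$clustering)
    expect_equal(m$closeness, m2$closeness)
  }
})

test_that("harmonic closeness alternative is computed and bounded", {
  net <- directed_network(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")), "T0")
  h <- node_metrics(net, closeness = "harmonic")$closeness
  expect_equal(h, c((1 + 1 / 2) / 2, 1 / 2, 0))
})

test_that("GraphML export round-trips adjacency and attributes", {
  p <- fixture_panel()
  f <- tempfile(fileext = ".graphml")
  write_graphml(p$t0, p$attrs, f)
  back <- read_graphml(f, "T0")
  expect_setequal(classnet:::edge_keys(back$net), classnet:::edge_keys(p$t0))
  expect_setequal(back$net$node_ids, p$t0$node_ids)
  expect_equal(back$attrs$sex[match(p$attrs$node_id, back$attrs$node_id)],
               p$attrs$sex)

  # empty network -> valid, parseable GraphML (independent reader: xml2)
  empty <- directed_network(c("A", "B"), NULL, "T0")
  write_graphml(empty, NULL, f)
  doc <- xml2::read_xml(f)
  expect_equal(xml2::xml_name(doc), "graphml")
  expect_equal(nrow(read_graphml(f)$net$edges), 0)
})
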