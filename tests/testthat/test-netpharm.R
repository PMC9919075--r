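test_that("target intersection matches element-wise membership", {
  ts <- intersect_targets(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ts$intersection, c("B", "C"))
  expect_equal(unname(ts$venn), c(1, 1, 2))

  expect_equal(intersect_targets(c("x"), c("y"))$intersection, character())
  expect_warning(intersect_targets(character(), c("a")), "empty")

  # identifiers are normalized before intersecting
  ts2 <- intersect_targets(c(" src ", "MAPK1"), c("SRC", "mapk1 "))
  expect_equal(ts2$intersection, c("MAPK1", "SRC"))

  set.seed(20)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    ts3 <- intersect_targets(a, b)
    brute <- sort(toupper(a[vapply(a, function(x) x %in% b, logical(1))]))
    expect_equal(ts3$intersection, brute)
  }
})

test_that("graph statistics match hand-computable cases", {
  tri <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
  st <- graph_stats(tri)
  expect_equal(st$n_nodes, 3)
  expect_equal(st$n_edges, 3)
  expect_equal(st$average_degree, 2.0)

  set.seed(7)
  g <- igraph::sample_gnm(50, 120)
  igraph::V(g)$name <- sprintf("n%02d", 1:50)
  el <- as.data.frame(igraph::as_edgelist(g))
  st2 <- graph_stats(el)
  expect_equal(sum(st2$degree), 2 * st2$n_edges)    # handshake lemma
  st3 <- graph_stats(el[sample(nrow(el)), 2:1])     # edge order + direction
  expect_equal(st3$degree[names(st2$degree)], st2$degree)

  expect_error(graph_stats(data.frame(from = "a", to = "a")), "self-loops")
  expect_warning(graph_stats(data.frame(from = c("a", "b"), to = c("b", "a"))),
                 "duplicate")
})

test_that("degree ranking is deterministic with lexicographic ties", {
  star <- data.frame(from = "hub", to = sprintf("leaf%d", 1:5))
  expect_equal(top_degree(star, 1), "hub")
  # two tied pairs: ties at the cut resolved by node name
  el <- data.frame(from = c("b", "d", "a"), to = c("c", "e", "b"))
  st <- graph_stats(el)
  ord <- order(-st$degree, names(st$degree))         # re-sort oracle
  expect_equal(top_degree(el, 3), names(st$degree)[ord][1:3])
  expect_setequal(top_degree(el, 5), names(st$degree))
  expect_warning(full <- top_degree(el, 10), "exceeds")
  expect_length(full, 5)
})

test_that("hypergeometric tails equal complete enumeration", {
  # literal enumeration of every draw on a small instance: 4/120
  expect_equal(oracle_hyper_enum(10, 4, 3, 3), 4 / 120)
  enr <- hypergeom_enrich(letters[1:3], list(t = letters[1:4]), letters[1:10])
  expect_equal(enr$p, 4 / 120, tolerance = 1e-12)

  # exhaustive sweep over all configurations with universe <= 20
  for (N in c(5, 11, 20)) {
    for (K in 1:N) for (n in 1:N) {
      u <- sprintf("g%02d", 1:N)
      enr <- hypergeom_enrich(u[1:n], list(t = u[1:K]), u)
      k <- enr$k
      expect_equal(enr$p, oracle_hyper_tail(N, K, n, k), tolerance = 1e-12)
    }
  }

  # a term disjoint from the study carries no evidence
  u <- sprintf("g%02d", 1:20)
  enr0 <- hypergeom_enrich(u[1:5], list(t = u[10:13]), u)
  expect_equal(enr0$k, 0)
  expect_gte(enr0$p, 0.99)
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(9)
  for (i in 1:20) {
    u <- sprintf("g%03d", 1:200)
    terms <- lapply(1:15, function(j) sample(u, sample(5:50, 1)))
    names(terms) <- sprintf("T%02d", 1:15)
    enr <- hypergeom_enrich(sample(u, 30), terms, u)
    expect_true(all(enr$p_adj >= enr$p - 1e-15))
    expect_true(all(enr$p_adj <= 1))
    expect_true(all(diff(enr$p_adj) >= -1e-15))   # sorted by p: nondecreasing
    expect_equal(enr$p_adj, p.adjust(enr$p, "BH"), tolerance = 1e-15)
  }
  expect_error(hypergeom_enrich(c("zz"), list(), sprintf("g%d", 1:5)),
               "outside the universe")
})

test_that("a strongly planted term attains the smallest adjusted p", {
  hits <- 0L
  for (seed in 1:100) {
    td <- gen_target_data(seed = seed, universe_size = 300, n_terms = 12,
                          planted_term_size = 30, study_size = 40,
                          planted_overlap = 18, term_size_range = c(10, 40))
    enr <- hypergeom_enrich(td$study, td$terms, td$universe)
    if (enr$term[which.min(enr$p_adj)] == td$planted_term) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("an expectation-level overlap leaves the planted term unremarkable", {
  # planted overlap at E[k] = K n / N: the term should behave like a null
  top_decile <- 0L
  for (seed in 1:100) {
    td <- gen_target_data(seed = seed, universe_size = 300, n_terms = 20,
                          planted_term_size = 30, study_size = 40,
                          planted_overlap = 4, term_size_range = c(25, 35))
    enr <- hypergeom_enrich(td$study, td$terms, td$universe)
    if (which(enr$term == td$planted_term) <= 2) top_decile <- top_decile + 1L
  }
  expect_lte(top_decile, 30L)
})

test_that("the component-target-pathway-disease network assembles by the rules", {
  # single target, single pathway: a three-edge path
  net <- build_ctpd_network(
    component = "cmp", targets = "T1",
    pathway_annotations = list(pw1 = "T1"),
    enrichment = data.frame(term = "pw1", p = 0.001),
    degree_map = c(T1 = 5, T2 = 1),
    disease_map = list(pw1 = "disease1"))
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$type,
               c("component-target", "target-pathway", "pathway-disease"))

  # strict > mean(degree): no target passes when all degrees are equal
  net2 <- suppressWarnings(build_ctpd_network(
    "cmp", c("T1", "T2"), list(pw1 = c("T1", "T2")),
    data.frame(term = "pw1", p = 0.01),
    degree_map = c(T1 = 3, T2 = 3)))
  expect_false(any(net2$nodes$type == "target"))

  # 30 candidate pathways: exactly the top 20 by p are retained
  enr <- data.frame(term = sprintf("pw%02d", 1:30),
                    p = seq(0.001, 0.03, length.out = 30))
  ann <- setNames(rep(list("T1"), 30), enr$term)
  net3 <- build_ctpd_network("cmp", "T1", ann, enr,
                             degree_map = c(T1 = 9, T2 = 1))
  expect_equal(sum(net3$nodes$type == "pathway"), 20)
  expect_setequal(net3$nodes$id[net3$nodes$type == "pathway"],
                  sprintf("pw%02d", 1:20))

  # a selected target without annotation is kept, with a warning
  expect_warning(
    net4 <- build_ctpd_network("cmp", c("T1", "T9"),
                               list(pw1 = "T1"),
                               data.frame(term = "pw1", p = 0.01),
                               degree_map = c(T1 = 9, T9 = 9, T2 = 1)),
    "T9")
  expect_true("T9" %in% net4$nodes$id)
})

test_that("network-stage text formats round-trip", {
  dir <- withr::local_tempdir()
  el_path <- file.path(dir, "edges.tsv")
  writeLines(c("from\tto", "SRC\tMAPK1", "SRC\tAKT1"), el_path)
  el <- read_edge_list(el_path)
  expect_equal(graph_stats(el)$n_edges, 2)

  tm_path <- file.path(dir, "terms.tsv")
  writeLines(c("term\tmember", "pw1\tSRC", "pw1\tAKT1", "pw2\tMAPK1"),
             tm_path)
  tm <- read_term_map(tm_path)
  expect_equal(tm$pw1, c("SRC", "AKT1"))

  ts_path <- file.path(dir, "targets.txt")
  writeLines(c("# predicted", "SRC", "", "MAPK1"), ts_path)
  expect_equal(read_target_set(ts_path), c("SRC", "MAPK1"))

  net <- build_ctpd_network("cmp", "T1", list(pw1 = "T1"),
                            data.frame(term = "pw1", p = 0.001),
                            degree_map = c(T1 = 5, T2 = 1),
                            disease_map = list(pw1 = "d1"))
  sif <- file.path(dir, "net.sif")
  write_sif(net, sif)
  expect_equal(length(readLines(sif)), 3)
})
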