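# modularity conventions, multiplex objective, Louvain optimisation against
# exhaustive search, module filtering

test_that("modularity follows the doubled-adjacency convention", {
  tri2 <- two_triangles_layer()
  all_one <- stats::setNames(rep(1, 6), tri2$nodes)
  split2 <- stats::setNames(c(1, 1, 1, 2, 2, 2), tri2$nodes)
  expect_equal(modularity_score(tri2, all_one, gamma = 1), 0)
  expect_equal(modularity_score(tri2, split2, gamma = 1), 0.5)
  # gamma scales only the null term: per-triangle 6 - 2 * 36/12 = 0
  expect_equal(modularity_score(tri2, split2, gamma = 2), 0)

  # whole-graph single community scores 0 at gamma 1 on any graph, and the
  # score agrees with an independent implementation on random partitions
  set.seed(13)
  for (r in 1:6) {
    l <- random_layer(8, 0.4, seed = 100 + r)
    mem <- stats::setNames(sample(1:3, 8, replace = TRUE), l$nodes)
    expect_equal(modularity_score(l, stats::setNames(rep(1, 8), l$nodes), 1), 0)
    if (nrow(l$edges)) {
      g <- layer_igraph(l)
      for (gam in c(0.5, 1, 2)) {
        expect_equal(modularity_score(l, mem, gam),
                     igraph::modularity(g, mem[l$nodes], resolution = gam),
                     tolerance = 1e-12)
      }
    }
  }
  # empty layer is defined as 0
  empty <- new_layer(c("A", "B"), character(), character(), "e")
  expect_equal(modularity_score(empty, c(A = 1, B = 2)), 0)
})

test_that("multiplex modularity is the weighted sum of per-layer modularities", {
  tri2 <- two_triangles_layer()
  split2 <- stats::setNames(c(1, 1, 1, 2, 2, 2), tri2$nodes)
  net_same <- assemble_multiplex(tri2, new_layer(tri2$nodes, tri2$edges$from,
                                                 tri2$edges$to, "phenotype"))
  expect_equal(multiplex_modularity(net_same, split2, 1),
               modularity_score(tri2, split2, 1))

  other <- new_layer(tri2$nodes, c("a", "d"), c("e", "c"), "phenotype")
  net <- assemble_multiplex(tri2, other)
  h1 <- modularity_score(tri2, split2, 1)
  h2 <- modularity_score(net$layers$phenotype, split2, 1)
  expect_equal(multiplex_modularity(net, split2, 1), 0.5 * h1 + 0.5 * h2)
  expect_equal(multiplex_modularity(net, split2, 1, weights = c(1, 0)), h1)
})

test_that("Louvain recovers exhaustive-search optima on small graphs", {
  tri2 <- two_triangles_layer()
  p <- louvain_single(tri2, modularity_params(n_restarts = 50, seed = 1))
  expect_equal(p$quality, 0.5)
  expect_equal(unname(module_sizes(p)), c(3L, 3L))
  expect_equal(p$quality, brute_force_modularity(tri2, 1))
  # reported quality matches an independent re-evaluation
  expect_equal(p$quality, modularity_score(tri2, p$membership, 1),
               tolerance = 1e-9)

  # complete graph: no split scores above the single community
  k4 <- block_layer(4, "k4")
  pk <- louvain_single(k4, modularity_params(n_restarts = 20, seed = 1))
  expect_equal(pk$quality, 0)
  expect_equal(brute_force_modularity(k4, 1), 0)
  expect_equal(length(module_sizes(pk)), 1)

  # randomized sweep: restarted Louvain attains the exact optimum
  hits <- 0
  for (r in 1:8) {
    l <- random_layer(6, 0.45, seed = 300 + r)
    if (!nrow(l$edges)) next
    p <- louvain_single(l, modularity_params(n_restarts = 100, seed = r))
    if (abs(p$quality - brute_force_modularity(l, 1)) < 1e-9) hits <- hits + 1
    expect_equal(p$quality, modularity_score(l, p$membership, 1), tolerance = 1e-9)
  }
  expect_gte(hits, 7)
})

test_that("module numbering is stable: by size, then smallest member symbol", {
  # two triangles with controlled labels: both size 3, tie broken by symbol
  l <- new_layer(c("z1", "z2", "z3", "a1", "a2", "a3"),
                 c("z1", "z2", "z1", "a1", "a2", "a1"),
                 c("z2", "z3", "z3", "a2", "a3", "a3"), "t")
  p <- louvain_single(l, modularity_params(n_restarts = 20, seed = 1))
  expect_equal(sort(names(p$membership)[p$membership == 1]), c("a1", "a2", "a3"))
  expect_equal(unname(p$membership[c("z1", "z2", "z3")]), rep(2L, 3))
})

test_that("gene relabeling permutes the partition identically", {
  tri2 <- two_triangles_layer()
  p1 <- louvain_single(tri2, modularity_params(n_restarts = 20, seed = 1))
  relab <- c(a = "P", b = "Q", c = "R", d = "S", e = "T", f = "U")
  l2 <- new_layer(unname(relab[tri2$nodes]),
                  unname(relab[tri2$edges$from]), unname(relab[tri2$edges$to]), "t")
  p2 <- louvain_single(l2, modularity_params(n_restarts = 20, seed = 1))
  expect_equal(unname(p2$membership[relab[names(p1$membership)]]),
               unname(p1$membership))
})

test_that("module count is non-decreasing along the resolution sweep", {
  tri2 <- two_triangles_layer()
  p <- louvain_single(tri2, modularity_params(gamma = 1, n_restarts = 30,
                                              resolutions = c(0.25, 1, 2, 6),
                                              seed = 2))
  expect_equal(p$sweep$gamma, c(0.25, 1, 2, 6))
  expect_true(all(diff(p$sweep$n_modules) >= 0))
})

test_that("multiplex Louvain shares one partition and uses both layers", {
  tri2 <- two_triangles_layer()
  same <- assemble_multiplex(tri2, new_layer(tri2$nodes, tri2$edges$from,
                                             tri2$edges$to, "phenotype"))
  pm <- louvain_multiplex(same, modularity_params(n_restarts = 30, seed = 1))
  ps <- louvain_single(tri2, modularity_params(n_restarts = 30, seed = 1))
  expect_equal(pm$quality, ps$quality)
  expect_equal(pm$membership, ps$membership)

  # one empty layer with equal weights: the non-empty layer drives everything
  empty <- new_layer(tri2$nodes, character(), character(), "phenotype")
  pe <- louvain_multiplex(assemble_multiplex(tri2, empty),
                          modularity_params(n_restarts = 30, seed = 1))
  expect_equal(pe$membership, ps$membership)
  expect_equal(pe$quality, 0.5 * ps$quality)

  # a PPI-isolated gene connected to a block only in the phenotype layer is
  # pulled into that block's module
  nodes <- c("x", two_triangles_layer()$nodes)
  ppi <- new_layer(nodes, c("a", "b", "a", "d", "e", "d"),
                   c("b", "c", "c", "e", "f", "f"), "ppi")
  phen <- new_layer(nodes, c("x", "x", "d", "e", "d"),
                    c("d", "e", "e", "f", "f"), "phenotype")
  px <- louvain_multiplex(assemble_multiplex(ppi, phen),
                          modularity_params(n_restarts = 30, seed = 1))
  expect_equal(unname(px$membership["x"]), unname(px$membership[["d"]]))
})

test_that("module filtering orders, thresholds and truncates", {
  mem <- c(rep(1, 10), rep(2, 8), rep(3, 3), 4)
  genes <- sprintf("g%02d", seq_along(mem))
  part <- structure(list(membership = stats::setNames(mem, genes)),
                    class = "gp_partition")
  singles <- structure(list(membership = stats::setNames(1:4, letters[1:4])),
                       class = "gp_partition")
  expect_length(filter_modules(singles, min_size = 2), 0)
  f <- filter_modules(part, min_size = 2)
  expect_equal(unname(lengths(f)), c(10L, 8L, 3L))
  f2 <- filter_modules(part, min_size = 2, keep_top = 2)
  expect_equal(unname(lengths(f2)), c(10L, 8L))
})
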