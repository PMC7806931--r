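# betweenness conventions, centrality ranking, module matching, candidate
# rules, common-vs-specific centrality comparison

test_that("betweenness follows the endpoint conventions on canonical graphs", {
  path3 <- new_layer(c("a", "b", "c"), c("a", "b"), c("b", "c"), "p")
  b <- betweenness_centrality(path3, normalized = FALSE)
  expect_equal(unname(b["b"]), 2)  # ordered pairs (a,c) and (c,a)
  expect_equal(unname(b[c("a", "c")]), c(0, 0))

  star4 <- new_layer(c("h", "x", "y", "z"), c("h", "h", "h"),
                     c("x", "y", "z"), "s")
  expect_equal(unname(betweenness_centrality(star4, normalized = TRUE)["h"]), 1)

  two_edges <- new_layer(c("a", "b", "c", "d"), c("a", "c"), c("b", "d"), "e")
  expect_equal(unname(betweenness_centrality(two_edges, normalized = FALSE)),
               rep(0, 4))
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  set.seed(5)
  total_checked <- 0
  for (r in 1:10) {
    l <- random_layer(sample(5:7, 1), stats::runif(1, 0.25, 0.6), seed = 400 + r)
    raw <- betweenness_centrality(l, normalized = FALSE)
    oracle <- bf_betweenness_raw(l)
    expect_equal(raw, oracle, tolerance = 1e-12)
    # conservation: ordered-pair betweenness sums to sum over connected pairs
    # of (path length - 1)
    g <- layer_igraph(l)
    d <- igraph::distances(g)
    finite <- is.finite(d) & d > 0
    expect_equal(sum(raw), sum(d[finite] - 1), tolerance = 1e-12)
    total_checked <- total_checked + length(l$nodes)
  }
  expect_gt(total_checked, 0)
})

test_that("centrality table averages layers and ranks deterministically", {
  nodes <- c("CALM2", "KCNB1", "LONER")
  ppi <- new_layer(nodes, "CALM2", "KCNB1", "ppi")
  phen <- new_layer(nodes, "CALM2", "KCNB1", "phenotype")
  net <- assemble_multiplex(ppi, phen)
  ct <- centrality_table(net)
  expect_equal(ct$avg_degree[ct$gene == "CALM2"], 1)
  expect_equal(ct$gene[which.max(ct$rank_degree)], "LONER")  # isolated: last
  expect_equal(ct$avg_degree[ct$gene == "LONER"], 0)

  # the average degree is the arithmetic mean of per-layer degrees (e.g. the
  # 32/139 -> 85.5 pattern)
  expect_equal(mean(c(32, 139)), 85.5)
  fx <- planted_instance()
  ctf <- centrality_table(fx$net, universe = fx$bundle$universe)
  expect_equal(ctf$avg_degree, (ctf$ppi_degree + ctf$phen_degree) / 2)
  expect_equal(ctf$avg_bc, (ctf$ppi_bc + ctf$phen_bc) / 2)
  expect_false(is.unsorted(rev(ctf$avg_degree)))
  expect_true(all(nchar(ctf$annotation[ctf$gene %in% common_genes(fx$bundle$universe)]) > 0))
})

test_that("module matching reports shared genes and best fractions", {
  pa <- structure(list(membership = c(A = 1, B = 1, C = 2, D = 2, E = 3)),
                  class = "gp_partition")
  expect_true(all(match_modules(pa, pa)$frac_of_b_in_a[match_modules(pa, pa)$best] == 1))

  pb <- structure(list(membership = c(A = 1, B = 1, C = 1, Z = 2)),
                  class = "gp_partition")
  m <- match_modules(pa, pb)
  # module-b 1 has 3 genes in the a-universe: 2 fall in a-module 1
  r <- m[m$module_b == 1 & m$module_a == 1, ]
  expect_equal(r$shared, 2)
  expect_equal(r$frac_of_b_in_a, 2 / 3)
  expect_true(r$best)
  expect_equal(nrow(m[m$module_b == 2, ]), 0)  # Z unseen in pa

  pc <- structure(list(membership = c(X = 1, Y = 1)), class = "gp_partition")
  expect_equal(nrow(match_modules(pa, pc)), 0)  # disjoint universes
})

test_that("candidate rule returns exactly the disease-B-only overlap genes", {
  u <- data.frame(
    gene = sprintf("g%02d", 1:20),
    epilepsy_subgroup = c(rep("1", 10), rep("none", 4), rep("2", 6)),
    autism_subgroup = c(rep("1", 10), rep("2", 4), rep("none", 6)),
    stringsAsFactors = FALSE)
  class(u) <- c("gene_universe", "data.frame")
  overlap <- u$gene  # 10 common, 4 autism-only, 6 epilepsy-only
  expect_equal(candidate_genes(overlap, u, "epilepsy"), sprintf("g%02d", 11:14))
  expect_equal(candidate_genes(overlap, u, "autism"), sprintf("g%02d", 15:20))
  expect_equal(candidate_genes(u$gene[1:10], u, "epilepsy"), character(0))
  # candidates are always inside the overlap and never common genes
  cand <- candidate_genes(overlap, u, "epilepsy")
  expect_true(all(cand %in% overlap))
  expect_length(intersect(cand, common_genes(u)), 0)
})

test_that("secondary candidate rule follows genes into other prioritized modules", {
  u <- data.frame(
    gene = c("P1", "P2", "DLG4X", "C1"),
    epilepsy_subgroup = c("1", "1", "none", "1"),
    autism_subgroup = c("none", "none", "1", "1"),
    stringsAsFactors = FALSE)
  class(u) <- c("gene_universe", "data.frame")
  part <- structure(list(membership = c(P1 = 1, P2 = 1, DLG4X = 2, C1 = 1)),
                    class = "gp_partition")
  res <- secondary_candidates(c("P1", "DLG4X", "C1"), part,
                              prioritized_modules = 2, u, "epilepsy")
  expect_equal(res$gene, "DLG4X")
  expect_equal(res$large_module, 2L)
})

test_that("common genes with planted high degree are detected by the rank-sum test", {
  # flat fixture: all centralities equal -> no evidence
  nodes <- sprintf("n%02d", 1:10)
  flat <- block_layer(c(10), "ppi")
  flat2 <- new_layer(flat$nodes, flat$edges$from, flat$edges$to, "phenotype")
  net_flat <- assemble_multiplex(flat, flat2)
  u_flat <- data.frame(gene = flat$nodes,
                       epilepsy_subgroup = c(rep("1", 5), rep("none", 5)),
                       autism_subgroup = c(rep("1", 3), rep("none", 4), rep("2", 3)),
                       stringsAsFactors = FALSE)
  class(u_flat) <- c("gene_universe", "data.frame")
  res_flat <- common_gene_centrality_test(net_flat, u_flat)
  expect_gt(res_flat$p_value, 0.9)

  # hub fixture: the common genes are the high-degree block
  fx <- planted_instance()
  uni <- fx$bundle$universe
  ct <- centrality_table(fx$net)
  topg <- ct$gene[1:20]
  u2 <- uni
  u2$epilepsy_subgroup <- ifelse(uni$gene %in% topg, "1",
                                 ifelse(seq_len(nrow(uni)) %% 2 == 0, "2", "none"))
  u2$autism_subgroup <- ifelse(uni$gene %in% topg, "1",
                               ifelse(seq_len(nrow(uni)) %% 2 == 1, "2", "none"))
  res <- common_gene_centrality_test(fx$net, u2)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$direction, "common_higher")

  u3 <- u2
  u3$epilepsy_subgroup <- u2$autism_subgroup
  u3$autism_subgroup <- u2$epilepsy_subgroup
  res3 <- common_gene_centrality_test(fx$net, u3)
  expect_equal(res3$p_value, res$p_value)

  bad <- u2
  bad$epilepsy_subgroup <- "none"
  expect_error(common_gene_centrality_test(fx$net, bad), "degenerate")
})
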