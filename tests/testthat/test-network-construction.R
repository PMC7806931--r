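# layer construction: confidence thresholding, top-k score filtering,
# phenotype vectors, cosine similarity, permutation thresholds, multiplex
# assembly

test_that("PPI threshold keeps 700, drops 699, and is monotone in the cutoff", {
  genes <- c("G1", "G2", "G3", "G4", "G5")
  edges <- data.frame(gene_a = c("G1", "G1", "G2", "G9"),
                      gene_b = c("G2", "G3", "G3", "G1"),
                      combined_score = c(700, 699, 950, 999))
  l <- build_ppi_layer(edges, genes)
  keys <- paste(l$edges$from, l$edges$to)
  expect_setequal(keys, c("G1 G2", "G2 G3"))  # 699 dropped, G9 outside universe
  expect_equal(length(l$nodes), 5)

  empty <- build_ppi_layer(edges[0, ], genes)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(unname(layer_degrees(empty)), rep(0L, 5))

  for (cut in c(150, 400, 700, 900)) {
    lo <- build_ppi_layer(edges, genes, min_confidence = cut)
    hi <- build_ppi_layer(edges, genes, min_confidence = cut + 100)
    expect_true(all(paste(hi$edges$from, hi$edges$to) %in%
                    paste(lo$edges$from, lo$edges$to)))
  }

  bad <- data.frame(gene_a = "G1", gene_b = "G2", combined_score = "high")
  expect_error(build_ppi_layer(bad, genes), "row 1")
})

test_that("top-k score filter keeps per-term top scores including ties at rank k", {
  tab <- data.frame(term_id = c(rep("T1", 3), rep("T2", 3)),
                    gene = c("A", "B", "C", "A", "B", "C"),
                    score = c(5, 4, 3, 5, 4, 4), skew = 1)
  expect_equal(nrow(top_k_filter(tab, 10)), 6)
  f1 <- top_k_filter(tab, 2)
  expect_setequal(f1$gene[f1$term_id == "T1"], c("A", "B"))
  expect_setequal(f1$gene[f1$term_id == "T2"], c("A", "B", "C"))  # tie kept

  # downstream vectors are invariant to the input row order under ties
  ont <- data.frame(term_id = c("HP:ROOT", "T1", "T2"),
                    parent_id = c("NONE", "HP:ROOT", "HP:ROOT"))
  shuf <- tab[c(5, 2, 6, 1, 4, 3), ]
  v1 <- build_phenotype_vectors(top_k_filter(tab, 2), ont, genes = c("A", "B", "C"))
  v2 <- build_phenotype_vectors(top_k_filter(shuf, 2), ont, genes = c("A", "B", "C"))
  expect_equal(v1, v2)
})

test_that("phenotype vectors multiply score by skew and respect the root subtree", {
  # XX:* terms live under a separate root, outside the HP:ROOT subtree
  ont <- data.frame(term_id = c("HP:ROOT", "SEIZ:0001", "XX:ROOT", "XX:0001"),
                    parent_id = c("NONE", "HP:ROOT", "NONE", "XX:ROOT"))
  scores <- data.frame(term_id = c("SEIZ:0001", "XX:0001"),
                       gene = c("G1", "G1"), score = c(2, 9), skew = c(3, 1))
  v <- build_phenotype_vectors(scores, ont, root = "HP:ROOT",
                               genes = c("G1", "G2"))
  expect_equal(unname(v["G1", "SEIZ:0001"]), 6)       # 2 x 3
  expect_false("XX:0001" %in% colnames(v))            # outside subtree
  expect_equal(unname(rowSums(v)["G2"]), 0)           # scoreless gene: zeros
  expect_error(build_phenotype_vectors(scores, ont, root = "NOPE:1"), "unknown")
})

test_that("cosine similarity matches hand values and is symmetric and bounded", {
  u <- c(1, 1, 0); v <- c(1, 0, 1)
  expect_equal(phenotype_similarity(u, v), 0.5)
  expect_equal(phenotype_similarity(u, u), 1)
  expect_equal(phenotype_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(phenotype_similarity(c(0, 0, 0), v), 0)
  set.seed(42)
  for (r in 1:25) {
    a <- stats::rgamma(6, 1); b <- stats::rgamma(6, 1)
    s <- phenotype_similarity(a, b)
    expect_equal(s, phenotype_similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(phenotype_similarity(3.7 * a, b), s)  # scale invariance
  }
})

test_that("permutation threshold: degenerate inputs, calibration and exhaustive oracle", {
  # permutation-invariant vectors: every shuffle reproduces the observed value
  expect_equal(permutation_threshold(c(2, 2, 2), c(5, 5, 5), 200, 7, seed = 1), 1)
  # zero vector: +Inf sentinel, so no edge can ever be added
  expect_equal(permutation_threshold(c(0, 0, 0), c(1, 2, 3), 100, 1, seed = 1), Inf)
  expect_error(permutation_threshold(c(1, 0), c(0, 1), 5, 6), "n_shuffles >= rank")

  # exhaustive oracle on length-3 vectors: the rank-1 threshold approaches the
  # maximum over all 36 ordered permutation pairs
  u <- c(3, 1, 0); v <- c(2, 0, 5)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sims <- c()
  for (p in perms) for (q in perms) {
    sims <- c(sims, sum(u[p] * v[q]) / (sqrt(sum(u^2)) * sqrt(sum(v^2))))
  }
  thr <- permutation_threshold(u, v, n_shuffles = 1000, rank = 1, seed = 3)
  expect_equal(thr, max(sims))
  # and every Monte-Carlo threshold lies within the enumerated support
  for (s in 1:5) {
    t5 <- permutation_threshold(u, v, n_shuffles = 36, rank = 5, seed = s)
    expect_true(any(abs(sims - t5) < 1e-12))
  }

  # nominal calibration: the empirical tail probability of the threshold under
  # a fresh null sample is rank/n_shuffles
  set.seed(7)
  a <- stats::rgamma(12, 1); b <- stats::rgamma(12, 1)
  thr <- permutation_threshold(a, b, n_shuffles = 1000, rank = 10, seed = 21)
  fresh <- vapply(1:4000, function(i) {
    phenotype_similarity(a[sample.int(12)], b[sample.int(12)])
  }, numeric(1))
  p_tail <- mean(fresh >= thr)
  expect_lt(abs(p_tail - 0.01), 3 * sqrt(0.01 * 0.99 / 4000) + 0.004)
})

test_that("phenotype layer adds edges only above the per-pair null and is reproducible", {
  # all-zero vectors: empty layer
  vz <- matrix(0, 3, 4, dimnames = list(c("A", "B", "C"), paste0("T", 1:4)))
  expect_equal(nrow(build_phenotype_layer(vz, seed = 1)$edges), 0)

  # two identical strongly-concentrated vectors: observed similarity 1 beats
  # any non-degenerate permuted similarity
  vm <- matrix(0, 3, 30, dimnames = list(c("A", "B", "C"), paste0("T", 1:30)))
  vm["A", 1:3] <- c(10, 7, 4); vm["B", 1:3] <- c(10, 7, 4); vm["C", 5] <- 1
  l <- build_phenotype_layer(vm, n_shuffles = 300, rank = 3, seed = 2)
  expect_true(any(l$edges$from == "A" & l$edges$to == "B"))

  # reproducibility and node-order invariance of the edge set
  fx <- planted_instance()
  l1 <- build_phenotype_layer(fx$vectors, fx$bundle$universe, n_shuffles = 100,
                              rank = 1, seed = 5)
  l2 <- build_phenotype_layer(fx$vectors, fx$bundle$universe, n_shuffles = 100,
                              rank = 1, seed = 5)
  expect_identical(l1$edges, l2$edges)
  perm <- rev(fx$bundle$universe$gene)
  l3 <- build_phenotype_layer(fx$vectors, perm, n_shuffles = 100, rank = 1, seed = 5)
  expect_setequal(paste(l1$edges$from, l1$edges$to),
                  paste(l3$edges$from, l3$edges$to))
})

test_that("planted fixture: within-module phenotype density exceeds between-module", {
  fx <- planted_instance()
  mod <- stats::setNames(fx$bundle$universe$planted_module, fx$bundle$universe$gene)
  e <- fx$phen$edges
  within <- sum(mod[e$from] == mod[e$to])
  between <- nrow(e) - within
  n_within <- sum(choose(table(mod), 2))
  n_between <- choose(length(mod), 2) - n_within
  expect_gt(within / n_within, between / max(1, n_between))
  expect_gt(within / n_within, 0.5)
})

test_that("multiplex assembly aligns nodes and counts active genes", {
  l1 <- new_layer(c("A", "B", "C"), "A", "B", "ppi")
  l2 <- new_layer(c("C", "A", "B"), "B", "C", "phenotype")
  net <- assemble_multiplex(l1, l2)
  expect_identical(net$layers$phenotype$nodes, l1$nodes)  # realigned
  expect_equal(net$n_active, 3)  # C is PPI-isolated but phenotype-connected

  e1 <- new_layer(c("A", "B"), character(), character(), "ppi")
  e2 <- new_layer(c("A", "B"), character(), character(), "phenotype")
  expect_equal(assemble_multiplex(e1, e2)$n_active, 0)

  bad <- new_layer(c("A", "B", "D"), character(), character(), "phenotype")
  expect_error(assemble_multiplex(l1, bad), "alignment")
})
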