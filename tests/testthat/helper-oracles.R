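# Independent brute-force oracles and shared fixtures. Everything here is
# deliberately naive: enumeration and path listing, never the package's own
# code paths.

# ---- set-partition enumeration (restricted growth strings) ------------------

all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      grow(c(prefix, lab), max(maxlab, lab))
    }
  }
  grow(integer(0), 0L)
  out
}

# exact maximum modularity by exhaustive search over all partitions
brute_force_modularity <- function(layer, gamma = 1) {
  best <- -Inf
  for (mem in all_partitions(length(layer$nodes))) {
    q <- modularity_score(layer, stats::setNames(mem, layer$nodes), gamma)
    if (q > best) best <- q
  }
  best
}

# ---- exact betweenness by explicit shortest-path listing --------------------

# raw ordered-pair betweenness: for every ordered (s, t) pair, every shortest
# path is listed and each interior node credited sigma(s,t|v)/sigma(s,t)
bf_betweenness_raw <- function(layer) {
  nodes <- layer$nodes
  n <- length(nodes)
  adj <- rep(list(integer(0)), n)
  ei <- match(layer$edges$from, nodes)
  ej <- match(layer$edges$to, nodes)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
    adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
  }
  B <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0; queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[u]]) if (!is.finite(dist[w])) {
        dist[w] <- dist[u] + 1
        queue <- c(queue, w)
      }
    }
    for (t in seq_len(n)) {
      if (t == s || !is.finite(dist[t])) next
      paths <- list()
      walk <- function(v, acc) {
        if (v == s) {
          paths[[length(paths) + 1L]] <<- c(s, rev(acc))
          return(invisible())
        }
        for (u in adj[[v]]) if (dist[u] == dist[v] - 1) walk(u, c(acc, v))
      }
      walk(t, integer(0))
      sigma <- length(paths)
      interior <- setdiff(unlist(paths), c(s, t))
      for (v in unique(interior)) {
        through <- sum(vapply(paths, function(pp) v %in% pp, logical(1)))
        B[v] <- B[v] + through / sigma
      }
    }
  }
  stats::setNames(B, nodes)
}

# ---- exact hypergeometric tail by draw enumeration --------------------------

enum_hypergeom_tail <- function(k, K, n, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# ---- graph helpers ----------------------------------------------------------

random_layer <- function(n, p, seed, name = "rand") {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  new_layer(nodes, nodes[pairs[1L, keep]], nodes[pairs[2L, keep]], name)
}

two_triangles_layer <- function() {
  new_layer(letters[1:6], c("a", "b", "a", "d", "e", "d"),
            c("b", "c", "c", "e", "f", "f"), "tri2")
}

# complete within-module blocks with the given sizes; distinct degrees when
# sizes differ
block_layer <- function(sizes, name = "blocks") {
  nodes <- sprintf("b%02d", seq_len(sum(sizes)))
  mem <- rep(seq_along(sizes), sizes)
  from <- character(0); to <- character(0)
  for (m in seq_along(sizes)) {
    idx <- which(mem == m)
    if (length(idx) < 2) next
    pr <- utils::combn(idx, 2L)
    from <- c(from, nodes[pr[1L, ]])
    to <- c(to, nodes[pr[2L, ]])
  }
  new_layer(nodes, from, to, name)
}

# ---- shared planted fixture (medium size, cached per session) ---------------

.fixture_cache <- new.env(parent = emptyenv())

planted_instance <- function() {
  if (is.null(.fixture_cache$medium)) {
    cfg <- simulation_config(n_genes = 120, n_modules = 3, n_terms = 80,
                             terms_per_module = 6, seed = 11)
    b <- simulate_bundle(cfg)
    ppi <- build_ppi_layer(b$edges, b$universe)
    vec <- build_phenotype_vectors(top_k_filter(b$scores, 1000), b$ontology,
                                   genes = b$universe$gene)
    phen <- build_phenotype_layer(vec, b$universe, n_shuffles = 300, rank = 3,
                                  seed = 11)
    .fixture_cache$medium <- list(
      cfg = cfg, bundle = b, ppi = ppi, phen = phen, vectors = vec,
      net = assemble_multiplex(ppi, phen),
      truth = stats::setNames(b$universe$planted_module, b$universe$gene))
  }
  .fixture_cache$medium
}
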