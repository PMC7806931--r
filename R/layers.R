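#' Construct a binary network layer
#'
#' A layer is a simple undirected graph with unit edge weights over the full
#' gene universe: genes absent from the edge source are kept as degree-zero
#' nodes, since they may be connected in the other layer of the multiplex.
#'
#' @param nodes Character vector of unique node names (the universe order).
#' @param from,to Character vectors of edge endpoints; unordered, self-loops
#'   and duplicate pairs are removed.
#' @param name Layer name, conventionally `"ppi"` or `"phenotype"`.
#' @return Object of class `gp_layer`: list with `nodes`, `edges`
#'   (data.frame `from`/`to` with `from < to`), `name`.
#' @export
new_layer <- function(nodes, from = character(), to = character(), name = "layer") {
  .assert(!anyDuplicated(nodes), "layer nodes must be unique")
  .assert(length(from) == length(to), "from/to length mismatch")
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  .assert(all(from %in% nodes) && all(to %in% nodes),
          "layer edges reference nodes outside the universe")
  swap <- from > to
  lo <- ifelse(swap, to, from)
  hi <- ifelse(swap, from, to)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  edges <- data.frame(from = lo[!dup], to = hi[!dup], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = name), class = "gp_layer")
}

#' @export
print.gp_layer <- function(x, ...) {
  cat(sprintf("<gp_layer '%s'> %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @rdname new_layer
#' @param layer A `gp_layer`.
#' @return `layer_igraph()`: the layer as an [igraph][igraph::graph_from_data_frame]
#'   graph including isolated nodes.
#' @export
layer_igraph <- function(layer) {
  igraph::graph_from_data_frame(layer$edges, directed = FALSE,
                                vertices = data.frame(name = layer$nodes))
}

#' @rdname new_layer
#' @return `layer_degrees()`: named integer vector of node degrees.
#' @export
layer_degrees <- function(layer) {
  d <- integer(length(layer$nodes))
  names(d) <- layer$nodes
  t1 <- table(layer$edges$from)
  t2 <- table(layer$edges$to)
  d[names(t1)] <- d[names(t1)] + as.integer(t1)
  d[names(t2)] <- d[names(t2)] + as.integer(t2)
  d
}

.edge_keys <- function(layer) .pair_key(layer$edges$from, layer$edges$to)

#' Build the PPI layer from a confidence-scored edge table
#'
#' Keeps an edge iff both genes belong to the universe and the combined
#' confidence score is at least `min_confidence` (default 700, the
#' conventional "high confidence" cut on the 0-1000 STRING scale); resulting
#' edge weights are binary. Genes without any retained interaction remain as
#' degree-zero nodes.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `combined_score`.
#' @param universe A `gene_universe` data frame, or a character vector of genes.
#' @param min_confidence Minimum combined score retained.
#' @return A `gp_layer` named `"ppi"`.
#' @export
build_ppi_layer <- function(edges, universe, min_confidence = 700) {
  genes <- if (is.character(universe)) universe else universe$gene
  need <- c("gene_a", "gene_b", "combined_score")
  .assert(all(need %in% names(edges)),
          paste("edge table must have columns", paste(need, collapse = ", ")))
  score <- suppressWarnings(as.numeric(edges$combined_score))
  if (anyNA(score)) {
    stop(sprintf("malformed edge table: non-numeric combined_score at row %d",
                 which(is.na(score))[1L]), call. = FALSE)
  }
  keep <- score >= min_confidence & edges$gene_a %in% genes & edges$gene_b %in% genes
  new_layer(genes, edges$gene_a[keep], edges$gene_b[keep], name = "ppi")
}

#' Keep the top-k scoring genes per phenotype term
#'
#' For each term, retains only the `k` highest-scoring gene associations; all
#' rows tied with the k-th score are kept, so the result does not depend on
#' the input row order. Terms with at most `k` genes are untouched.
#'
#' @param scores A `score_table` (columns `term_id`, `gene`, `score`, `skew`).
#' @param k Positive integer.
#' @return Filtered score table.
#' @export
top_k_filter <- function(scores, k) {
  .assert(k >= 1, "k must be at least 1")
  thr <- stats::ave(scores$score, scores$term_id, FUN = function(s) {
    if (length(s) <= k) -Inf else sort(s, decreasing = TRUE)[k]
  })
  out <- scores[scores$score >= thr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-gene phenotype vectors
#'
#' Each gene's vector is indexed over the ontology terms lying under `root`
#' (the "Phenotypic abnormality"-style root); the entry for a term is the
#' association score multiplied by the term's skewness weight. Scored terms
#' outside the root's subtree are excluded; genes without scored terms get
#' all-zero vectors.
#'
#' @param scores A `score_table`.
#' @param ontology An `ontology_table`.
#' @param root Term id rooting the retained subtree.
#' @param genes Optional character vector fixing the vector set (e.g. the full
#'   universe); defaults to the genes present in `scores`.
#' @return Numeric matrix, genes in rows, terms in columns.
#' @export
build_phenotype_vectors <- function(scores, ontology, root = "HP:ROOT",
                                    genes = NULL) {
  terms <- hpo_subtree(ontology, root)
  if (is.null(genes)) genes <- sort(unique(scores$gene))
  keep <- scores$term_id %in% terms & scores$gene %in% genes
  s <- scores[keep, , drop = FALSE]
  m <- matrix(0, nrow = length(genes), ncol = length(terms),
              dimnames = list(genes, terms))
  if (nrow(s)) {
    m[cbind(match(s$gene, genes), match(s$term_id, terms))] <- s$score * s$skew
  }
  m
}

#' Cosine similarity between two phenotype vectors
#'
#' Returns 0 when either vector is all-zero (the cosine is undefined there and
#' a scoreless gene should not link to anything).
#'
#' @param u,v Nonnegative numeric vectors over the same term index.
#' @return Similarity in `[0, 1]`.
#' @export
phenotype_similarity <- function(u, v) {
  .assert(length(u) == length(v), "vectors must share the same term index")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  min(1, sum(u * v) / (nu * nv))
}

#' Permutation threshold for a phenotype-similarity edge
#'
#' The similarity threshold for a gene pair is calibrated from the pair's own
#' permutation null: the entries of both vectors are shuffled independently
#' `n_shuffles` times, the similarities are sorted, and the `rank`-th largest
#' is returned, so the threshold's nominal tail probability is
#' `rank / n_shuffles` (0.01 at the defaults 10/1000). Independent
#' permutation of both vectors is equivalent in distribution to permuting one
#' vector with a single uniform permutation, which is how the null is drawn.
#' A joint shuffle (the same permutation applied to both vectors) leaves the
#' cosine unchanged, so `shuffle = "joint"` degenerately returns the observed
#' similarity.
#'
#' @param u,v Nonnegative numeric vectors over the same term index.
#' @param n_shuffles Number of permutations.
#' @param rank Order statistic returned (`rank`-th largest).
#' @param seed Optional seed for the shuffles.
#' @param shuffle `"independent"` (default) or `"joint"`.
#' @return The threshold similarity; `Inf` when either vector is all-zero,
#'   so such pairs never gain an edge.
#' @export
permutation_threshold <- function(u, v, n_shuffles = 1000, rank = 10,
                                  seed = NULL,
                                  shuffle = c("independent", "joint")) {
  shuffle <- match.arg(shuffle)
  .assert(length(u) == length(v), "vectors must share the same term index")
  .assert(n_shuffles >= rank && rank >= 1, "need n_shuffles >= rank >= 1")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(Inf)
  if (shuffle == "joint") return(phenotype_similarity(u, v))
  p <- which(u != 0)
  a <- u[p]
  len <- length(u)
  .with_seed(seed, {
    sims <- vapply(seq_len(n_shuffles), function(b) {
      sum(a * v[sample.int(len, length(p))])
    }, numeric(1)) / (nu * nv)
    sort(sims, decreasing = TRUE)[rank]
  })
}

#' Build the phenotype-similarity layer
#'
#' For every unordered gene pair, an edge is added iff the observed cosine
#' similarity strictly exceeds the pair's permutation threshold
#' ([permutation_threshold()]). Each pair's shuffles are seeded
#' deterministically from `(seed, sorted pair)`, so the layer is reproducible
#' and independent of evaluation order. Pairs with zero observed similarity
#' are skipped outright (their threshold is nonnegative).
#'
#' @param vectors Phenotype-vector matrix from [build_phenotype_vectors()].
#' @param universe Optional `gene_universe` or character vector fixing the
#'   node set/order; defaults to the matrix rows.
#' @param n_shuffles,rank,shuffle Passed to [permutation_threshold()].
#' @param seed Global seed for the per-pair substreams.
#' @return A `gp_layer` named `"phenotype"`.
#' @export
build_phenotype_layer <- function(vectors, universe = NULL,
                                  n_shuffles = 1000, rank = 10, seed = 1,
                                  shuffle = "independent") {
  genes <- if (is.null(universe)) rownames(vectors)
           else if (is.character(universe)) universe else universe$gene
  .assert(all(genes %in% rownames(vectors)),
          "vectors must cover every universe gene")
  v <- vectors[genes, , drop = FALSE]
  norms <- sqrt(rowSums(v^2))
  sims <- tcrossprod(v)
  denom <- outer(norms, norms)
  sims <- ifelse(denom > 0, sims / denom, 0)

  n <- length(genes)
  from <- character(); to <- character()
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      js <- which(sims[i, (i + 1L):n] > 0) + i
      for (j in js) {
        thr <- permutation_threshold(v[i, ], v[j, ], n_shuffles, rank,
                                     seed = .pair_seed(seed, genes[i], genes[j]),
                                     shuffle = shuffle)
        if (sims[i, j] > thr) {
          from <- c(from, genes[i]); to <- c(to, genes[j])
        }
      }
    }
  }
  new_layer(genes, from, to, name = "phenotype")
}

#' Assemble the two-layer multiplex network
#'
#' Stacks the PPI and phenotype layers over one shared, identically ordered
#' node set. The inter-layer coupling of a node to itself across layers is
#' implicit in the shared partition optimised by [louvain_multiplex()]; no
#' explicit coupling edges are scored. Layers given in a different node order
#' (same set) are realigned.
#'
#' @param ppi,phenotype `gp_layer`s over the same node set.
#' @param weights Nonnegative per-layer modularity weights, default equal so
#'   both layers contribute equally.
#' @return Object of class `gp_multiplex`: list with `nodes`, `layers`
#'   (named list), `weights`, and `n_active` (nodes with degree >= 1 in at
#'   least one layer).
#' @export
assemble_multiplex <- function(ppi, phenotype, weights = c(0.5, 0.5)) {
  if (!setequal(ppi$nodes, phenotype$nodes)) {
    stop("alignment error: layers have different node sets", call. = FALSE)
  }
  .assert(length(weights) == 2 && all(weights >= 0) && any(weights > 0),
          "weights must be two nonnegative values, not both zero")
  phen <- new_layer(ppi$nodes, phenotype$edges$from, phenotype$edges$to,
                    name = phenotype$name)
  act <- (layer_degrees(ppi) + layer_degrees(phen)) > 0
  structure(list(
    nodes = ppi$nodes,
    layers = list(ppi = ppi, phenotype = phen),
    weights = c(ppi = weights[[1]], phenotype = weights[[2]]),
    n_active = sum(act)
  ), class = "gp_multiplex")
}

#' @export
print.gp_multiplex <- function(x, ...) {
  cat(sprintf("<gp_multiplex> %d nodes (%d active); ppi %d edges, phenotype %d edges; weights %.2f/%.2f\n",
              length(x$nodes), x$n_active, nrow(x$layers$ppi$edges),
              nrow(x$layers$phenotype$edges), x$weights[[1]], x$weights[[2]]))
  invisible(x)
}
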