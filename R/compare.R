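#' Degree histogram of a layer
#'
#' @param layer A `gp_layer`.
#' @return Named integer vector: counts of nodes per degree; counts sum to
#'   the node count.
#' @export
degree_distribution <- function(layer) {
  d <- layer_degrees(layer)
  tab <- table(d)
  stats::setNames(as.integer(tab), names(tab))
}

# degree-preserving randomization by double-edge swaps (degrees preserved
# exactly); swap budget 10x the edge count
.rewire_layer <- function(g, nswap_mult = 10) {
  ne <- igraph::ecount(g)
  if (ne < 2) return(g)
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = nswap_mult * ne))
}

.igraph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (!nrow(el)) return(character())
  .pair_key(el[, 1L], el[, 2L])
}

.null_result <- function(observed, null_values, statistic, meta = list()) {
  structure(list(
    observed = observed,
    null_values = null_values,
    empirical_p = (1 + sum(null_values >= observed)) / (1 + length(null_values)),
    n_trials = length(null_values),
    statistic = statistic,
    meta = meta
  ), class = "null_test")
}

#' @export
print.null_test <- function(x, ...) {
  cat(sprintf("<null_test %s> observed = %.4g, empirical p = %.4g (%d trials)\n",
              x$statistic, x$observed, x$empirical_p, x$n_trials))
  invisible(x)
}

#' Edge-overlap concordance test between two layers
#'
#' Counts edges shared by both layers and compares against a null ensemble in
#' which both layers are independently randomized by degree-preserving
#' double-edge swaps each trial. The empirical p uses the add-one estimator
#' `(1 + #[null >= observed]) / (1 + n_trials)`, so it is never exactly zero
#' and its floor at 10,000 trials is just below 1e-4.
#'
#' @param l1,l2 `gp_layer`s over the same node set.
#' @param n_trials Null ensemble size.
#' @param seed Seed for the randomizations.
#' @param nswap_mult Swap budget per trial, as a multiple of the edge count.
#' @return A `null_test` with `observed`, `null_values`, `empirical_p`.
#' @export
edge_overlap_test <- function(l1, l2, n_trials = 10000, seed = 1,
                              nswap_mult = 10) {
  .assert(setequal(l1$nodes, l2$nodes), "layers must share one node set")
  observed <- length(intersect(.edge_keys(l1), .edge_keys(l2)))
  g1 <- layer_igraph(l1); g2 <- layer_igraph(l2)
  null_values <- .with_seed(seed, vapply(seq_len(n_trials), function(t) {
    length(intersect(.igraph_edge_keys(.rewire_layer(g1, nswap_mult)),
                     .igraph_edge_keys(.rewire_layer(g2, nswap_mult))))
  }, numeric(1)))
  .null_result(observed, null_values, "edge_overlap")
}

#' Normalized mutual information between two partitions
#'
#' Arithmetic-mean normalization (`2 I / (H1 + H2)`), symmetric in its
#' arguments, 1 for identical partitions; the degenerate case of two
#' entropy-zero (single-community) partitions is defined as 1.
#'
#' @param m1,m2 Membership vectors over the same nodes (aligned by name when
#'   named).
#' @return NMI in `[0, 1]`.
#' @export
partition_nmi <- function(m1, m2) {
  if (!is.null(names(m1)) && !is.null(names(m2))) {
    .assert(setequal(names(m1), names(m2)), "partitions must cover the same nodes")
    m2 <- m2[names(m1)]
  }
  .assert(length(m1) == length(m2), "partitions must have equal length")
  a <- as.integer(factor(m1)); b <- as.integer(factor(m2))
  if (max(a) == 1L && max(b) == 1L) return(1)
  igraph::compare(a, b, method = "nmi")
}

#' Partition-concordance (NMI) test between two layers
#'
#' Each layer is clustered with restarted Louvain; the observed statistic is
#' the NMI between the two partitions. The null replaces both layers by
#' degree-preserving randomizations each trial and re-clusters them
#' (with `null_restarts` restarts, a cheaper budget than the observed fit).
#'
#' @param l1,l2 `gp_layer`s over the same node set.
#' @param n_trials Null ensemble size.
#' @param gamma Resolution used for all clusterings.
#' @param seed Seed driving restarts and randomizations.
#' @param n_restarts Restarts for the observed partitions.
#' @param null_restarts Restarts per null clustering.
#' @param nswap_mult Swap budget multiple per trial.
#' @return A `null_test` carrying the NMI settings in `$meta`.
#' @export
partition_nmi_test <- function(l1, l2, n_trials = 1000, gamma = 1, seed = 1,
                               n_restarts = 20, null_restarts = 2,
                               nswap_mult = 10) {
  .assert(setequal(l1$nodes, l2$nodes), "layers must share one node set")
  p1 <- louvain_single(l1, modularity_params(gamma = gamma, n_restarts = n_restarts,
                                             seed = seed))
  p2 <- louvain_single(l2, modularity_params(gamma = gamma, n_restarts = n_restarts,
                                             seed = seed + 500000L))
  observed <- partition_nmi(p1$membership, p2$membership)
  g1 <- layer_igraph(l1); g2 <- layer_igraph(l2)
  null_values <- .with_seed(seed + 1000000L, vapply(seq_len(n_trials), function(t) {
    r1 <- .igraph_to_layer(.rewire_layer(g1, nswap_mult), l1$nodes, "null1")
    r2 <- .igraph_to_layer(.rewire_layer(g2, nswap_mult), l1$nodes, "null2")
    q1 <- louvain_single(r1, modularity_params(gamma = gamma, n_restarts = null_restarts,
                                               seed = seed + 2000000L + t))
    q2 <- louvain_single(r2, modularity_params(gamma = gamma, n_restarts = null_restarts,
                                               seed = seed + 3000000L + t))
    partition_nmi(q1$membership, q2$membership)
  }, numeric(1)))
  .null_result(observed, null_values, "partition_nmi",
               meta = list(nmi_normalization = "arithmetic",
                           gamma = gamma, n_restarts = n_restarts,
                           null_restarts = null_restarts))
}

.igraph_to_layer <- function(g, nodes, name) {
  el <- igraph::as_edgelist(g, names = TRUE)
  new_layer(nodes, el[, 1L], el[, 2L], name = name)
}

#' Cross-layer degree correlation
#'
#' Correlates each node's degree in one layer with its degree in the other.
#' Spearman rank correlation is the default since network degree
#' distributions are heavy-tailed; Pearson is available.
#'
#' @param l1,l2 `gp_layer`s over the same node set.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation coefficient.
#' @export
degree_correlation <- function(l1, l2, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  .assert(setequal(l1$nodes, l2$nodes), "layers must share one node set")
  if (length(l1$nodes) < 3) stop("degree correlation undefined for fewer than 3 nodes",
                                 call. = FALSE)
  d1 <- layer_degrees(l1)
  d2 <- layer_degrees(l2)[names(d1)]
  # a constant degree sequence carries no ordering information
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) return(NA_real_)
  stats::cor(d1, d2, method = method)
}

#' Serialize a null-ensemble test as a JSON report
#'
#' @param x A `null_test`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_null_test <- function(x, path) {
  rep <- list(statistic = x$statistic, observed = x$observed,
              n_trials = x$n_trials, empirical_p = x$empirical_p,
              null_quantiles = as.list(stats::quantile(x$null_values,
                                                       c(0, .25, .5, .75, .95, 1))),
              meta = x$meta)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
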