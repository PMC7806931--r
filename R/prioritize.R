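#' Shortest-path betweenness centrality of a layer
#'
#' `B(v) = sum over ordered pairs (s, t) of sigma(s, t | v) / sigma(s, t)`,
#' where `sigma(s, t)` counts shortest s-t paths (1 when `s = t`) and
#' `sigma(s, t | v)` those passing through `v` (0 when `v` is an endpoint).
#' The normalized mode (default) rescales by the number of eligible
#' unordered pairs excluding `v`, `(n - 1)(n - 2) / 2`, matching the
#' magnitude of values conventionally reported for undirected networks; the
#' raw mode returns the ordered-pair sum of the formula above (twice the
#' unordered-pair sum).
#'
#' @param layer A `gp_layer`.
#' @param normalized Logical.
#' @return Named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(layer, normalized = TRUE) {
  g <- layer_igraph(layer)
  b <- igraph::betweenness(g, directed = FALSE)   # unordered-pair sum
  n <- length(layer$nodes)
  out <- if (normalized) {
    if (n < 3) stats::setNames(numeric(n), layer$nodes) else b * 2 / ((n - 1) * (n - 2))
  } else {
    2 * b
  }
  out[layer$nodes]
}

.annotation_string <- function(universe, genes) {
  idx <- match(genes, universe$gene)
  epi <- universe$epilepsy_subgroup[idx]
  aut <- universe$autism_subgroup[idx]
  vapply(seq_along(genes), function(i) {
    parts <- c(if (epi[i] != "none") paste("Epilepsy", epi[i]),
               if (aut[i] != "none") paste("Autism", aut[i]))
    paste(parts, collapse = ", ")
  }, character(1))
}

#' Within-module centrality table
#'
#' Per-layer degree and betweenness (computed on the full layers, then
#' restricted to module members) plus their cross-layer arithmetic means.
#' Ranks by average degree and by average betweenness are attached, ties
#' broken deterministically by gene symbol.
#'
#' @param net A `gp_multiplex`.
#' @param module_genes Genes of the module (defaults to all nodes).
#' @param universe Optional `gene_universe` used to annotate rows with
#'   disease subgroup labels.
#' @param normalized Betweenness normalization flag.
#' @return `data.frame` ordered by decreasing average degree with columns
#'   `gene`, `ppi_degree`, `phen_degree`, `avg_degree`, `ppi_bc`, `phen_bc`,
#'   `avg_bc`, `rank_degree`, `rank_bc` (and `annotation` when a universe is
#'   supplied).
#' @export
centrality_table <- function(net, module_genes = NULL, universe = NULL,
                             normalized = TRUE) {
  genes <- module_genes %||% net$nodes
  .assert(all(genes %in% net$nodes), "module genes must lie in the universe")
  d1 <- layer_degrees(net$layers$ppi)[genes]
  d2 <- layer_degrees(net$layers$phenotype)[genes]
  b1 <- betweenness_centrality(net$layers$ppi, normalized)[genes]
  b2 <- betweenness_centrality(net$layers$phenotype, normalized)[genes]
  out <- data.frame(
    gene = genes,
    ppi_degree = as.integer(d1), phen_degree = as.integer(d2),
    avg_degree = (d1 + d2) / 2,
    ppi_bc = b1, phen_bc = b2, avg_bc = (b1 + b2) / 2,
    stringsAsFactors = FALSE)
  out$rank_degree <- order(order(-out$avg_degree, out$gene))
  out$rank_bc <- order(order(-out$avg_bc, out$gene))
  if (!is.null(universe)) out$annotation <- .annotation_string(universe, genes)
  out <- out[order(out$rank_degree), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match modules across two partitions
#'
#' For every pair of modules from two partitions (possibly over different
#' universes with a shared subset), reports the shared genes and the fraction
#' of the b-module's genes -- among those present in the a-universe -- that
#' fall into the a-module. The best match per b-module (maximal fraction,
#' ties to the larger shared count then smaller a-module id) is flagged.
#'
#' @param pa,pb `gp_partition`s.
#' @return `data.frame` with columns `module_a`, `module_b`, `shared`,
#'   `shared_genes` (comma-separated), `frac_of_b_in_a`, `best`.
#' @export
match_modules <- function(pa, pb) {
  ga <- names(pa$membership)
  rows <- list()
  for (mb in sort(unique(pb$membership))) {
    genes_b <- names(pb$membership)[pb$membership == mb]
    in_a <- intersect(genes_b, ga)
    if (!length(in_a)) next
    for (ma in sort(unique(pa$membership[in_a]))) {
      shared <- in_a[pa$membership[in_a] == ma]
      rows[[length(rows) + 1L]] <- data.frame(
        module_a = ma, module_b = mb, shared = length(shared),
        shared_genes = paste(sort(shared), collapse = ","),
        frac_of_b_in_a = length(shared) / length(in_a),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(module_a = integer(), module_b = integer(),
                      shared = integer(), shared_genes = character(),
                      frac_of_b_in_a = numeric(), best = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$best <- FALSE
  for (mb in unique(out$module_b)) {
    i <- which(out$module_b == mb)
    j <- i[order(-out$frac_of_b_in_a[i], -out$shared[i], out$module_a[i])][1L]
    out$best[j] <- TRUE
  }
  rownames(out) <- NULL
  out
}

#' Candidate genes from cross-network module overlap
#'
#' Within the overlap of two disease-A-focused modules (one per network), the
#' candidate genes for disease A are the genes currently labelled only with
#' disease B: membership in an A-focused, common-gene-enriched module argues
#' for an undiscovered association with A. `focus = "epilepsy"` returns
#' autism-only genes; `focus = "autism"` the symmetric set.
#'
#' @param overlap_genes Genes in the module overlap.
#' @param universe A `gene_universe` covering them.
#' @param focus `"epilepsy"` or `"autism"`: the disease the module focuses on.
#' @return Character vector of candidate genes (sorted).
#' @export
candidate_genes <- function(overlap_genes, universe,
                            focus = c("epilepsy", "autism")) {
  focus <- match.arg(focus)
  .assert(all(overlap_genes %in% universe$gene),
          "overlap genes must lie in the universe")
  idx <- match(overlap_genes, universe$gene)
  epi <- universe$epilepsy_subgroup[idx] != "none"
  aut <- universe$autism_subgroup[idx] != "none"
  keep <- if (focus == "epilepsy") !epi & aut else epi & !aut
  sort(overlap_genes[keep])
}

#' Secondary candidate rule: focused-module genes landing in another
#' prioritized module
#'
#' Genes of the small-network focused module that are disease-B-specific but
#' fall outside the overlap because their large-network module is a
#' different prioritized module (rather than the matched one) are still
#' candidates: they sit in an A-focused module of one network and a
#' common-gene-enriched module of the other.
#'
#' @param focused_module_genes Genes of the small-network focused module.
#' @param partition_large `gp_partition` of the large network.
#' @param prioritized_modules Module ids of the large network considered
#'   prioritized (common-gene enriched).
#' @param universe A `gene_universe`.
#' @param focus As in [candidate_genes()].
#' @param exclude Genes already returned by the primary rule.
#' @return `data.frame` with columns `gene`, `large_module`.
#' @export
secondary_candidates <- function(focused_module_genes, partition_large,
                                 prioritized_modules, universe,
                                 focus = c("epilepsy", "autism"),
                                 exclude = character()) {
  focus <- match.arg(focus)
  pool <- setdiff(intersect(focused_module_genes, names(partition_large$membership)),
                  exclude)
  specific <- candidate_genes(intersect(pool, universe$gene), universe, focus)
  mods <- partition_large$membership[specific]
  keep <- specific[mods %in% prioritized_modules]
  data.frame(gene = keep,
             large_module = as.integer(partition_large$membership[keep]),
             stringsAsFactors = FALSE)
}

#' Rank-sum comparison of centrality between common and disease-specific genes
#'
#' Two-sided Mann-Whitney test of a chosen centrality measure between genes
#' carrying both disease labels ("common") and genes carrying exactly one
#' ("specific"), with the effect direction reported.
#'
#' @param net A `gp_multiplex`.
#' @param universe A `gene_universe` over its nodes.
#' @param measure `"avg_degree"` or `"avg_bc"`.
#' @return List with `p_value`, `direction` (`"common_higher"` /
#'   `"common_lower"` / `"none"`), group medians and sizes.
#' @export
common_gene_centrality_test <- function(net, universe,
                                        measure = c("avg_degree", "avg_bc")) {
  measure <- match.arg(measure)
  ct <- centrality_table(net)
  idx <- match(ct$gene, universe$gene)
  epi <- universe$epilepsy_subgroup[idx] != "none"
  aut <- universe$autism_subgroup[idx] != "none"
  common <- ct[[measure]][epi & aut]
  specific <- ct[[measure]][xor(epi, aut)]
  if (length(common) < 2 || length(specific) < 2) {
    stop("degenerate class: need at least 2 genes per class", call. = FALSE)
  }
  # a fully tied comparison carries no evidence either way
  pv <- if (length(unique(c(common, specific))) == 1L) 1 else
    stats::wilcox.test(common, specific, alternative = "two.sided",
                       exact = FALSE)$p.value
  dm <- stats::median(common) - stats::median(specific)
  list(p_value = pv,
       direction = if (dm > 0) "common_higher" else if (dm < 0) "common_lower" else "none",
       median_common = stats::median(common),
       median_specific = stats::median(specific),
       n_common = length(common), n_specific = length(specific),
       measure = measure)
}
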