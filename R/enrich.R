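#' Hypergeometric upper-tail enrichment probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` members of a size-`K` group when sampling `n` genes without
#' replacement from a background of `N`.
#'
#' @param k Observed overlap.
#' @param K Group size in the background.
#' @param n Draw (module) size.
#' @param N Background size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_p <- function(k, K, n, N) {
  .assert(all(c(k, K, n, N) >= 0) && k <= min(K, n) && K <= N && n <= N,
          "inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values, order-preserving with respect to
#' the input.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return q-values, each `>=` its p-value.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  .assert(all(pvals > 0 & pvals <= 1), "p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Significance tiers for FDR values
#'
#' Star bands used when reporting enrichment heat maps: `"****"` below 1e-4,
#' `"***"` below 0.01, `"**"` below 0.05, `"*"` below 0.1.
#'
#' @param fdr Numeric vector of q-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(fdr) {
  cut(fdr, breaks = c(-Inf, 1e-4, 0.01, 0.05, 0.1, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE) |> as.character()
}

#' All terms of an ontology subtree
#'
#' Returns `root` plus every descendant reachable through parent-child rows.
#'
#' @param ontology An `ontology_table` (columns `term_id`, `parent_id`).
#' @param root Subtree root term id.
#' @return Character vector of term ids.
#' @export
hpo_subtree <- function(ontology, root) {
  if (!root %in% ontology$term_id) {
    stop(sprintf("unknown ontology root '%s'", root), call. = FALSE)
  }
  children <- split(ontology$term_id, ontology$parent_id)
  out <- character(0)
  frontier <- root
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(children[frontier], use.names = FALSE)
    frontier <- setdiff(frontier, out)   # guards against malformed cycles
  }
  out
}

#' Gene-group enrichment of modules
#'
#' One hypergeometric upper-tail test per (module, gene group) cell, with
#' BH correction across all cells of the call (one test family per figure
#' panel). Two background conventions: `"network"` uses the genes of the
#' analysed network (group sizes are intersected with it), `"genome"` uses a
#' configured genome-wide count (default 19,556, a STRING-scale background)
#' with module and group counts unchanged.
#'
#' @param modules Named list of module gene vectors (e.g. from
#'   [filter_modules()]).
#' @param groups Named list of gene-group vectors.
#' @param background_genes Character vector of network genes.
#' @param background `"network"` or `"genome"`.
#' @param genome_size Background size for `background = "genome"`.
#' @return `data.frame` with columns `module`, `target`, `k`, `K`, `n`, `N`,
#'   `statistic`, `p`, `fdr`, `background`, `mode`, `stars`.
#' @export
gene_group_enrichment <- function(modules, groups, background_genes,
                                  background = c("network", "genome"),
                                  genome_size = 19556) {
  background <- match.arg(background)
  rows <- list()
  for (mn in names(modules)) {
    mod <- intersect(modules[[mn]], background_genes)
    for (gn in names(groups)) {
      if (background == "network") {
        K <- length(intersect(groups[[gn]], background_genes))
        N <- length(background_genes)
      } else {
        K <- length(unique(groups[[gn]]))
        N <- genome_size
        if (K > N) stop(sprintf("group '%s' larger than the genome background", gn),
                        call. = FALSE)
      }
      k <- length(intersect(mod, groups[[gn]]))
      rows[[length(rows) + 1L]] <- data.frame(
        module = mn, target = gn, k = k, K = K, n = length(mod), N = N,
        statistic = k, p = hypergeom_p(k, K, length(mod), N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$background <- background
  out$mode <- "hypergeometric"
  out$stars <- significance_stars(out$fdr)
  rownames(out) <- NULL
  out
}

#' Empirical mean-score phenotype enrichment of a module
#'
#' The statistic is the mean gene-phenotype association score of the module's
#' genes for one term (genes without a score row count as 0, since
#' association tables are sparse). The p-value compares it to the mean of
#' `n_trials` draws of `|module|` genes sampled uniformly without replacement
#' from the background, with the add-one estimator
#' `(1 + #[trial mean >= observed]) / (1 + n_trials)`.
#'
#' @param module_genes Genes of the module (must be within the background).
#' @param term_id Phenotype term tested.
#' @param scores A `score_table`.
#' @param background_genes Background pool: the network's genes, or all
#'   knowledgebase genes.
#' @param n_trials Number of random draws.
#' @param seed Optional seed.
#' @return One-row `data.frame` (`target`, `n`, `N`, `statistic`, `p`, `mode`).
#' @export
phenotype_score_enrichment <- function(module_genes, term_id, scores,
                                       background_genes, n_trials = 10000,
                                       seed = NULL) {
  .assert(length(module_genes) > 0, "module must not be empty")
  .assert(all(module_genes %in% background_genes),
          "module genes must be contained in the background")
  s <- scores[scores$term_id == term_id, , drop = FALSE]
  sv <- stats::setNames(numeric(length(background_genes)), background_genes)
  hit <- s$gene %in% background_genes
  sv[s$gene[hit]] <- s$score[hit]
  observed <- mean(sv[module_genes])
  n <- length(module_genes)
  N <- length(background_genes)
  trial_means <- .with_seed(seed, vapply(seq_len(n_trials), function(b) {
    mean(sv[sample.int(N, n)])
  }, numeric(1)))
  p <- (1 + sum(trial_means >= observed)) / (1 + n_trials)
  data.frame(target = term_id, n = n, N = N, statistic = observed, p = p,
             mode = "empirical_score", stringsAsFactors = FALSE)
}

#' Phenotype enrichment table over modules and terms
#'
#' Runs [phenotype_score_enrichment()] for every (module, term) pair, with BH
#' correction across terms within each module-level family of the call.
#'
#' @param modules Named list of module gene vectors.
#' @param terms Term ids to test.
#' @param scores A `score_table`.
#' @param background_genes Background pool.
#' @param n_trials Draws per test.
#' @param seed Base seed; each (module, term) gets a derived substream.
#' @return `data.frame` with one row per module x term.
#' @export
phenotype_enrichment_table <- function(modules, terms, scores,
                                       background_genes, n_trials = 10000,
                                       seed = 1) {
  rows <- list()
  for (mn in names(modules)) {
    for (tm in terms) {
      r <- phenotype_score_enrichment(modules[[mn]], tm, scores,
                                      background_genes, n_trials,
                                      seed = .pair_seed(seed, mn, tm))
      r$module <- mn
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$stars <- significance_stars(out$fdr)
  out[c("module", "target", "n", "N", "statistic", "p", "fdr", "mode", "stars")]
}

#' Annotated-term hypergeometric phenotype enrichment
#'
#' The hypergeometric variant of phenotype enrichment: each term contributes
#' its annotated gene set, and the module's overlap with it is tested against
#' the background, with BH correction across terms.
#'
#' @param module_genes Genes of the module.
#' @param term_annotations Named list: term id -> annotated gene set.
#' @param background_genes Background gene pool.
#' @return `data.frame` with one row per term (`target`, `k`, `K`, `n`, `N`,
#'   `p`, `fdr`, `mode`, `stars`).
#' @export
annotated_term_enrichment <- function(module_genes, term_annotations,
                                      background_genes) {
  if (!length(term_annotations)) {
    return(data.frame(target = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), statistic = integer(),
                      p = numeric(), fdr = numeric(), mode = character(),
                      stars = character(), stringsAsFactors = FALSE))
  }
  mod <- intersect(module_genes, background_genes)
  N <- length(background_genes)
  rows <- lapply(names(term_annotations), function(tm) {
    K <- length(intersect(term_annotations[[tm]], background_genes))
    k <- length(intersect(mod, term_annotations[[tm]]))
    data.frame(target = tm, k = k, K = K, n = length(mod), N = N,
               statistic = k, p = hypergeom_p(k, K, length(mod), N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$mode <- "annotated_hypergeom"
  out$stars <- significance_stars(out$fdr)
  rownames(out) <- NULL
  out
}

#' Generic annotation-set enrichment
#'
#' Hypergeometric enrichment of a module in arbitrary user-supplied named
#' gene sets (functional categories, pathways, ...), replacing any external
#' annotation service. Identical machinery to [annotated_term_enrichment()].
#'
#' @param module_genes Genes of the module.
#' @param named_sets Named list of gene sets.
#' @param background_genes Background gene pool.
#' @return As [annotated_term_enrichment()].
#' @export
annotation_set_enrichment <- function(module_genes, named_sets,
                                      background_genes) {
  annotated_term_enrichment(module_genes, named_sets, background_genes)
}
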