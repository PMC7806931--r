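#' Simulation configuration for synthetic multiplex inputs
#'
#' Defines the study conditions for the synthetic-data generator, which
#' emulates the four inputs of the real analysis: a dual-labelled disease gene
#' universe (disease A = epilepsy-like subgroups 1-4, disease B = autism-like
#' subgroups 1/2/3/S), a STRING-style confidence-scored PPI edge table, a
#' rooted phenotype ontology with marked "seizure-like" (`SEIZ:`) and
#' "autistic-behaviour-like" (`AUT:`) subtrees, and a sparse gene-phenotype
#' association score table with a per-term skewness weight. Module structure
#' is planted: genes in the same planted module preferentially share
#' high-confidence PPI edges and characteristic phenotype terms.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_modules Number of planted modules.
#' @param frac_disease_a,frac_disease_b Fractions of genes labelled with
#'   disease A (epilepsy-like) and disease B (autism-like).
#' @param frac_common Fraction of genes carrying both labels; must not exceed
#'   `min(frac_disease_a, frac_disease_b)`.
#' @param common_module_bias Fraction of common genes planted inside module 1,
#'   making it the "common-gene-rich" module.
#' @param p_in,p_out Within- and between-module PPI edge probabilities.
#' @param n_terms Total number of ontology terms (including the root).
#' @param terms_per_module Characteristic phenotype terms per planted module.
#' @param noise_terms_per_gene Background terms scored per gene.
#' @param score_signal,score_noise Magnitudes of characteristic and background
#'   association scores. `score_noise = 0` yields disjoint phenotype supports
#'   across modules.
#' @param seed Integer seed; each generator stage derives its own substream
#'   from it so stages are reproducible in isolation.
#'
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 60, n_modules = 3, seed = 7)
#' u <- generate_universe(cfg)
#' table(u$planted_module)
simulation_config <- function(n_genes = 200L, n_modules = 4L,
                              frac_disease_a = 0.585, frac_disease_b = 0.535,
                              frac_common = 0.12, common_module_bias = 0.8,
                              p_in = 0.4, p_out = 0.01,
                              n_terms = 120L, terms_per_module = 8L,
                              noise_terms_per_gene = 5L,
                              score_signal = 10, score_noise = 1,
                              seed = 1L) {
  props <- c(frac_disease_a = frac_disease_a, frac_disease_b = frac_disease_b,
             frac_common = frac_common, common_module_bias = common_module_bias,
             p_in = p_in, p_out = p_out)
  if (any(!is.finite(props)) || any(props < 0) || any(props > 1)) {
    stop("configuration error: all proportions/probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (frac_common > min(frac_disease_a, frac_disease_b) + 1e-12) {
    stop("configuration error: frac_common must not exceed min(frac_disease_a, frac_disease_b)",
         call. = FALSE)
  }
  .assert(n_genes >= 1 && n_modules >= 1, "configuration error: counts must be positive")
  .assert(n_terms >= 3, "configuration error: n_terms must be at least 3")
  .assert(score_signal >= 0 && score_noise >= 0,
          "configuration error: score magnitudes must be nonnegative")
  structure(list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    frac_disease_a = frac_disease_a, frac_disease_b = frac_disease_b,
    frac_common = frac_common, common_module_bias = common_module_bias,
    p_in = p_in, p_out = p_out,
    n_terms = as.integer(n_terms), terms_per_module = as.integer(terms_per_module),
    noise_terms_per_gene = as.integer(noise_terms_per_gene),
    score_signal = score_signal, score_noise = score_noise,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# substream offsets: one global seed drives independent per-stage streams
.stage_seed <- function(cfg, stage) {
  off <- c(universe = 11L, edges = 22L, ontology = 33L, scores = 44L)[[stage]]
  as.integer((cfg$seed + off) %% 2147483647)
}

#' Generate a labelled gene universe with planted modules
#'
#' Genes are assigned uniformly to `n_modules` planted modules. Disease labels
#' are then drawn to match the configured fractions to within one gene:
#' `frac_common` of genes carry both labels (concentrated in module 1 with
#' probability `common_module_bias`), the remainder of each disease fraction
#' is label-specific. Subgroup labels mimic the field's convention (disease A
#' subgroups `"1"`-`"4"`, disease B subgroups `"1","2","3","S"`, or `"none"`).
#' Auxiliary gene groups (WES hits per disease, two other brain-disorder gene
#' sets, an intellectual-disability set and brain-enriched-gene flags) are
#' sampled as logical columns.
#'
#' @param cfg A [simulation_config()] object.
#' @return A `data.frame` of class `gene_universe` with columns `gene`,
#'   `epilepsy_subgroup`, `autism_subgroup`, `planted_module` and logical
#'   auxiliary columns `wes_epilepsy`, `wes_autism`, `bd`, `scz`, `id`, `beg`.
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  n_common <- round(cfg$frac_common * n)
  n_a <- round(cfg$frac_disease_a * n)
  n_b <- round(cfg$frac_disease_b * n)
  if (n_a + n_b - n_common > n) {
    stop("configuration error: label fractions exceed the universe size", call. = FALSE)
  }
  .with_seed(.stage_seed(cfg, "universe"), {
    genes <- sprintf("G%04d", seq_len(n))
    planted <- sample(rep_len(seq_len(cfg$n_modules), n))

    idx <- seq_len(n)
    m1 <- idx[planted == 1L]
    n_c1 <- min(length(m1), round(cfg$common_module_bias * n_common))
    common <- c(
      if (n_c1 > 0) sample(m1, n_c1),
      if (n_common - n_c1 > 0) sample(setdiff(idx, m1), n_common - n_c1)
    )
    rest <- setdiff(idx, common)
    a_only <- if (n_a - n_common > 0) sample(rest, n_a - n_common) else integer()
    rest2 <- setdiff(rest, a_only)
    b_only <- if (n_b - n_common > 0) sample(rest2, n_b - n_common) else integer()

    epi <- rep("none", n)
    aut <- rep("none", n)
    has_a <- union(common, a_only)
    has_b <- union(common, b_only)
    # subgroup frequencies follow the published summary table proportions
    epi[has_a] <- sample(c("1", "2", "3", "4"), length(has_a), replace = TRUE,
                         prob = c(84, 273, 529, 314))
    aut[has_b] <- sample(c("1", "2", "3", "S"), length(has_b), replace = TRUE,
                         prob = c(144, 219, 472, 119))

    flag <- function(pool, frac) {
      f <- rep(FALSE, n)
      k <- round(frac * length(pool))
      if (k > 0) f[sample(pool, k)] <- TRUE
      f
    }
    universe <- data.frame(
      gene = genes,
      epilepsy_subgroup = epi,
      autism_subgroup = aut,
      planted_module = planted,
      wes_epilepsy = flag(has_a, 0.25),
      wes_autism = flag(has_b, 0.25),
      bd = flag(idx, 0.10),
      scz = flag(idx, 0.10),
      id = flag(idx, 0.10),
      beg = flag(idx, 0.30),
      stringsAsFactors = FALSE
    )
    class(universe) <- c("gene_universe", "data.frame")
    universe
  })
}

#' @rdname generate_universe
#' @param universe A `gene_universe`.
#' @return `common_genes()`: character vector of genes carrying both disease
#'   labels.
#' @export
common_genes <- function(universe) {
  universe$gene[universe$epilepsy_subgroup != "none" & universe$autism_subgroup != "none"]
}

#' Named auxiliary and subgroup gene sets of a universe
#'
#' Collects the disease subgroup memberships, the common-gene set and the
#' auxiliary flags of a gene universe into a named list of gene vectors, the
#' shape consumed by [gene_group_enrichment()].
#'
#' @param universe A `gene_universe`.
#' @return Named list of character vectors.
#' @export
gene_groups <- function(universe) {
  g <- universe$gene
  out <- list(
    common = common_genes(universe),
    epilepsy_all = g[universe$epilepsy_subgroup != "none"],
    autism_all = g[universe$autism_subgroup != "none"]
  )
  for (s in c("1", "2", "3", "4")) {
    out[[paste0("epilepsy_", s)]] <- g[universe$epilepsy_subgroup == s]
  }
  for (s in c("1", "2", "3", "S")) {
    out[[paste0("autism_", s)]] <- g[universe$autism_subgroup == s]
  }
  for (f in c("wes_epilepsy", "wes_autism", "bd", "scz", "id", "beg")) {
    out[[f]] <- g[universe[[f]]]
  }
  out
}

#' Generate a STRING-style PPI edge table over a planted universe
#'
#' Every within-module gene pair receives an edge with probability `p_in` and
#' an integer confidence score drawn from 700-999 (so planted structure
#' survives the default confidence threshold); every between-module pair with
#' probability `p_out` and confidence uniform over 150-999 (so some edges fall
#' below it). Undirected, no self-loops, no duplicate pairs.
#'
#' @param universe A `gene_universe` with `planted_module`.
#' @param cfg The [simulation_config()] used.
#' @return `data.frame` with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
generate_ppi_edges <- function(universe, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .assert(!is.null(universe$planted_module), "universe must carry planted_module")
  n <- nrow(universe)
  .with_seed(.stage_seed(cfg, "edges"), {
    if (n < 2) {
      return(data.frame(gene_a = character(), gene_b = character(),
                        combined_score = integer(), stringsAsFactors = FALSE))
    }
    pr <- utils::combn(n, 2L)
    i <- pr[1L, ]; j <- pr[2L, ]
    same <- universe$planted_module[i] == universe$planted_module[j]
    keep <- stats::runif(length(i)) < ifelse(same, cfg$p_in, cfg$p_out)
    i <- i[keep]; j <- j[keep]; same <- same[keep]
    score <- integer(length(i))
    score[same] <- sample(700:999, sum(same), replace = TRUE)
    score[!same] <- sample(150:999, sum(!same), replace = TRUE)
    data.frame(gene_a = universe$gene[i], gene_b = universe$gene[j],
               combined_score = score, stringsAsFactors = FALSE)
  })
}

#' Generate a rooted phenotype ontology with marked subtrees
#'
#' Produces a rooted tree of `n_terms` terms under a single root
#' (`HP:ROOT`, standing for the "Phenotypic abnormality" root of a real
#' phenotype ontology). Two marked subtrees, rooted at `SEIZ:0001` and
#' `AUT:0001`, emulate the seizure and autistic-behaviour subtrees used for
#' phenotype enrichment; all remaining terms live under a generic `GEN:0001`
#' branch or one of the marked branches, attached to a random parent within
#' their branch.
#'
#' @param cfg A [simulation_config()].
#' @return `data.frame` of class `ontology_table` with columns `term_id`,
#'   `parent_id`; the root's parent is `"NONE"`.
#' @export
generate_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_terms
  .with_seed(.stage_seed(cfg, "ontology"), {
    root <- "HP:ROOT"
    term <- c(root, "SEIZ:0001", "AUT:0001")
    parent <- c("NONE", root, root)
    if (n >= 4L) {
      term <- c(term, "GEN:0001")
      parent <- c(parent, root)
    }
    counters <- c(SEIZ = 1L, AUT = 1L, GEN = 1L)
    branches <- if (n >= 4L) c("SEIZ", "AUT", "GEN") else c("SEIZ", "AUT")
    while (length(term) < n) {
      br <- branches[(length(term)) %% length(branches) + 1L]
      counters[[br]] <- counters[[br]] + 1L
      id <- sprintf("%s:%04d", br, counters[[br]])
      pool <- term[startsWith(term, br)]
      term <- c(term, id)
      parent <- c(parent, if (length(pool) == 1L) pool else sample(pool, 1L))
    }
    out <- data.frame(term_id = term, parent_id = parent, stringsAsFactors = FALSE)
    class(out) <- c("ontology_table", "data.frame")
    out
  })
}

#' Generate a gene-phenotype association score table with planted signal
#'
#' Each planted module receives `terms_per_module` characteristic terms,
#' disjoint across modules; module 1 draws its terms from the `SEIZ:` subtree
#' and module 2 from the `AUT:` subtree (falling back to generic terms if a
#' branch is exhausted), so phenotype-enrichment structure is planted
#' alongside edge structure. Member genes score `score_signal * U(0.5, 1.5)`
#' on their module's terms; every gene additionally scores
#' `score_noise * U(0.5, 1.5)` on `noise_terms_per_gene` random terms (none
#' when `score_noise = 0`). One positive skewness weight is drawn per term.
#'
#' @param universe A `gene_universe` with `planted_module`.
#' @param ontology An `ontology_table` from [generate_ontology()].
#' @param cfg The [simulation_config()] used.
#' @return `data.frame` of class `score_table` with columns `term_id`, `gene`,
#'   `score`, `skew`; `(term_id, gene)` pairs unique, one skew per term. The
#'   planted module-to-term map is attached as attribute `module_terms`.
#' @export
generate_scores <- function(universe, ontology, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .assert(!is.null(universe$planted_module), "universe must carry planted_module")
  terms <- ontology$term_id[ontology$parent_id != "NONE"]
  need <- cfg$n_modules * cfg$terms_per_module
  .assert(length(terms) >= need,
          "configuration error: not enough ontology terms for the planted modules")
  .with_seed(.stage_seed(cfg, "scores"), {
    avail <- terms
    module_terms <- vector("list", cfg$n_modules)
    pick <- function(pref, k) {
      pool <- avail[startsWith(avail, pref)]
      got <- if (length(pool) >= k) sample(pool, k) else
        c(pool, sample(setdiff(avail, pool), k - length(pool)))
      avail <<- setdiff(avail, got)
      got
    }
    for (m in seq_len(cfg$n_modules)) {
      pref <- if (m == 1L) "SEIZ" else if (m == 2L) "AUT" else "GEN"
      module_terms[[m]] <- pick(pref, cfg$terms_per_module)
    }

    rows <- list()
    for (m in seq_len(cfg$n_modules)) {
      members <- universe$gene[universe$planted_module == m]
      if (!length(members)) next
      grid <- expand.grid(term_id = module_terms[[m]], gene = members,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      grid$score <- cfg$score_signal * stats::runif(nrow(grid), 0.5, 1.5)
      rows[[length(rows) + 1L]] <- grid
    }
    if (cfg$score_noise > 0 && cfg$noise_terms_per_gene > 0) {
      k <- min(cfg$noise_terms_per_gene, length(terms))
      noise <- do.call(rbind, lapply(universe$gene, function(g) {
        data.frame(term_id = sample(terms, k), gene = g,
                   score = cfg$score_noise * stats::runif(k, 0.5, 1.5),
                   stringsAsFactors = FALSE)
      }))
      rows[[length(rows) + 1L]] <- noise
    }
    tab <- do.call(rbind, rows)
    tab <- tab[!duplicated(tab[c("term_id", "gene")]), , drop = FALSE]
    skew_by_term <- stats::runif(length(terms), 0.5, 2)
    names(skew_by_term) <- terms
    tab$skew <- unname(skew_by_term[tab$term_id])
    tab <- tab[order(tab$term_id, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("score_table", "data.frame")
    attr(tab, "module_terms") <- module_terms
    tab
  })
}

#' Generate the full synthetic input bundle
#'
#' Convenience wrapper running the four generator stages under one
#' configuration.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `universe`, `edges`, `ontology`, `scores`.
#' @export
simulate_bundle <- function(cfg) {
  universe <- generate_universe(cfg)
  ontology <- generate_ontology(cfg)
  list(
    universe = universe,
    edges = generate_ppi_edges(universe, cfg),
    ontology = ontology,
    scores = generate_scores(universe, ontology, cfg)
  )
}
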