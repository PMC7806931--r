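# Readers, writers and pipeline orchestration.
#
# All table dialects are plain TSV with '#' comment headers; gene symbols are
# standardized (trimmed, upper-cased) on read and duplicate gene rows are
# merged with label union.

.std_symbol <- function(x) toupper(trimws(x))

.check_columns <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("schema error in '%s': missing column(s) %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read the four pipeline input tables
#'
#' `read_gene_table()` reads the labelled gene list (columns `gene`,
#' `epilepsy_subgroup`, `autism_subgroup`, optional auxiliary flag columns
#' and `planted_module`); duplicate symbols are merged with label union
#' (a non-`"none"` subgroup wins; conflicting non-`"none"` labels keep the
#' first and emit a warning; flags are OR-ed). `read_edge_table()` reads a
#' 3-column confidence-scored PPI edge list, `read_ontology_table()` a
#' 2-column parent-child term table (root parent `"NONE"`), and
#' `read_score_table()` the 4-column gene-phenotype score table (one skew
#' value per term enforced).
#'
#' @param path File path (TSV, `#` comments allowed).
#' @return The corresponding validated object.
#' @export
read_gene_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("gene", "epilepsy_subgroup", "autism_subgroup"), path)
  df$gene <- .std_symbol(df$gene)
  for (col in c("epilepsy_subgroup", "autism_subgroup")) df[[col]] <- as.character(df[[col]])
  flags <- intersect(c("wes_epilepsy", "wes_autism", "bd", "scz", "id", "beg"), names(df))
  if (anyDuplicated(df$gene)) {
    merged <- lapply(split(seq_len(nrow(df)), df$gene), function(i) {
      row <- df[i[1L], , drop = FALSE]
      for (col in c("epilepsy_subgroup", "autism_subgroup")) {
        vals <- setdiff(unique(df[[col]][i]), "none")
        if (length(vals) > 1) {
          warning(sprintf("gene '%s': conflicting %s labels (%s); keeping '%s'",
                          row$gene, col, paste(vals, collapse = "/"), vals[1L]),
                  call. = FALSE)
        }
        row[[col]] <- if (length(vals)) vals[1L] else "none"
      }
      for (col in flags) row[[col]] <- any(df[[col]][i])
      row
    })
    df <- do.call(rbind, merged)
    df <- df[order(match(df$gene, unique(df$gene))), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("gene_universe", "data.frame")
  df
}

#' @rdname read_gene_table
#' @export
read_edge_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("gene_a", "gene_b", "combined_score"), path)
  df$gene_a <- .std_symbol(df$gene_a)
  df$gene_b <- .std_symbol(df$gene_b)
  if (!is.numeric(df$combined_score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$combined_score))))[1L]
    stop(sprintf("schema error in '%s': non-numeric combined_score at data row %d",
                 path, bad), call. = FALSE)
  }
  df
}

#' @rdname read_gene_table
#' @export
read_ontology_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("term_id", "parent_id"), path)
  roots <- df$term_id[df$parent_id == "NONE"]
  if (length(roots) != 1) {
    stop(sprintf("schema error in '%s': ontology must have exactly one root (found %d)",
                 path, length(roots)), call. = FALSE)
  }
  known <- c(df$term_id, "NONE")
  if (!all(df$parent_id %in% known)) {
    stop(sprintf("schema error in '%s': parent term '%s' is not defined",
                 path, setdiff(df$parent_id, known)[1L]), call. = FALSE)
  }
  class(df) <- c("ontology_table", "data.frame")
  df
}

#' @rdname read_gene_table
#' @export
read_score_table <- function(path) {
  df <- .read_tsv(path)
  .check_columns(df, c("term_id", "gene", "score", "skew"), path)
  df$gene <- .std_symbol(df$gene)
  .assert(is.numeric(df$score) && is.numeric(df$skew),
          sprintf("schema error in '%s': score and skew must be numeric", path))
  .assert(all(df$score >= 0) && all(df$skew >= 0),
          sprintf("schema error in '%s': scores and skews must be nonnegative", path))
  if (anyDuplicated(df[c("term_id", "gene")])) {
    stop(sprintf("schema error in '%s': duplicate (term_id, gene) rows", path),
         call. = FALSE)
  }
  nskew <- tapply(df$skew, df$term_id, function(s) length(unique(s)))
  if (any(nskew > 1)) {
    stop(sprintf("schema error in '%s': term '%s' has multiple skew values",
                 path, names(nskew)[nskew > 1][1L]), call. = FALSE)
  }
  class(df) <- c("score_table", "data.frame")
  df
}

#' @rdname read_gene_table
#' @param paths Named list/vector with elements `genes`, `edges`, `ontology`,
#'   `scores`.
#' @export
read_tables <- function(paths) {
  list(universe = read_gene_table(paths[["genes"]]),
       edges = read_edge_table(paths[["edges"]]),
       ontology = read_ontology_table(paths[["ontology"]]),
       scores = read_score_table(paths[["scores"]]))
}

.output_header <- function(seed, hash) {
  c(sprintf("# phenoplex %s", as.character(utils::packageVersion("phenoplex"))),
    sprintf("# seed=%s config_hash=%s", format(seed), hash))
}

.write_table <- function(df, path, seed = NA, hash = "none", sep = "\t") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(.output_header(seed, hash), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated fixture bundle to a directory
#'
#' Emits the four input tables in their TSV dialects (`genes.tsv`,
#' `edges.tsv`, `ontology.tsv`, `scores.tsv`), round-trippable through
#' [read_tables()].
#'
#' @param bundle List from [simulate_bundle()] (or equivalent).
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the file headers.
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(bundle$universe$gene)
  paths <- c(genes = file.path(dir, "genes.tsv"),
             edges = file.path(dir, "edges.tsv"),
             ontology = file.path(dir, "ontology.tsv"),
             scores = file.path(dir, "scores.tsv"))
  .write_table(bundle$universe, paths[["genes"]], seed, hash)
  .write_table(bundle$edges, paths[["edges"]], seed, hash)
  .write_table(bundle$ontology, paths[["ontology"]], seed, hash)
  .write_table(bundle$scores, paths[["scores"]], seed, hash)
  invisible(paths)
}

#' Export a layer (or the union of both layers) as GraphML
#'
#' @param x A `gp_layer` or `gp_multiplex` (union of the two layers, with a
#'   `layer` edge attribute).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(x, path) {
  g <- if (inherits(x, "gp_multiplex")) {
    e1 <- x$layers$ppi$edges; e2 <- x$layers$phenotype$edges
    ed <- rbind(cbind(e1, layer = "ppi"), cbind(e2, layer = "phenotype"))
    igraph::graph_from_data_frame(ed, directed = FALSE,
                                  vertices = data.frame(name = x$nodes))
  } else {
    layer_igraph(x)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with defaults matching the study's
#' settings: PPI confidence cut 700; top 1000 scoring genes per term for the
#' full-network profile (500 for the WES profile); 1000 shuffles / 10th
#' largest value for the phenotype edge threshold (nominal p = 0.01); equal
#' layer weights; resolution 1 with 1000 Louvain restarts; modules of at
#' least 2 genes with the 14 largest retained (WES: at least 5 genes);
#' 10,000-trial edge-overlap and empirical-enrichment ensembles, 1000-trial
#' partition-NMI ensemble; genome background 19,556.
#'
#' @param simulate Optional [simulation_config()]; when given, inputs are
#'   generated rather than read.
#' @param paths Named paths for [read_tables()] when not simulating.
#' @param ... Overrides of any default listed above (see source for names).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, ...) {
  cfg <- list(
    simulate = simulate, paths = paths,
    min_confidence = 700, top_k = 1000, top_k_wes = 500,
    root = "HP:ROOT",
    n_shuffles = 1000, rank = 10,
    layer_weights = c(0.5, 0.5),
    gamma = 1, resolutions = 1, n_restarts = 1000,
    min_size = 2, keep_top = 14,
    min_size_wes = 5, keep_top_wes = NULL,
    overlap_trials = 10000, nmi_trials = 1000,
    nmi_restarts = 20, null_restarts = 2,
    enrich_trials = 10000, genome_size = 19556,
    wes = FALSE, seed = 1L, out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown pipeline option(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  .assert(is.null(cfg$simulate) == !is.null(cfg$paths),
          "provide exactly one of 'simulate' or 'paths'")
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# build layers + multiplex for one gene set profile
.build_network <- function(universe, edges, ontology, scores, cfg, top_k, seed) {
  scores_f <- top_k_filter(scores, top_k)
  vectors <- build_phenotype_vectors(scores_f, ontology, cfg$root,
                                     genes = universe$gene)
  ppi <- build_ppi_layer(edges, universe, cfg$min_confidence)
  phen <- build_phenotype_layer(vectors, universe, cfg$n_shuffles, cfg$rank,
                                seed = seed)
  list(net = assemble_multiplex(ppi, phen, cfg$layer_weights),
       scores = scores_f, vectors = vectors)
}

#' Run the full multiplex gene-phenotype analysis pipeline
#'
#' Orchestrates every stage over one configuration: input generation or
#' reading, layer construction, layer-concordance tests, single-layer and
#' multiplex community detection, module filtering, gene-group enrichment
#' under both backgrounds, empirical phenotype enrichment over the marked
#' subtrees, centrality ranking of the common-gene-enriched modules and the
#' common-vs-specific centrality test; with `wes = TRUE`, a second network is
#' built from the WES-flagged genes, modules are matched across networks and
#' candidate genes extracted by the overlap rules. Deterministic given the
#' configured seed; when `out_dir` is set, every artifact is written with a
#' header carrying the tool version, seed and config hash.
#'
#' @param cfg A [pipeline_config()].
#' @return Named list of all intermediate and final results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  # hash the analysis settings only, not where the outputs land
  hash <- .config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])

  data <- .stage("inputs", {
    if (!is.null(cfg$simulate)) simulate_bundle(cfg$simulate) else read_tables(cfg$paths)
  })
  universe <- data$universe

  built <- .stage("network_construction",
                  .build_network(universe, data$edges, data$ontology, data$scores,
                                 cfg, cfg$top_k, cfg$seed))
  net <- built$net

  comparison <- .stage("layer_comparison", list(
    degree_correlation = degree_correlation(net$layers$ppi, net$layers$phenotype),
    edge_overlap = edge_overlap_test(net$layers$ppi, net$layers$phenotype,
                                     n_trials = cfg$overlap_trials, seed = cfg$seed),
    partition_nmi = partition_nmi_test(net$layers$ppi, net$layers$phenotype,
                                       n_trials = cfg$nmi_trials, gamma = cfg$gamma,
                                       seed = cfg$seed, n_restarts = cfg$nmi_restarts,
                                       null_restarts = cfg$null_restarts)
  ))

  params <- modularity_params(gamma = cfg$gamma, weights = cfg$layer_weights,
                              n_restarts = cfg$n_restarts,
                              resolutions = unique(c(cfg$resolutions, cfg$gamma)),
                              seed = cfg$seed)
  partitions <- .stage("community_detection", list(
    multiplex = louvain_multiplex(net, params),
    ppi = louvain_single(net$layers$ppi, params),
    phenotype = louvain_single(net$layers$phenotype, params)
  ))
  modules <- filter_modules(partitions$multiplex, cfg$min_size, cfg$keep_top)

  groups <- gene_groups(universe)
  enrichment <- .stage("enrichment", {
    terms <- character(0)
    for (r in intersect(c("SEIZ:0001", "AUT:0001"), data$ontology$term_id)) {
      terms <- c(terms, hpo_subtree(data$ontology, r))
    }
    terms <- intersect(terms, unique(built$scores$term_id))
    list(
      gene_groups_network = gene_group_enrichment(modules, groups, universe$gene,
                                                  "network"),
      gene_groups_genome = gene_group_enrichment(modules, groups, universe$gene,
                                                 "genome", cfg$genome_size),
      phenotypes = if (length(terms)) {
        phenotype_enrichment_table(modules, terms, built$scores, universe$gene,
                                   n_trials = cfg$enrich_trials, seed = cfg$seed)
      }
    )
  })

  prioritization <- .stage("prioritization", {
    enet <- enrichment$gene_groups_network
    common_rows <- enet[enet$target == "common", , drop = FALSE]
    prioritized <- common_rows$module[common_rows$fdr < 0.05]
    list(
      prioritized_modules = prioritized,
      centrality = stats::setNames(
        lapply(prioritized, function(mn) {
          centrality_table(net, modules[[mn]], universe)
        }), prioritized),
      common_centrality = common_gene_centrality_test(net, universe)
    )
  })

  wes_results <- NULL
  if (isTRUE(cfg$wes)) {
    wes_results <- .stage("wes_profile", {
      sub <- universe[universe$wes_epilepsy | universe$wes_autism, , drop = FALSE]
      bw <- .build_network(sub, data$edges, data$ontology, data$scores, cfg,
                           cfg$top_k_wes, cfg$seed + 7L)
      pw <- louvain_multiplex(bw$net, params)
      mods_w <- filter_modules(pw, cfg$min_size_wes, cfg$keep_top_wes)
      enr_w <- gene_group_enrichment(mods_w, gene_groups(sub), sub$gene, "network")
      matches <- match_modules(partitions$multiplex, pw)

      pick_focus <- function(enr, prioritized, group) {
        rows <- enr[enr$module %in% prioritized & enr$target == group, , drop = FALSE]
        if (!nrow(rows)) return(NULL)
        rows$module[which.min(rows$p)]
      }
      common_w <- enr_w[enr_w$target == "common", , drop = FALSE]
      prio_w <- common_w$module[common_w$fdr < 0.05]
      focus_large <- pick_focus(enrichment$gene_groups_network,
                                prioritization$prioritized_modules, "epilepsy_1")
      focus_wes <- pick_focus(enr_w, prio_w, "epilepsy_1")
      candidates <- NULL
      if (!is.null(focus_large) && !is.null(focus_wes)) {
        overlap <- intersect(modules[[focus_large]], mods_w[[focus_wes]])
        primary <- candidate_genes(overlap, universe, "epilepsy")
        secondary <- secondary_candidates(
          mods_w[[focus_wes]], partitions$multiplex,
          setdiff(prioritization$prioritized_modules, focus_large),
          universe, "epilepsy", exclude = primary)
        candidates <- list(overlap = overlap, primary = primary,
                           secondary = secondary,
                           focus_large = focus_large, focus_wes = focus_wes)
      }
      list(universe = sub, net = bw$net, partition = pw, modules = mods_w,
           enrichment = enr_w, matches = matches, candidates = candidates)
    })
  }

  result <- list(cfg = cfg, config_hash = hash, data = data, net = net,
                 comparison = comparison, partitions = partitions,
                 modules = modules, enrichment = enrichment,
                 prioritization = prioritization, wes = wes_results)

  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(result)
  result
}

.write_pipeline_outputs <- function(res) {
  cfg <- res$cfg
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed; hash <- res$config_hash
  p <- function(f) file.path(cfg$out_dir, f)

  cfg_out <- unclass(cfg)
  cfg_out$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  cfg_out$config_hash <- hash
  cfg_out$version <- as.character(utils::packageVersion("phenoplex"))
  jsonlite::write_json(cfg_out, p("config.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  .write_table(res$net$layers$ppi$edges, p("ppi_layer.tsv"), seed, hash)
  .write_table(res$net$layers$phenotype$edges, p("phenotype_layer.tsv"), seed, hash)
  for (nm in names(res$partitions)) {
    part <- res$partitions[[nm]]
    .write_table(data.frame(gene = names(part$membership),
                            module_id = as.integer(part$membership)),
                 p(sprintf("partition_%s.tsv", nm)), seed, hash)
  }
  jsonlite::write_json(res$partitions$multiplex$sweep, p("sweep.json"),
                       digits = NA, pretty = TRUE)
  write_null_test(res$comparison$edge_overlap, p("edge_overlap_test.json"))
  write_null_test(res$comparison$partition_nmi, p("partition_nmi_test.json"))
  jsonlite::write_json(list(degree_correlation = res$comparison$degree_correlation,
                            method = "spearman"),
                       p("degree_correlation.json"), auto_unbox = TRUE, digits = NA)
  .write_table(res$enrichment$gene_groups_network,
               p("enrichment_gene_groups_network.csv"), seed, hash, sep = ",")
  .write_table(res$enrichment$gene_groups_genome,
               p("enrichment_gene_groups_genome.csv"), seed, hash, sep = ",")
  if (!is.null(res$enrichment$phenotypes)) {
    .write_table(res$enrichment$phenotypes, p("enrichment_phenotypes.csv"),
                 seed, hash, sep = ",")
  }
  for (mn in names(res$prioritization$centrality)) {
    .write_table(res$prioritization$centrality[[mn]],
                 p(sprintf("centrality_module_%s.csv", mn)), seed, hash, sep = ",")
  }
  jsonlite::write_json(res$prioritization$common_centrality,
                       p("common_centrality_test.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(res$wes)) {
    .write_table(res$wes$matches, p("module_matches.csv"), seed, hash, sep = ",")
    .write_table(res$wes$enrichment, p("enrichment_wes_gene_groups.csv"),
                 seed, hash, sep = ",")
    if (!is.null(res$wes$candidates)) {
      cand <- res$wes$candidates
      df <- rbind(
        if (length(cand$primary)) data.frame(gene = cand$primary, rule = "overlap",
                                             stringsAsFactors = FALSE),
        if (nrow(cand$secondary)) data.frame(gene = cand$secondary$gene,
                                             rule = sprintf("secondary:module_%d",
                                                            cand$secondary$large_module),
                                             stringsAsFactors = FALSE)
      )
      if (is.null(df)) df <- data.frame(gene = character(), rule = character())
      .write_table(df, p("candidates.tsv"), seed, hash)
    }
  }
  invisible(cfg$out_dir)
}
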