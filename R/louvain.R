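#' Modularity optimisation parameters
#'
#' @param gamma Primary resolution parameter (> 0); larger values favour
#'   smaller communities.
#' @param weights Two nonnegative per-layer weights for the multiplex
#'   objective (ignored by single-layer optimisation).
#' @param n_restarts Independent restarts of the Louvain heuristic; the
#'   best-quality partition is kept, ties broken by the earliest restart.
#' @param resolutions Resolutions to sweep; must contain `gamma`, which
#'   designates the reported partition (quality at different resolutions is
#'   not directly comparable, so the sweep is recorded rather than collapsed).
#' @param seed Base seed; restart r uses `seed + r - 1`.
#' @return Object of class `modularity_params`.
#' @export
modularity_params <- function(gamma = 1, weights = c(0.5, 0.5),
                              n_restarts = 100, resolutions = gamma,
                              seed = 1L) {
  .assert(gamma > 0, "gamma must be positive")
  .assert(all(weights >= 0) && any(weights > 0),
          "layer weights must be nonnegative and not both zero")
  .assert(n_restarts >= 1, "n_restarts must be positive")
  .assert(gamma %in% resolutions, "resolutions must include the primary gamma")
  structure(list(gamma = gamma, weights = weights,
                 n_restarts = as.integer(n_restarts),
                 resolutions = sort(unique(resolutions)),
                 seed = as.integer(seed)),
            class = "modularity_params")
}

# dense symmetric adjacency of a layer (unit weights)
.layer_adjacency <- function(layer) {
  n <- length(layer$nodes)
  a <- matrix(0, n, n, dimnames = list(layer$nodes, layer$nodes))
  if (nrow(layer$edges)) {
    i <- match(layer$edges$from, layer$nodes)
    j <- match(layer$edges$to, layer$nodes)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

#' Newman-Girvan modularity of a partition at resolution gamma
#'
#' Evaluates `H = (1/2m) * sum_c (e_c - gamma * K_c^2 / (2m))`, where `e_c`
#' is the within-community sum of adjacency entries (twice the internal edge
#' count -- the convention under which the whole-graph single community
#' scores exactly 0 at `gamma = 1`), `m` the total edge count and `K_c` the
#' summed degree of community `c`. An empty layer scores 0.
#'
#' @param layer A `gp_layer`.
#' @param membership Integer community labels, either named by gene or in
#'   `layer$nodes` order.
#' @param gamma Resolution parameter.
#' @return Modularity value.
#' @export
modularity_score <- function(layer, membership, gamma = 1) {
  mem <- .align_membership(membership, layer$nodes)
  m <- nrow(layer$edges)
  if (m == 0) return(0)
  deg <- layer_degrees(layer)
  kc <- tapply(deg, mem, sum)
  mi <- mem[layer$edges$from]
  mj <- mem[layer$edges$to]
  within <- table(factor(mi[mi == mj], levels = names(kc)))
  ec <- 2 * as.numeric(within)
  sum(ec - gamma * as.numeric(kc)^2 / (2 * m)) / (2 * m)
}

.align_membership <- function(membership, nodes) {
  if (!is.null(names(membership))) {
    .assert(all(nodes %in% names(membership)),
            "membership must cover every node")
    mem <- membership[nodes]
  } else {
    .assert(length(membership) == length(nodes),
            "membership length must match the node count")
    mem <- membership
    names(mem) <- nodes
  }
  mem
}

#' Multiplex modularity: weighted sum of per-layer modularities
#'
#' `H = w_ppi * H_ppi + w_phenotype * H_phenotype` under one shared
#' partition; with equal weights both layers contribute equally.
#'
#' @param net A `gp_multiplex`.
#' @param membership Shared community labels (named by gene or in node order).
#' @param gamma Resolution parameter applied to both layers.
#' @param weights Per-layer weights; defaults to the network's.
#' @return Modularity value.
#' @export
multiplex_modularity <- function(net, membership, gamma = 1, weights = NULL) {
  w <- weights %||% net$weights
  sum(vapply(seq_along(net$layers), function(s) {
    w[[s]] * modularity_score(net$layers[[s]], membership, gamma)
  }, numeric(1)))
}

# One Louvain run over a list of aligned dense adjacency matrices maximising
# sum_s w_s/(2 m_s) sum_c (e_c^s - gamma K_c^s^2 / (2 m_s)). Local moves use
# the standard gain, aggregation collapses all layers by the same community
# map; self-loop weights accumulated during aggregation enter e_c but cannot
# change move gains, so they are carried in the matrices untouched.
.louvain_once <- function(a_list, w, gamma) {
  n0 <- nrow(a_list[[1L]])
  mapping <- seq_len(n0)

  repeat {
    n <- nrow(a_list[[1L]])
    two_m <- vapply(a_list, sum, numeric(1))
    live <- which(two_m > 0 & w > 0)
    if (!length(live)) break
    coef <- 2 * w[live] / two_m[live]            # per-layer gain scale
    k_list <- lapply(a_list[live], rowSums)
    ktot <- lapply(k_list, function(k) {
      kt <- numeric(n); kt[] <- 0
      kt
    })
    comm <- seq_len(n)
    for (s in seq_along(live)) ktot[[s]] <- k_list[[s]]  # one node per comm

    moved_any <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(n)) {
        a <- comm[i]
        # candidate communities: those adjacent to i in any live layer
        links <- vector("list", length(live))
        cand <- integer(0)
        for (s in seq_along(live)) {
          row <- a_list[[live[s]]][i, ]
          row[i] <- 0
          nb <- which(row > 0)
          if (length(nb)) {
            l <- rowsum(row[nb], comm[nb])
            links[[s]] <- stats::setNames(as.numeric(l), rownames(l))
            cand <- c(cand, as.integer(rownames(l)))
          } else {
            links[[s]] <- numeric(0)
          }
        }
        cand <- unique(c(cand, a))
        # remove i from its community
        for (s in seq_along(live)) ktot[[s]][a] <- ktot[[s]][a] - k_list[[s]][i]
        gain <- vapply(cand, function(cc) {
          g <- 0
          for (s in seq_along(live)) {
            l <- links[[s]][as.character(cc)]
            if (is.na(l)) l <- 0
            g <- g + coef[s] * (l - gamma * k_list[[s]][i] * ktot[[s]][cc] / two_m[live[s]])
          }
          g
        }, numeric(1))
        best <- cand[which.max(gain)]
        if (gain[match(best, cand)] <= gain[match(a, cand)] + 1e-12) best <- a
        for (s in seq_along(live)) ktot[[s]][best] <- ktot[[s]][best] + k_list[[s]][i]
        if (best != a) {
          comm[i] <- best
          improved <- TRUE
          moved_any <- TRUE
        }
      }
      if (!improved) break
    }

    labels <- sort(unique(comm))
    if (length(labels) == n || !moved_any) {
      mapping <- match(comm, labels)[mapping]
      break
    }
    comp <- match(comm, labels)
    mapping <- comp[mapping]
    a_list <- lapply(a_list, function(a) {
      b <- rowsum(a, comp)
      t(rowsum(t(b), comp))
    })
  }
  mapping
}

# order module ids by decreasing size, ties by lexicographically smallest
# member symbol; returns named membership with contiguous ids from 1
.canonical_membership <- function(mem, nodes) {
  names(mem) <- nodes
  sizes <- table(mem)
  first <- tapply(nodes, mem, function(g) min(g))
  ord <- order(-as.numeric(sizes), first)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- relabel[as.character(mem)]
  names(out) <- nodes
  out
}

.new_partition <- function(mem, nodes, quality, layer_quality, gamma, params,
                           sweep, method) {
  structure(list(
    membership = .canonical_membership(mem, nodes),
    quality = quality, layer_quality = layer_quality,
    gamma = gamma, params = params, sweep = sweep, method = method
  ), class = "gp_partition")
}

#' @export
print.gp_partition <- function(x, ...) {
  sz <- module_sizes(x)
  cat(sprintf("<gp_partition %s> %d nodes, %d modules (largest %s), H = %.4f at gamma = %g\n",
              x$method, length(x$membership), length(sz),
              paste(utils::head(sz, 5), collapse = "/"), x$quality, x$gamma))
  invisible(x)
}

#' @rdname louvain_single
#' @param partition A `gp_partition`.
#' @return `module_sizes()`: named integer vector, decreasing;
#'   `module_members()`: named list of gene vectors in the same order.
#' @export
module_sizes <- function(partition) {
  sz <- table(partition$membership)
  stats::setNames(as.integer(sz), names(sz))[order(as.integer(names(sz)))]
}

#' @rdname louvain_single
#' @export
module_members <- function(partition) {
  split(names(partition$membership), partition$membership)
}

.louvain_engine <- function(a_list, w, params, quality_fun) {
  sweep <- data.frame()
  best_primary <- NULL
  for (g in params$resolutions) {
    best <- NULL
    for (r in seq_len(params$n_restarts)) {
      mem <- .with_seed(params$seed + r - 1L,
                        .louvain_once(a_list, w, g))
      q <- quality_fun(mem, g)
      if (is.null(best) || q > best$q + 1e-12) best <- list(mem = mem, q = q)
    }
    sweep <- rbind(sweep, data.frame(gamma = g, quality = best$q,
                                     n_modules = length(unique(best$mem))))
    if (g == params$gamma) best_primary <- best
  }
  list(best = best_primary, sweep = sweep)
}

#' Louvain community detection
#'
#' `louvain_single()` maximises single-layer modularity
#' ([modularity_score()]) with `n_restarts` independent restarts at each
#' resolution in the sweep; `louvain_multiplex()` maximises the weighted
#' two-layer objective ([multiplex_modularity()]) under one partition shared
#' by both layers, which is how the implicit inter-layer coupling of each
#' node to itself is realised. The reported partition is the best restart at
#' the primary `gamma`; the full resolution sweep is recorded in `$sweep`.
#' The attained quality is recomputed independently from the returned
#' membership.
#'
#' @param layer A `gp_layer`.
#' @param params A [modularity_params()].
#' @return A `gp_partition`: named membership (module ids contiguous from 1,
#'   ordered by decreasing size then smallest member symbol), attained
#'   `quality`, per-layer qualities, the parameters and the sweep table.
#' @export
louvain_single <- function(layer, params = modularity_params()) {
  a <- .layer_adjacency(layer)
  res <- .louvain_engine(list(a), 1, params,
                         function(mem, g) modularity_score(layer, stats::setNames(mem, layer$nodes), g))
  q <- modularity_score(layer, stats::setNames(res$best$mem, layer$nodes), params$gamma)
  .new_partition(res$best$mem, layer$nodes, q,
                 stats::setNames(q, layer$name), params$gamma, params,
                 res$sweep, method = paste0("louvain:", layer$name))
}

#' @rdname louvain_single
#' @param net A `gp_multiplex`.
#' @export
louvain_multiplex <- function(net, params = modularity_params()) {
  a_list <- lapply(net$layers, .layer_adjacency)
  w <- params$weights %||% net$weights
  res <- .louvain_engine(a_list, w, params, function(mem, g) {
    multiplex_modularity(net, stats::setNames(mem, net$nodes), g, weights = w)
  })
  mem <- stats::setNames(res$best$mem, net$nodes)
  lq <- vapply(seq_along(net$layers), function(s) {
    modularity_score(net$layers[[s]], mem, params$gamma)
  }, numeric(1))
  names(lq) <- names(net$layers)
  .new_partition(res$best$mem, net$nodes, sum(w * lq), lq, params$gamma,
                 params, res$sweep, method = "louvain:multiplex")
}

#' Filter and order modules by size
#'
#' Returns the modules with at least `min_size` members, ordered by
#' decreasing size (module numbering already reflects that order), optionally
#' truncated to the `keep_top` largest.
#'
#' @param partition A `gp_partition`.
#' @param min_size Minimum module size retained.
#' @param keep_top Optional cap on the number of modules returned.
#' @return Named list of gene vectors.
#' @export
filter_modules <- function(partition, min_size = 2, keep_top = NULL) {
  mods <- module_members(partition)
  mods <- mods[order(-lengths(mods), as.integer(names(mods)))]
  mods <- mods[lengths(mods) >= min_size]
  if (!is.null(keep_top)) mods <- utils::head(mods, keep_top)
  mods
}
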