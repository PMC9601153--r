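# Synthetic graph-pair generator: random connected background graphs with a
# shared planted module (path or clique) at a controlled weight contrast,
# rewired back to the requested density.

#' Generator parameters
#'
#' Bundles the five scan parameters of the benchmark generator. Defaults
#' mirror a typical metabolite co-perturbation use case: networks of a
#' thousand nodes with average unweighted degree 5, a module on 0.5% of the
#' nodes, planted as a clique at background contrast.
#'
#' @param n_nodes number of nodes (>= 5).
#' @param avg_degree average unweighted node degree; at least
#'   `2 * (n_nodes - 1) / n_nodes` (a connected graph's floor).
#' @param module_fraction fraction of nodes in the module S, in (0, 1];
#'   `round(module_fraction * n_nodes)` must be at least 2.
#' @param contrast requested ratio of mean planted-edge weight to mean
#'   background-edge weight (>= 0).
#' @param pattern planted pattern: `"path"` or `"clique"`.
#' @param seed integer seed; the whole generation pipeline is deterministic
#'   given it.
#' @return a `gen_params` list.
#' @export
gen_params <- function(n_nodes = 1000, avg_degree = 5, module_fraction = 0.005,
                       contrast = 1.0, pattern = c("clique", "path"),
                       seed = 1L) {
  pattern <- match.arg(pattern)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 5) stop("n_nodes must be at least 5")
  if (avg_degree < 2 * (n_nodes - 1) / n_nodes) {
    stop("avg_degree below connectivity floor 2*(n-1)/n = ",
         format(2 * (n_nodes - 1) / n_nodes))
  }
  if (module_fraction <= 0 || module_fraction > 1) {
    stop("module_fraction must be in (0, 1]")
  }
  if (round(module_fraction * n_nodes) < 2) {
    stop("module_fraction too small: round(module_fraction * n_nodes) must be >= 2")
  }
  if (contrast < 0) stop("contrast must be nonnegative")
  structure(list(n_nodes = n_nodes, avg_degree = avg_degree,
                 module_fraction = module_fraction, contrast = contrast,
                 pattern = pattern, seed = as.integer(seed)),
            class = "gen_params")
}

node_labels_for <- function(n) {
  sprintf("n%0*d", nchar(as.character(n)), seq_len(n))
}

#' Random connected weighted graph
#'
#' Generates a uniformly random labeled spanning tree, then adds edges
#' sampled uniformly from the absent pairs until the edge count reaches
#' `round(n_nodes * avg_degree / 2)`. Weights are i.i.d. Uniform(0.5, 1.5)
#' (positive, bounded, mean 1, so contrast ratios read directly). This
#' construction has predictable runtime at the price of a slight bias in the
#' graph distribution.
#'
#' @inheritParams gen_params
#' @return a connected weighted igraph object with labels `n001, n002, ...`.
#' @export
random_connected_graph <- function(n_nodes, avg_degree, seed) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  m <- round(n_nodes * avg_degree / 2)
  if (m < n_nodes - 1) {
    stop("avg_degree below connectivity floor: ", m, " edges requested, ",
         n_nodes - 1, " needed for a spanning tree")
  }
  if (m > n_nodes * (n_nodes - 1) / 2) {
    stop("requested edges exceed n*(n-1)/2")
  }
  withr::with_seed(as.integer(seed), {
    tree <- igraph::sample_tree(n_nodes, directed = FALSE, method = "prufer")
    el <- igraph::as_edgelist(tree, names = FALSE)
    have <- new.env(hash = TRUE, size = 2L * m)
    ekey <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
    for (r in seq_len(nrow(el))) assign(ekey(el[r, 1], el[r, 2]), TRUE, envir = have)
    extra_i <- integer(0); extra_j <- integer(0)
    need <- m - (n_nodes - 1L)
    while (need > 0L) {
      i <- sample.int(n_nodes, 1L)
      j <- sample.int(n_nodes, 1L)
      if (i == j) next
      k <- ekey(i, j)
      if (exists(k, envir = have, inherits = FALSE)) next
      assign(k, TRUE, envir = have)
      extra_i <- c(extra_i, i); extra_j <- c(extra_j, j)
      need <- need - 1L
    }
    lab <- node_labels_for(n_nodes)
    from <- lab[c(el[, 1], extra_i)]
    to <- lab[c(el[, 2], extra_j)]
    weighted_graph(data.frame(from = from, to = to,
                              weight = runif(m, 0.5, 1.5),
                              stringsAsFactors = FALSE),
                   nodes = lab)
  })
}

pattern_edges <- function(S, pattern) {
  lab <- sort(module_labels(S))
  if (length(lab) < 2) stop("module must contain at least 2 nodes to plant")
  if (pattern == "path") {
    cbind(lab[-length(lab)], lab[-1])
  } else {
    t(utils::combn(lab, 2))
  }
}

#' Plant a path or clique module into a graph
#'
#' Adds any missing pattern edges over the module nodes (path edges follow
#' the module's label-sorted order), then sets every planted edge's weight to
#' `contrast` times the mean background (non-planted) edge weight, so the
#' realized mean-weight ratio equals `contrast` exactly.
#'
#' @param g weighted igraph object.
#' @param S node module (labels in `g`), size at least 2.
#' @param pattern `"path"` or `"clique"`.
#' @param contrast requested planted/background mean-weight ratio.
#' @return list with `g` (the planted graph) and `S` (the module carrying its
#'   `planted_edges` record).
#' @export
plant_module <- function(g, S, pattern = c("clique", "path"), contrast = 1.0) {
  pattern <- match.arg(pattern)
  assert_weighted_graph(g)
  lab <- module_labels(S)
  if (!all(lab %in% igraph::V(g)$name)) stop("module labels must be nodes of g")
  pe <- pattern_edges(S, pattern)
  ids <- igraph::get_edge_ids(g, t(pe), error = FALSE)
  missing <- which(ids == 0)
  if (length(missing)) {
    g <- igraph::add_edges(g, t(pe[missing, , drop = FALSE]),
                           attr = list(weight = 0))
    ids <- igraph::get_edge_ids(g, t(pe), error = FALSE)
  }
  w <- igraph::E(g)$weight
  bg <- setdiff(seq_along(w), ids)
  if (!length(bg)) stop("no background edges left to set the contrast against")
  igraph::E(g)$weight[ids] <- contrast * mean(w[bg])
  list(g = g, S = node_module(lab, planted_edges = pe))
}

#' Measure the planted-module weight contrast
#'
#' Ratio of the mean weight over the planted edges to the mean weight over
#' all remaining edges. Only planted edges count on the module side: the
#' S-induced subgraph may contain background edges, which stay in the
#' denominator.
#'
#' @param g weighted igraph object.
#' @param planted_edges two-column character matrix of planted edges (as
#'   recorded on a module by [plant_module()]).
#' @return the realized contrast ratio.
#' @export
measure_contrast <- function(g, planted_edges) {
  assert_weighted_graph(g)
  if (is.null(planted_edges) || nrow(planted_edges) == 0) {
    stop("planted_edges must be non-empty")
  }
  ids <- igraph::get_edge_ids(g, t(planted_edges), error = FALSE)
  if (any(ids == 0)) stop("planted edges missing from the graph")
  w <- igraph::E(g)$weight
  bg <- setdiff(seq_along(w), ids)
  if (!length(bg)) stop("no non-planted edges to compare against")
  mean(w[ids]) / mean(w[bg])
}

#' Prune a graph back to a target edge count
#'
#' Removes non-protected, non-bridge edges uniformly at random until the edge
#' count equals `target_edge_count`, so the graph stays connected and the
#' planted pattern is untouched. Planting can only add edges, so pruning is
#' the only direction needed.
#'
#' @param g weighted igraph object.
#' @param target_edge_count wanted edge count (at most the current count).
#' @param protected_edges optional two-column character matrix of edges that
#'   must not be removed.
#' @param seed integer seed.
#' @return the pruned graph.
#' @export
rewire_to_density <- function(g, target_edge_count, protected_edges = NULL,
                              seed = 1L) {
  assert_weighted_graph(g)
  if (igraph::ecount(g) < target_edge_count) {
    stop("graph has fewer edges (", igraph::ecount(g), ") than the target (",
         target_edge_count, ")")
  }
  withr::with_seed(as.integer(seed), {
    while (igraph::ecount(g) > target_edge_count) {
      prot <- rep(FALSE, igraph::ecount(g))
      if (!is.null(protected_edges) && nrow(protected_edges)) {
        ids <- igraph::get_edge_ids(g, t(protected_edges), error = FALSE)
        prot[ids[ids > 0]] <- TRUE
      }
      candidates <- setdiff(which(!prot), igraph::bridges(g))
      if (!length(candidates)) {
        stop("cannot reach target edge count ", target_edge_count,
             ": every remaining edge is protected or a bridge (",
             igraph::ecount(g), " edges left)")
      }
      drop <- candidates[sample.int(length(candidates), 1L)]
      g <- igraph::delete_edges(g, drop)
    }
  })
  g
}

#' Generate a synthetic proposer/tester graph pair with a shared module
#'
#' Pipeline: two independent connected background graphs are generated from
#' sub-seeds derived from `params$seed`; a shared module S of size
#' `round(module_fraction * n_nodes)` is drawn uniformly; the same pattern is
#' planted in both graphs at the same contrast; each graph is pruned back to
#' the background edge count. The whole pipeline is deterministic given the
#' seed.
#'
#' @param params a [gen_params()] object.
#' @return list with `g1`, `g2` (weighted igraph objects), `S` (the module,
#'   carrying `planted_edges`), `params`, and the realized contrasts
#'   `contrast_planted` (after planting; equals the request up to rounding
#'   error) and `realized_contrast` (after pruning, per graph).
#' @export
generate_pair <- function(params) {
  stopifnot(inherits(params, "gen_params"))
  p <- params
  # independent sub-seeds, kept within 32-bit integer range
  sub <- (as.numeric(p$seed) * 7 + c(1, 2, 3, 4, 5)) %% 2147483647
  m_target <- round(p$n_nodes * p$avg_degree / 2)
  g1 <- random_connected_graph(p$n_nodes, p$avg_degree, seed = sub[1])
  g2 <- random_connected_graph(p$n_nodes, p$avg_degree, seed = sub[2])
  s_size <- round(p$module_fraction * p$n_nodes)
  if (s_size < 2) stop("module size ", s_size, " too small; need at least 2")
  lab <- igraph::V(g1)$name
  S <- withr::with_seed(as.integer(sub[3]), node_module(sample(lab, s_size)))
  p1 <- plant_module(g1, S, pattern = p$pattern, contrast = p$contrast)
  p2 <- plant_module(g2, S, pattern = p$pattern, contrast = p$contrast)
  S <- p1$S
  pe <- attr(S, "planted_edges")
  c1 <- measure_contrast(p1$g, pe)
  c2 <- measure_contrast(p2$g, pe)
  g1 <- rewire_to_density(p1$g, m_target, protected_edges = pe, seed = sub[4])
  g2 <- rewire_to_density(p2$g, m_target, protected_edges = pe, seed = sub[5])
  list(g1 = g1, g2 = g2, S = S, params = p,
       contrast_planted = c(g1 = c1, g2 = c2),
       realized_contrast = c(g1 = measure_contrast(g1, pe),
                             g2 = measure_contrast(g2, pe)))
}

#' Write a generated pair as a file bundle
#'
#' Two edge-list files, one module file and a JSON sidecar with the
#' generator parameters and realized statistics.
#'
#' @param pair result of [generate_pair()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_pair_bundle <- function(pair, dir, prefix = "pair") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_g1.edges", "_g2.edges",
                                           "_module.txt", "_meta.json")))
  write_weighted_graph(pair$g1, paths[1])
  write_weighted_graph(pair$g2, paths[2])
  write_node_module(pair$S, paths[3])
  meta <- c(unclass(pair$params),
            list(contrast_planted = as.list(pair$contrast_planted),
                 realized_contrast = as.list(pair$realized_contrast),
                 planted_edges = apply(attr(pair$S, "planted_edges"), 1,
                                       paste, collapse = " ")))
  jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
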