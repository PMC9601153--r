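# Single-pair scoring workflow (proposer proposes S, tester scores it) and
# the parameter-scan driver over the synthetic generator grid.

#' Score a node module against a proposer/tester graph pair
#'
#' Applies [absolute_weights()] to both graphs, harmonizes their node sets,
#' encodes the module in the proposer (`g1`) and the tester (`g2`) with
#' [encode_module()], and returns the weighted-Bonferroni bound from
#' [pair_bound()]. The roles are asymmetric: only the tester's node count
#' enters the null length, so swapping `g1` and `g2` generally changes the
#' bound.
#'
#' @param g1 proposer graph.
#' @param g2 tester graph.
#' @param S node module.
#' @param harmonization `"removal"` (drop module nodes missing from the
#'   tester, and from the proposer), `"isolation"` (extend both graphs to the
#'   union label set with isolated nodes) or `"none"` (require the module in
#'   both graphs as given).
#' @return a `ctd_significance` (see [pair_bound()]) with the encodings
#'   attached as attributes `enc1` and `enc2`.
#' @examples
#' pair <- generate_pair(gen_params(n_nodes = 100, avg_degree = 5,
#'                                  module_fraction = 0.05, contrast = 2,
#'                                  pattern = "clique", seed = 7))
#' score_pair(pair$g1, pair$g2, pair$S)
#' @export
score_pair <- function(g1, g2, S,
                       harmonization = c("removal", "isolation", "none")) {
  harmonization <- match.arg(harmonization)
  g1 <- absolute_weights(g1)
  g2 <- absolute_weights(g2)
  if (harmonization == "removal") {
    h <- harmonize_by_removal(g1, g2, S)
    g1 <- h$g1; S <- h$S
  } else if (harmonization == "isolation") {
    h <- harmonize_by_isolation(g1, g2)
    g1 <- h$g1; g2 <- h$g2
  }
  lab <- module_labels(S)
  ok1 <- all(lab %in% igraph::V(g1)$name)
  ok2 <- all(lab %in% igraph::V(g2)$name)
  if (!ok1 || !ok2) {
    stop("module labels missing from ", if (!ok1) "proposer" else "tester",
         " graph; use harmonization = \"removal\" or \"isolation\"")
  }
  enc1 <- encode_module(g1, S)
  enc2 <- encode_module(g2, S)
  res <- pair_bound(enc1, enc2)
  attr(res, "enc1") <- enc1
  attr(res, "enc2") <- enc2
  res
}

# stable, platform-independent hash of a parameter cell -> small integer
cell_hash <- function(key) {
  codes <- utf8ToInt(key)
  sum(codes * (seq_along(codes) %% 31 + 1)) %% 100003
}

#' Run a parameter scan over the synthetic generator grid
#'
#' Takes the Cartesian product of the axes, generates `replicates` graph
#' pairs per cell and scores each with [score_pair()]. Cells whose module
#' size falls below [min_module_size()] at the 0.05 level are skipped (the
#' closed-form pruning of the parameter space). Replicate seeds are
#' `base_seed + hash(cell) + replicate`, so records are reproducible and
#' independent of execution order or grid edits.
#'
#' @param grid named list of axes: `n_nodes`, `avg_degree`,
#'   `module_fraction`, `contrast`, `pattern`. Scalars are allowed.
#' @param replicates replicates per cell (>= 1).
#' @param base_seed integer base seed.
#' @param alpha significance threshold for the `significant` flag.
#' @return data frame of scan records: the cell parameters, `replicate`,
#'   `seed`, `module_size`, `skipped`, `realized_contrast` (tester graph),
#'   `log2_p_bound` and `significant`.
#' @export
run_scan <- function(grid, replicates = 20L, base_seed = 1L, alpha = 0.05) {
  stopifnot(replicates >= 1)
  axes <- grid[c("n_nodes", "avg_degree", "module_fraction", "contrast", "pattern")]
  if (any(vapply(axes, is.null, logical(1)))) {
    stop("grid must name axes n_nodes, avg_degree, module_fraction, contrast, pattern")
  }
  cells <- expand.grid(n_nodes = axes$n_nodes, avg_degree = axes$avg_degree,
                       module_fraction = axes$module_fraction,
                       contrast = axes$contrast, pattern = axes$pattern,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells) * replicates)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    s_size <- round(cell$module_fraction * cell$n_nodes)
    skip <- min_module_size(cell$n_nodes, alpha) > s_size
    key <- paste(cell$n_nodes, cell$avg_degree, cell$module_fraction,
                 cell$contrast, cell$pattern, sep = "|")
    for (r in seq_len(replicates)) {
      k <- k + 1L
      seed <- (as.numeric(base_seed) + cell_hash(key) * 1009 + r) %% 2147483647
      rec <- data.frame(cell, replicate = r, seed = seed,
                        module_size = s_size, skipped = skip,
                        realized_contrast = NA_real_,
                        log2_p_bound = NA_real_, significant = NA,
                        stringsAsFactors = FALSE)
      if (!skip) {
        pair <- generate_pair(gen_params(
          n_nodes = cell$n_nodes, avg_degree = cell$avg_degree,
          module_fraction = cell$module_fraction, contrast = cell$contrast,
          pattern = cell$pattern, seed = seed))
        res <- score_pair(pair$g1, pair$g2, pair$S, harmonization = "none")
        rec$realized_contrast <- unname(pair$realized_contrast["g2"])
        rec$log2_p_bound <- res$log2_p_bound
        rec$significant <- is_significant(res, alpha)
      }
      out[[k]] <- rec
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records
}

#' Summarize scan records per parameter cell
#'
#' @param records data frame from [run_scan()].
#' @return data frame with one row per cell: replicate count,
#'   `frac_significant` (NA for skipped cells) and `median_log2_p`.
#' @export
summarize_scan <- function(records) {
  if (!nrow(records)) stop("no scan records to summarize")
  keyvars <- c("n_nodes", "avg_degree", "module_fraction", "contrast", "pattern")
  key <- interaction(records[keyvars], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(records, key), function(d) {
    cbind(d[1, keyvars, drop = FALSE],
          data.frame(replicates = nrow(d),
                     skipped = all(d$skipped),
                     frac_significant = if (all(d$skipped)) NA_real_ else
                       mean(d$significant),
                     median_log2_p = if (all(d$skipped)) NA_real_ else
                       median(d$log2_p_bound)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$n_nodes, out$avg_degree, out$module_fraction,
            out$contrast, out$pattern), , drop = FALSE]
}

#' Read a scan configuration file
#'
#' YAML (or plain key: value) file with the five grid axes plus optional
#' `replicates` and `base_seed`.
#'
#' @param path file path.
#' @return list with `grid`, `replicates`, `base_seed`.
#' @export
read_scan_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("n_nodes", "avg_degree", "module_fraction", "contrast", "pattern")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("scan config missing axes: ", paste(missing, collapse = ", "))
  }
  list(grid = cfg[need],
       replicates = if (is.null(cfg$replicates)) 20L else as.integer(cfg$replicates),
       base_seed = if (is.null(cfg$base_seed)) 1L else as.integer(cfg$base_seed))
}
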