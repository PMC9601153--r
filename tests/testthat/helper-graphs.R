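# Small graph builders used across the suite.

path_graph <- function(labels, weight = 1) {
  weighted_graph(data.frame(from = labels[-length(labels)], to = labels[-1],
                            weight = weight, stringsAsFactors = FALSE))
}

clique_graph <- function(labels, weight = 1) {
  pairs <- t(combn(labels, 2))
  weighted_graph(data.frame(from = pairs[, 1], to = pairs[, 2],
                            weight = weight, stringsAsFactors = FALSE))
}

star_graph <- function(hub, leaves, weights) {
  weighted_graph(data.frame(from = hub, to = leaves, weight = weights,
                            stringsAsFactors = FALSE))
}

edges_df <- function(g) {
  df <- igraph::as_data_frame(g, what = "edges")
  key <- paste(pmin(df$from, df$to), pmax(df$from, df$to))
  df <- df[order(key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_graph <- function(g1, g2) {
  expect_setequal(igraph::V(g1)$name, igraph::V(g2)$name)
  expect_equal(edges_df(g1), edges_df(g2))
}
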