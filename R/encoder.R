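# Diffusion-based bitstring encoder for a node module S in a weighted graph.
#
# The walker starts at a module node (paid for with log2|V| bits), then
# repeatedly diffuses one unit of probability mass from the module nodes found
# so far and visits the unvisited node carrying the most mass, emitting bit 1
# if that node belongs to S and 0 otherwise. Nodes of S the walker never
# reaches are "hardcoded" at log2|V| bits each. The resulting
# alternate-hypothesis description length is
#
#   I_A = (|S| - found + 1) * log2(|V|) + l - 1
#
# with l the bitstring length and found the number of 1-bits.

# --- internal walker machinery (integer indices) ----------------------------

walker_context <- function(g) {
  assert_weighted_graph(g)
  n <- igraph::vcount(g)
  labels <- igraph::V(g)$name
  adj <- rep(list(integer(0)), n)
  adjw <- rep(list(numeric(0)), n)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- as.numeric(igraph::E(g)$weight)
    both_i <- c(el[, 1], el[, 2])
    both_j <- c(el[, 2], el[, 1])
    both_w <- c(w, w)
    o <- order(both_i)
    runs <- split(seq_along(both_i)[o], both_i[o])
    for (k in names(runs)) {
      i <- as.integer(k)
      adj[[i]] <- both_j[runs[[k]]]
      adjw[[i]] <- both_w[runs[[k]]]
    }
  }
  list(n = n, labels = labels, adj = adj, adjw = adjw,
       rank = order(labels))  # rank[i] gives i-th smallest label's index
}

# Spread one unit of mass from `frontier` (indices, subset of visited) onto
# unvisited nodes. Each frontier node gets an equal share; the share splits
# over its unvisited neighbors proportionally to edge weight. A frontier node
# with no (positively weighted) unvisited neighbor passes its share through
# its visited neighbors, one level deep, onto their unvisited neighbors;
# anything that cannot be forwarded is lost.
diffuse_idx <- function(ctx, visited, frontier) {
  masses <- numeric(ctx$n)
  share <- 1 / length(frontier)
  for (f in frontier) {
    nb <- ctx$adj[[f]]
    wt <- ctx$adjw[[f]]
    if (!length(nb)) next
    unv <- !visited[nb]
    tw <- sum(wt[unv])
    if (tw > 0) {
      idx <- nb[unv]
      masses[idx] <- masses[idx] + share * wt[unv] / tw
    } else {
      vis <- visited[nb] & wt > 0
      tv <- sum(wt[vis])
      if (tv <= 0) next
      vn <- nb[vis]; vw <- wt[vis]
      for (j in seq_along(vn)) {
        v <- vn[j]
        nb2 <- ctx$adj[[v]]
        wt2 <- ctx$adjw[[v]]
        unv2 <- !visited[nb2]
        tw2 <- sum(wt2[unv2])
        if (tw2 > 0) {
          idx2 <- nb2[unv2]
          masses[idx2] <- masses[idx2] + share * (vw[j] / tv) * wt2[unv2] / tw2
        }
      }
    }
  }
  masses
}

# argmax with deterministic tie-break by ascending label order
next_node_idx <- function(ctx, masses) {
  mx <- max(masses)
  cand <- which(masses == mx)
  if (length(cand) > 1L) cand <- cand[order(ctx$labels[cand])]
  cand[1L]
}

# --- public surface ---------------------------------------------------------

#' One step of probability diffusion
#'
#' Distributes one unit of probability mass from the frontier nodes onto the
#' unvisited part of the graph: each frontier node receives an equal share,
#' which it splits over its unvisited neighbors proportionally to edge
#' weight. A frontier node whose neighbors are all visited forwards its share
#' through them (one pass-through level) to their unvisited neighbors; mass
#' that cannot be forwarded is lost, so the returned masses sum to at most 1.
#'
#' @param g weighted igraph object.
#' @param visited character vector of visited node labels.
#' @param frontier character vector of labels to diffuse from; must be a
#'   subset of `visited`.
#' @return named numeric vector of masses over the unvisited nodes (zeros
#'   included).
#' @export
diffuse <- function(g, visited, frontier) {
  ctx <- walker_context(g)
  if (!length(frontier)) stop("frontier must not be empty")
  if (!all(frontier %in% visited)) stop("frontier must be a subset of visited")
  vi <- match(visited, ctx$labels)
  fi <- match(frontier, ctx$labels)
  if (anyNA(vi) || anyNA(fi)) stop("visited/frontier labels must be nodes of g")
  vis <- logical(ctx$n); vis[vi] <- TRUE
  m <- diffuse_idx(ctx, vis, fi)
  setNames(m[!vis], ctx$labels[!vis])
}

new_encoding <- function(start, bits, module_size, n_nodes) {
  l <- length(bits)
  found <- sum(bits == 1L)
  structure(
    list(start = start,
         bitstring = paste(bits, collapse = ""),
         l = l,
         found = found,
         module_size = module_size,
         n_nodes = n_nodes,
         I_A = (module_size - found + 1) * log2(n_nodes) + l - 1),
    class = "ctd_encoding"
  )
}

#' @export
print.ctd_encoding <- function(x, ...) {
  bs <- x$bitstring
  if (nchar(bs) > 40) bs <- paste0(substr(bs, 1, 40), "...")
  cat("Module encoding: start =", x$start,
      sprintf("| l = %d bits | found = %d of %d | I_A = %.4f bits\n",
              x$l, x$found, x$module_size, x$I_A))
  cat("  bitstring:", bs, "\n")
  invisible(x)
}

#' @export
format.ctd_encoding <- function(x, ...) {
  jsonlite::toJSON(x[c("start", "bitstring", "l", "found", "I_A")],
                   auto_unbox = TRUE, digits = NA)
}

walk_encode <- function(ctx, s_idx, start_idx, threshold) {
  visited <- logical(ctx$n)
  in_s <- logical(ctx$n); in_s[s_idx] <- TRUE
  visited[start_idx] <- TRUE
  frontier <- start_idx
  bits <- integer(ctx$n); bits[1L] <- 1L
  nbits <- 1L
  nfound <- 1L
  while (nfound < length(s_idx) && nbits < ctx$n) {
    masses <- diffuse_idx(ctx, visited, frontier)
    if (max(masses) < threshold) break
    nxt <- next_node_idx(ctx, masses)
    visited[nxt] <- TRUE
    nbits <- nbits + 1L
    if (in_s[nxt]) {
      bits[nbits] <- 1L
      nfound <- nfound + 1L
      frontier <- c(frontier, nxt)
    }
  }
  bits[seq_len(nbits)]
}

#' Encode a node module from a given start node
#'
#' Marks `start` visited (first bit 1), then repeatedly diffuses probability
#' mass from the module nodes found so far and visits the unvisited node of
#' maximal mass, appending bit 1 when the node belongs to `S` and 0
#' otherwise. The walk halts when all of `S` has been found, when the maximal
#' unvisited mass falls below `1/|V|^2`, or after `|V|` visits. Module nodes
#' never reached are accounted for by the hardcoding term of the description
#' length.
#'
#' @param g weighted igraph object.
#' @param S node module (labels must be nodes of `g`).
#' @param start a label of `S` to start from.
#' @return a `ctd_encoding`: list with `start`, `bitstring`, `l`, `found`,
#'   `module_size`, `n_nodes` and the description length `I_A` in bits.
#' @examples
#' g <- weighted_graph(data.frame(from = c("a", "b", "c", "d"),
#'                                to = c("b", "c", "d", "e"), weight = 1))
#' encode_from_start(g, node_module(letters[1:5]), "a")
#' @export
encode_from_start <- function(g, S, start) {
  ctx <- walker_context(g)
  lab <- module_labels(S)
  s_idx <- match(lab, ctx$labels)
  if (anyNA(s_idx)) {
    stop("module labels not in graph: ",
         paste(lab[is.na(s_idx)], collapse = ", "))
  }
  if (!start %in% lab) stop("start node '", start, "' is not in the module")
  start_idx <- match(start, ctx$labels)
  bits <- walk_encode(ctx, s_idx, start_idx, threshold = 1 / ctx$n^2)
  new_encoding(start, bits, module_size = length(lab), n_nodes = ctx$n)
}

#' Encode a node module with the best start node
#'
#' Runs [encode_from_start()] from every module node and returns the encoding
#' of minimal description length `I_A`; ties are broken by ascending label
#' order. The start identity is already paid for by the `log2(|V|)` term, so
#' the choice is decodable.
#'
#' @inheritParams encode_from_start
#' @return a `ctd_encoding`.
#' @export
encode_module <- function(g, S) {
  lab <- sort(module_labels(S))
  best <- NULL
  for (s in lab) {
    enc <- encode_from_start(g, S, s)
    if (is.null(best) || enc$I_A < best$I_A) best <- enc
  }
  best
}

#' Decode a walker bitstring back to the found node set
#'
#' Replays the deterministic walker (identical diffusion and tie-breaking)
#' from `start`, consuming the bits: each bit corresponds to the next visited
#' node, and 1-bits mark module members. Decoding the bitstring of an
#' encoding recovers exactly its found subset.
#'
#' @param g weighted igraph object.
#' @param start start node label.
#' @param bitstring character string of 0/1, beginning with "1".
#' @return a [node_module()] containing the 1-marked labels.
#' @export
decode <- function(g, start, bitstring) {
  ctx <- walker_context(g)
  bits <- as.integer(strsplit(bitstring, "")[[1]])
  if (!length(bits) || bits[1] != 1L || anyNA(bits) || any(!bits %in% 0:1)) {
    stop("bitstring must be a 0/1 string beginning with 1")
  }
  start_idx <- match(start, ctx$labels)
  if (is.na(start_idx)) stop("start node '", start, "' is not in the graph")
  threshold <- 1 / ctx$n^2
  visited <- logical(ctx$n); visited[start_idx] <- TRUE
  frontier <- start_idx
  found <- start_idx
  for (i in seq_along(bits)[-1]) {
    if (sum(visited) >= ctx$n) {
      stop("bitstring longer than the walker's natural halt")
    }
    masses <- diffuse_idx(ctx, visited, frontier)
    if (max(masses) < threshold) {
      stop("bitstring longer than the walker's natural halt")
    }
    nxt <- next_node_idx(ctx, masses)
    visited[nxt] <- TRUE
    if (bits[i] == 1L) {
      found <- c(found, nxt)
      frontier <- c(frontier, nxt)
    }
  }
  node_module(ctx$labels[found])
}

#' Power-set description-length sum (Kraft--McMillan check)
#'
#' Enumerates every non-empty node subset `A` of a small graph, encodes it
#' with [encode_module()], and returns the sum of `2^(-I_A(A))`. For a
#' uniquely decodable code this sum would be at most 1, licensing the
#' interpretation of `2^(-I_A)` as subset probabilities.
#'
#' @param g weighted igraph object with at most `max_nodes` nodes.
#' @param max_nodes guard against accidental exponential blow-up.
#' @return the numeric sum over all non-empty subsets.
#' @export
kraft_sum <- function(g, max_nodes = 12L) {
  assert_weighted_graph(g)
  n <- igraph::vcount(g)
  if (n > max_nodes) stop("kraft_sum enumerates 2^n subsets; n = ", n, " is too large")
  labels <- igraph::V(g)$name
  total <- 0
  for (mask in seq_len(2^n - 1)) {
    A <- labels[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    enc <- encode_module(g, node_module(A))
    total <- total + 2^(-enc$I_A)
  }
  total
}
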