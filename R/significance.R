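# Closed-form significance machinery: null description length, the weighted
# Bonferroni-corrected p-value bound for a module scored in a proposer/tester
# graph pair, the ideal-case bound, and the minimal detectable module size.

#' Null-hypothesis description length of a module
#'
#' Under the null, each of the `module_size` nodes is spelled out at
#' `log2(n_nodes)` bits. The formula assumes the module is small relative to
#' the graph (`module_size < 2 * n_nodes / log2(n_nodes)`).
#'
#' @param n_nodes number of nodes of the (tester) graph, at least 2.
#' @param module_size number of nodes in the module.
#' @return description length in bits: `module_size * log2(n_nodes)`.
#' @examples
#' null_encoding_length(1024, 5) # 50
#' @export
null_encoding_length <- function(n_nodes, module_size) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  if (module_size < 1) stop("module_size must be positive")
  if (module_size >= 2 * n_nodes / log2(n_nodes)) {
    stop("module too large for null-model formula: need module_size < ",
         "2 * n_nodes / log2(n_nodes) = ", format(2 * n_nodes / log2(n_nodes)))
  }
  module_size * log2(n_nodes)
}

#' Conservative log2 subset probability of an encoding
#'
#' The encoding-induced distribution on the power set of the proposer graph
#' assigns a subset `A` probability at least `2^(-I_A)`; this function
#' returns that conservative exponent, the weight used by the weighted
#' Bonferroni correction.
#'
#' @param enc a `ctd_encoding` (see [encode_module()]).
#' @return `-enc$I_A` (bits).
#' @export
subset_log2_probability <- function(enc) {
  stopifnot(inherits(enc, "ctd_encoding"))
  -enc$I_A
}

#' Weighted-Bonferroni p-value bound for a module in a graph pair
#'
#' Combines the module's description lengths in the proposer (`enc1`) and
#' tester (`enc2`) graphs:
#' `log2 p <= I_A(G1) + I_A(G2) - I_0(G2)`, with `I_0(G2)` the null length
#' in the tester. The bound may exceed 1; it is reported verbatim (a bound,
#' not a probability estimate) and simply reads "not significant".
#'
#' @param enc1 encoding of S in the proposer graph G1.
#' @param enc2 encoding of S in the tester graph G2.
#' @param n2 node count of the tester graph; defaults to `enc2$n_nodes`.
#' @param module_size size of S; defaults to the encodings' module size,
#'   which must agree between `enc1` and `enc2`.
#' @return object of class `ctd_significance`: list with `I_A_g1`, `I_A_g2`,
#'   `I_0_g2`, `log2_p_bound` and `p_bound`.
#' @seealso [is_significant()], [ideal_bound()]
#' @export
pair_bound <- function(enc1, enc2, n2 = enc2$n_nodes,
                       module_size = enc2$module_size) {
  stopifnot(inherits(enc1, "ctd_encoding"), inherits(enc2, "ctd_encoding"))
  if (enc1$module_size != enc2$module_size) {
    stop("encodings refer to modules of different sizes (",
         enc1$module_size, " vs ", enc2$module_size, ")")
  }
  i0 <- null_encoding_length(n2, module_size)
  log2p <- enc1$I_A + enc2$I_A - i0
  structure(
    list(I_A_g1 = enc1$I_A, I_A_g2 = enc2$I_A, I_0_g2 = i0,
         log2_p_bound = log2p, p_bound = 2^log2p),
    class = "ctd_significance"
  )
}

#' @export
print.ctd_significance <- function(x, ...) {
  cat(sprintf("I_A(G1) = %.4f bits, I_A(G2) = %.4f bits, I_0(G2) = %.4f bits\n",
              x$I_A_g1, x$I_A_g2, x$I_0_g2))
  cat(sprintf("log2 p-value bound = %.4f  (p <= %.4g)%s\n",
              x$log2_p_bound, x$p_bound,
              if (is_significant(x)) "  [significant at 0.05]" else ""))
  invisible(x)
}

#' Is a pair bound significant at a threshold?
#'
#' Compared on the log2 scale so that extremely small bounds do not underflow.
#'
#' @param x a `ctd_significance` from [pair_bound()] or [score_pair()].
#' @param alpha significance threshold (default 0.05).
#' @return logical.
#' @export
is_significant <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "ctd_significance"))
  x$log2_p_bound < log2(alpha)
}

#' Ideal-case p-value bound
#'
#' In the best case the bitstring encoding of S in both graphs contains all
#' of S and nothing else, so each description length collapses to
#' `log2(n) + |S| - 1` bits and the corrected bound simplifies to
#' `4 * (4 / n_nodes)^(module_size - 2)`. No realized encoding can beat this,
#' which makes it the detectability floor for a graph of a given size.
#'
#' @param n_nodes number of nodes, greater than 4.
#' @param module_size module size, at least 2.
#' @return the ideal p-value bound.
#' @examples
#' ideal_bound(1000, 3) # 0.016
#' @export
ideal_bound <- function(n_nodes, module_size) {
  if (n_nodes <= 4) stop("bound undefined for n_nodes <= 4")
  if (module_size < 2) stop("module_size must be at least 2")
  4 * (4 / n_nodes)^(module_size - 2)
}

#' Minimal discoverable module size
#'
#' The smallest module size whose ideal-case bound can reach a wanted
#' significance level in a graph of `n_nodes` nodes:
#' `|S| >= 2 + (2 - log2(p_wanted)) / (log2(n_nodes) - 2)`. A module below
#' this size can never be declared significant at `p_wanted` by the
#' compression bound, whatever its connectedness — which also licenses
#' skipping such cells in parameter scans.
#'
#' @param n_nodes number of nodes, greater than 4.
#' @param p_wanted wanted significance level in (0, 1].
#' @return the smallest integer module size satisfying the inequality.
#' @examples
#' min_module_size(1000, 0.05)   # 3
#' min_module_size(1000, 5e-10)  # 7
#' @export
min_module_size <- function(n_nodes, p_wanted) {
  if (n_nodes <= 4) stop("bound undefined: n_nodes must exceed 4")
  if (!is.numeric(p_wanted) || p_wanted <= 0 || p_wanted > 1) {
    stop("p_wanted must be in (0, 1]")
  }
  rhs <- 2 + (2 - log2(p_wanted)) / (log2(n_nodes) - 2)
  # "at least" semantics, with a guard against float noise at integer rhs
  as.integer(ceiling(rhs - 1e-9))
}

#' Construct the ideal encoding of a module
#'
#' The hypothetical best-case encoding (all of S found, nothing else
#' visited): bitstring of `module_size` ones, `I_A = log2(n_nodes) +
#' module_size - 1`. Useful for analytic cross-checks against
#' [ideal_bound()].
#'
#' @inheritParams ideal_bound
#' @return a `ctd_encoding`.
#' @export
ideal_encoding <- function(n_nodes, module_size) {
  stopifnot(n_nodes >= 2, module_size >= 1)
  new_encoding(start = NA_character_, bits = rep(1L, module_size),
               module_size = module_size, n_nodes = n_nodes)
}
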