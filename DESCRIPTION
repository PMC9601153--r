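Package: ctdpair
Title: Information-Theoretic Significance Bounds for Node Modules Shared
    between Weighted Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Upper bounds on the p-value of a candidate node module that is
    highly connected in two weighted, node-labeled graphs. One graph acts as
    a proposer whose diffusion-based bitstring encoding of the module induces
    a probability distribution on its power set via the Kraft-McMillan
    inequality; the other acts as a tester in which the module's
    connectedness is scored. Combining the two through a weighted Bonferroni
    correction yields a closed-form bound that avoids permutation testing.
    Includes the closed-form detectability limits (ideal-case bound and
    minimal discoverable module size), a planted-module random connected
    graph-pair generator for benchmarking, and a parameter-scan driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
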