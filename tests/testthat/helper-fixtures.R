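# Fixture factories: everything is generated in code at test time.

# Scaffold from an explicit edge table (2-column character matrix or data
# frame) plus optional isolated nodes; evidence defaults to two categories so
# fixtures survive the filtered path.
make_scaffold <- function(edges, nodes = NULL, evidence = "expA;expB") {
  edges <- as.matrix(edges)
  all_nodes <- unique(c(as.vector(edges), nodes))
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  igraph::V(g)$name <- all_nodes
  if (length(edges) > 0L) {
    idx <- rbind(match(edges[, 1L], all_nodes), match(edges[, 2L], all_nodes))
    g <- igraph::add_edges(g, as.vector(idx))
    igraph::E(g)$evidence <- rep_len(evidence, nrow(edges))
  }
  ppienrich:::scaffold_from_graph(g)
}

# Write an interactome TSV from row vectors (used for loader tests)
write_edge_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path)
  path
}

# Random simple graph as an edge table (for oracle-equivalence tests);
# igraph only generates, all checking goes through the plain edge table.
random_graph_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(3:30, 1L)
  p <- runif(1L, 0.05, 0.3)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(nodes, 2L))
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}

# Minimal enrichment-result stub for summary/pooling arithmetic tests
fake_result <- function(module_id, p = NULL, collection = "fake",
                        attrs = list(), observed = NULL,
                        skipped_reason = NULL, alpha = 0.05) {
  ppienrich:::new_mcn_enrich(
    module_id, collection = collection, attrs = attrs, mapped_n = 10L,
    n_unmapped = 0L, allow_external = TRUE, reps = 100L, alpha = alpha,
    seed = 1L, p = p, observed = observed, skipped_reason = skipped_reason)
}

full_p <- function(degree = 0.5, betweenness = 0.5, clustering = 0.5,
                   components = 0.5) {
  c(degree = degree, clustering = clustering, betweenness = betweenness,
    components = components)
}
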