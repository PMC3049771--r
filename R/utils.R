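# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so that seeded generators do not perturb the session.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Draw k child seeds (< 2^31) from a parent seed, for functions that need
# several independent reproducible streams.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max, k))
}

# Canonical (lexicographically sorted endpoint) edge table of a scaffold,
# ordered deterministically; the basis for hashing and round-trip output.
canonical_edges <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el) == 0L)
    return(data.frame(node_a = character(), node_b = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  ev <- igraph::edge_attr(graph, "evidence")
  if (is.null(ev)) ev <- rep("", nrow(el))
  ord <- order(a, b)
  data.frame(node_a = a[ord], node_b = b[ord], evidence = ev[ord],
             stringsAsFactors = FALSE)
}

# md5 of the canonical edge list (written to a tempfile; tools::md5sum is
# file-based). Used to key null-distribution caches.
scaffold_hash <- function(scaffold) {
  ed <- canonical_edges(scaffold$graph)
  iso <- setdiff(sort(igraph::V(scaffold$graph)$name),
                 unique(c(ed$node_a, ed$node_b)))
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf), add = TRUE)
  writeLines(c(paste(ed$node_a, ed$node_b, ed$evidence, sep = "\t"), iso), tf)
  unname(tools::md5sum(tf))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
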