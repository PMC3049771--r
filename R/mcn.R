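# Minimal connected network (MCN) construction and topological statistics.
#
# The base MCN of a gene list is the subgraph of the scaffold induced by the
# list members that map onto it; members without any surviving edge remain as
# singleton components. The extended MCN additionally admits external linker
# nodes: scaffold nodes outside the list that are adjacent to at least two
# distinct mapped members. Statistics are always computed within the MCN,
# never on the whole scaffold, and the resampling null uses the identical
# construction.

#' Build the minimal connected network of a gene list
#'
#' @param members character vector of identifiers (or a [gene_module]).
#' @param scaffold a `ppi_scaffold` from [read_interactome()] or the
#'   synthetic generators.
#' @param allow_external if `TRUE`, every scaffold node adjacent to at least
#'   two distinct mapped members is added to the network and flagged as an
#'   external linker (the "+node" analysis compensating incomplete lists).
#' @return An `mcn` object: the induced [igraph] subgraph (`graph`), the
#'   mapped members (`mapped`), list identifiers absent from the scaffold
#'   (`unmapped`), the external linker nodes (`external`) and
#'   `source_list_size` (number of mapped members, the N used to size-match
#'   the null).
#' @export
build_mcn <- function(members, scaffold, allow_external = FALSE) {
  if (inherits(members, "gene_module")) members <- members$members
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("`members` is empty", call. = FALSE)
  g <- scaffold$graph
  vnames <- igraph::V(g)$name
  mapped <- intersect(members, vnames)
  unmapped <- setdiff(members, mapped)
  if (length(mapped) == 0L)
    stop("unmappable module: no members map to the scaffold", call. = FALSE)

  external <- character()
  if (isTRUE(allow_external)) {
    midx <- match(mapped, vnames)
    nb <- igraph::adjacent_vertices(g, midx)
    cnt <- tabulate(unlist(lapply(nb, as.integer), use.names = FALSE),
                    nbins = igraph::vcount(g))
    cnt[midx] <- 0L
    external <- vnames[cnt >= 2L]
  }

  sub <- igraph::induced_subgraph(g, c(mapped, external))
  igraph::V(sub)$external <- igraph::V(sub)$name %in% external
  structure(list(graph = sub, mapped = mapped, unmapped = unmapped,
                 external = external,
                 source_list_size = length(mapped)),
            class = "mcn")
}

#' Connection degree of every MCN node
#'
#' Number of edges incident to each node within the MCN subgraph.
#'
#' @param mcn an `mcn` object.
#' @return Named integer vector.
#' @export
connection_degree <- function(mcn) {
  stopifnot(inherits(mcn, "mcn"))
  d <- igraph::degree(mcn$graph)
  stats::setNames(as.integer(d), igraph::V(mcn$graph)$name)
}

#' Local clustering coefficient of every MCN node
#'
#' `C(v) = e_n / (n_v (n_v - 1) / 2)` where `e_n` is the number of edges
#' among the neighbours of `v` and `n_v` the number of neighbours; nodes with
#' fewer than two neighbours get 0.
#'
#' @param mcn an `mcn` object.
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(mcn) {
  stopifnot(inherits(mcn, "mcn"))
  cc <- igraph::transitivity(mcn$graph, type = "localundirected",
                             isolates = "zero")
  stats::setNames(as.numeric(cc), igraph::V(mcn$graph)$name)
}

#' Relative betweenness centrality of every MCN node
#'
#' Betweenness `C_B(v)` sums, over unordered node pairs `s != t != v`, the
#' fraction of shortest `s`-`t` paths passing through `v` (unit edge weights;
#' pairs in different components contribute nothing). The relative form
#' normalizes by the maximum attainable value, `(n - 1)(n - 2) / 2`, with `n`
#' the total number of nodes in the MCN; it is defined as 0 when `n < 3`.
#'
#' @param mcn an `mcn` object.
#' @return Named numeric vector in `[0, 1]` (the relative betweenness).
#' @export
rel_betweenness <- function(mcn) {
  stopifnot(inherits(mcn, "mcn"))
  g <- mcn$graph
  n <- igraph::vcount(g)
  raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  out <- if (n < 3L) rep(0, n) else as.numeric(raw) / ((n - 1) * (n - 2) / 2)
  stats::setNames(out, igraph::V(g)$name)
}

#' Number of connected components of an MCN
#'
#' Counts maximal sets of mutually reachable nodes, including singleton
#' components (isolated mapped members).
#'
#' @param mcn an `mcn` object.
#' @return Integer component count.
#' @export
count_components <- function(mcn) {
  stopifnot(inherits(mcn, "mcn"))
  as.integer(igraph::components(mcn$graph)$no)
}

#' All four topological parameters of an MCN
#'
#' @param mcn an `mcn` object.
#' @return A `node_params` object: named vectors `degree`, `clustering`,
#'   `rel_betweenness` over the same node set, and the scalar `n_components`.
#' @export
node_params <- function(mcn) {
  stopifnot(inherits(mcn, "mcn"))
  structure(list(degree = connection_degree(mcn),
                 clustering = clustering_coefficient(mcn),
                 rel_betweenness = rel_betweenness(mcn),
                 n_components = count_components(mcn)),
            class = "node_params")
}

#' @export
print.mcn <- function(x, ...) {
  cat(sprintf("Minimal connected network: %d nodes (%d mapped members, %d external linkers), %d edges, %d components\n",
              igraph::vcount(x$graph), length(x$mapped), length(x$external),
              igraph::ecount(x$graph), count_components(x)))
  if (length(x$unmapped) > 0L)
    cat(sprintf("  %d list identifiers not in the scaffold\n",
                length(x$unmapped)))
  invisible(x)
}

#' Plot a minimal connected network
#'
#' Mapped members are drawn dark blue, external linker nodes pale blue.
#'
#' @param x an `mcn` object.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.mcn <- function(x, ...) {
  col <- ifelse(igraph::V(x$graph)$external, "lightblue", "steelblue4")
  igraph::plot.igraph(x$graph, vertex.color = col, vertex.size = 8,
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' @export
print.node_params <- function(x, ...) {
  cat(sprintf("MCN parameters over %d nodes: mean degree %.3g, mean clustering %.3g, mean rel. betweenness %.3g, %d components\n",
              length(x$degree), mean(x$degree), mean(x$clustering),
              mean(x$rel_betweenness), x$n_components))
  invisible(x)
}
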