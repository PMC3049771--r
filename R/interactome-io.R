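# Scaffold interactome input/output.
#
# The scaffold is an undirected simple graph with an optional set of
# evidence-category tags per edge (semicolon separated in the TSV). Two
# flavours are distinguished: the non-filtered scaffold keeps every
# interaction, the filtered scaffold keeps only interactions supported by at
# least two distinct evidence categories.

new_scaffold <- function(graph, filtered = FALSE, report = NULL) {
  structure(list(graph = graph, filtered = filtered, report = report),
            class = "ppi_scaffold")
}

# Wrap an igraph object (synthetic generators, tests). Vertices must be named;
# a missing `evidence` edge attribute is added empty.
scaffold_from_graph <- function(graph, filtered = FALSE) {
  if (is.null(igraph::V(graph)$name))
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  if (igraph::ecount(graph) > 0 &&
      is.null(igraph::edge_attr(graph, "evidence")))
    igraph::E(graph)$evidence <- ""
  new_scaffold(graph, filtered = filtered)
}

scaffold_nodes <- function(scaffold) igraph::V(scaffold$graph)$name

#' Read a scaffold interactome from an edge-list TSV
#'
#' The file holds one interaction per row: `node_a TAB node_b` with an
#' optional third column of semicolon-separated evidence-category tags.
#' Lines starting with `#` are ignored. Self-interactions are dropped,
#' duplicate rows are merged with the union of their evidence categories,
#' and -- when `min_evidence >= 1` -- edges supported by fewer than
#' `min_evidence` distinct categories are removed. A scaffold produced with
#' `min_evidence >= 2` is marked as filtered (the "at least two evidence
#' categories" confidence rule).
#'
#' @param path path to the TSV file.
#' @param min_evidence non-negative integer; minimum number of distinct
#'   evidence categories an edge needs to be kept. `0` (default) keeps all.
#' @param id_map optional identifier translation: a named character vector
#'   (`old -> new`) or a path to a two-column TSV (`old TAB new`). Applied to
#'   both endpoints at load time; identifiers without a mapping pass through
#'   unchanged.
#' @return A `ppi_scaffold` object: an undirected simple [igraph] graph with
#'   an `evidence` edge attribute, a `filtered` flag and a load `report`
#'   (counts of input rows, dropped self-edges, merged duplicates and edges
#'   removed by the evidence filter).
#' @seealso [write_interactome()] for the inverse operation.
#' @export
read_interactome <- function(path, min_evidence = 0, id_map = NULL) {
  if (!is_string(path) || !file.exists(path))
    stop("interactome file not found: ", path, call. = FALSE)
  min_evidence <- as.integer(min_evidence)
  if (is.na(min_evidence) || min_evidence < 0L)
    stop("`min_evidence` must be a non-negative integer", call. = FALSE)

  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty scaffold: no interaction rows in ", path, call. = FALSE)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed row at line %d: expected 2 or 3 tab-separated fields, found %d",
                 lineno[bad[1L]], nf[bad[1L]]), call. = FALSE)

  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  ev <- vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "", "")

  if (!is.null(id_map)) {
    map <- load_id_map(id_map)
    a <- translate_ids(a, map)
    b <- translate_ids(b, map)
  }

  n_rows <- length(a)
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; ev <- ev[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")

  cats <- strsplit(ev, ";", fixed = TRUE)
  cats <- lapply(cats, function(x) unique(trimws(x[nzchar(trimws(x))])))
  merged <- tapply(cats, key, function(l) sort(unique(unlist(l))),
                   simplify = FALSE)
  ukey <- names(merged)
  n_dup <- length(key) - length(ukey)

  n_cat <- lengths(merged)
  keep_edge <- if (min_evidence >= 1L) n_cat >= min_evidence else rep(TRUE, length(ukey))
  n_filtered <- sum(!keep_edge)
  if (!any(keep_edge))
    stop("empty scaffold: no edge has >= ", min_evidence,
         " distinct evidence categories", call. = FALSE)

  parts <- strsplit(ukey[keep_edge], "\r", fixed = TRUE)
  d <- data.frame(
    from = vapply(parts, `[[`, "", 1L),
    to = vapply(parts, `[[`, "", 2L),
    evidence = vapply(merged[keep_edge], paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(d, directed = FALSE)
  new_scaffold(
    g,
    filtered = min_evidence >= 2L,
    report = list(rows = n_rows, self_edges = n_self, duplicates = n_dup,
                  filtered_out = n_filtered)
  )
}

load_id_map <- function(id_map) {
  if (is.character(id_map) && length(id_map) == 1L && file.exists(id_map)) {
    d <- utils::read.table(id_map, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
    if (ncol(d) < 2L)
      stop("identifier map must have two tab-separated columns", call. = FALSE)
    return(stats::setNames(as.character(d[[2L]]), as.character(d[[1L]])))
  }
  if (is.character(id_map) && !is.null(names(id_map))) return(id_map)
  stop("`id_map` must be a named character vector or a two-column TSV path",
       call. = FALSE)
}

translate_ids <- function(x, map) {
  hit <- x %in% names(map)
  x[hit] <- unname(map[x[hit]])
  x
}

#' Write a scaffold interactome to an edge-list TSV
#'
#' Writes the canonical (sorted) edge list with evidence tags; reading the
#' file back with [read_interactome()] reproduces the scaffold exactly.
#'
#' @param scaffold a `ppi_scaffold`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(scaffold, path) {
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  ed <- canonical_edges(scaffold$graph)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("#node_a\tnode_b\tevidence", con)
  if (nrow(ed) > 0L)
    writeLines(paste(ed$node_a, ed$node_b, ed$evidence, sep = "\t"), con)
  invisible(path)
}

#' Export a minimal connected network in SIF format
#'
#' Writes `node_a TAB pp TAB node_b` rows plus a sidecar
#' `<path>.nodes.tsv` flagging which nodes are external linkers.
#'
#' @param mcn an `mcn` object from [build_mcn()].
#' @param path output path for the SIF file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(mcn, path) {
  stopifnot(inherits(mcn, "mcn"))
  ed <- canonical_edges(mcn$graph)
  writeLines(paste(ed$node_a, "pp", ed$node_b, sep = "\t"), path)
  nodes <- sort(igraph::V(mcn$graph)$name)
  side <- data.frame(node = nodes,
                     external = as.integer(nodes %in% mcn$external))
  utils::write.table(side, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ppi_scaffold <- function(x, ...) {
  cat(sprintf("PPI scaffold interactome: %d nodes, %d edges (%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (x$filtered) "filtered, >=2 evidence categories" else "non-filtered"))
  if (!is.null(x$report))
    cat(sprintf("  load report: %d rows, %d self-edges dropped, %d duplicates merged, %d edges below evidence threshold\n",
                x$report$rows, x$report$self_edges, x$report$duplicates,
                x$report$filtered_out))
  invisible(x)
}
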