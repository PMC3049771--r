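# Term annotations: a parent-child DAG of terms (GO-like), direct
# gene-to-term annotations, and optional term namespaces. Annotations are
# propagated upwards -- a gene annotated to a term is a member of every
# ancestor term too (the true-path rule) -- and the level of a term is its
# shortest parent-link distance to a namespace root (roots are level 0).

#' Build a term-annotation object
#'
#' @param dag_edges data frame (or 2-column matrix) of `child`, `parent`
#'   term pairs; must be acyclic.
#' @param gene2terms named list mapping gene identifiers to character vectors
#'   of directly annotated terms, or a data frame with columns `gene`, `term`.
#' @param namespaces optional named character vector (term -> namespace) or
#'   data frame with columns `term`, `namespace`.
#' @return A `term_annotation` object with components `dag_edges`, `parents`
#'   (term -> character vector of parents), `children`, `gene2terms`,
#'   `namespaces` and `roots` (terms without parents).
#' @export
term_annotation <- function(dag_edges, gene2terms, namespaces = NULL) {
  dag_edges <- as.data.frame(dag_edges, stringsAsFactors = FALSE)
  if (ncol(dag_edges) < 2L)
    stop("`dag_edges` needs two columns: child, parent", call. = FALSE)
  names(dag_edges)[1:2] <- c("child", "parent")
  dag_edges$child <- as.character(dag_edges$child)
  dag_edges$parent <- as.character(dag_edges$parent)

  if (is.data.frame(gene2terms)) {
    names(gene2terms)[1:2] <- c("gene", "term")
    gene2terms <- split(as.character(gene2terms$term),
                        as.character(gene2terms$gene))
  }
  gene2terms <- lapply(gene2terms, function(x) unique(as.character(x)))

  if (is.data.frame(namespaces)) {
    names(namespaces)[1:2] <- c("term", "namespace")
    namespaces <- stats::setNames(as.character(namespaces$namespace),
                                  as.character(namespaces$term))
  }

  terms <- unique(c(dag_edges$child, dag_edges$parent,
                    unlist(gene2terms, use.names = FALSE)))
  parents <- split(dag_edges$parent, dag_edges$child)
  parents <- lapply(parents, unique)
  children <- split(dag_edges$child, dag_edges$parent)
  children <- lapply(children, unique)
  roots <- setdiff(terms, dag_edges$child)

  ann <- structure(list(dag_edges = dag_edges[, 1:2], parents = parents,
                        children = children, gene2terms = gene2terms,
                        namespaces = namespaces, terms = terms, roots = roots),
                   class = "term_annotation")
  cyc <- find_dag_cycle(ann)
  if (!is.null(cyc))
    stop("term DAG contains a cycle: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  ann
}

# Kahn topological sort over parent links; returns one cycle (as a term path)
# if the DAG property is violated, else NULL.
find_dag_cycle <- function(ann) {
  terms <- ann$terms
  indeg <- stats::setNames(integer(length(terms)), terms)
  for (ch in names(ann$parents))
    indeg[ch] <- length(ann$parents[[ch]])
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in ann$children[[t]] %||% character()) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(terms)) return(NULL)
  # walk parent pointers inside the residual subgraph until a repeat
  resid <- names(indeg)[indeg > 0L]
  path <- resid[[1L]]
  repeat {
    nxt <- intersect(ann$parents[[path[length(path)]]], resid)[1L]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' Read term annotations from TSV files
#'
#' @param dag_path TSV of `child TAB parent` term pairs.
#' @param anno_path TSV of `gene TAB term` direct annotations.
#' @param namespace_path optional TSV of `term TAB namespace`.
#' @return A [term_annotation] object.
#' @export
read_term_annotation <- function(dag_path, anno_path, namespace_path = NULL) {
  read2 <- function(p, what) {
    if (!is_string(p) || !file.exists(p))
      stop(what, " file not found: ", p, call. = FALSE)
    utils::read.table(p, sep = "\t", header = FALSE, quote = "",
                      comment.char = "#", stringsAsFactors = FALSE,
                      col.names = c("a", "b"))
  }
  dag <- read2(dag_path, "DAG")
  anno <- read2(anno_path, "annotation")
  ns <- if (!is.null(namespace_path)) {
    d <- read2(namespace_path, "namespace")
    stats::setNames(d$b, d$a)
  }
  term_annotation(dag, data.frame(gene = anno$a, term = anno$b), ns)
}

# All ancestors (transitive parents) of every term, memoised.
term_ancestors <- function(ann) {
  memo <- new.env(parent = emptyenv())
  anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    ps <- ann$parents[[t]] %||% character()
    out <- unique(c(ps, unlist(lapply(ps, anc), use.names = FALSE)))
    memo[[t]] <- out
    out
  }
  stats::setNames(lapply(ann$terms, anc), ann$terms)
}

#' Propagate gene annotations up the term DAG
#'
#' Applies the true-path rule: a gene directly annotated to a term is made a
#' member of that term and of all its ancestors. Propagating an already
#' propagated map is a no-op.
#'
#' @param ann a [term_annotation] object.
#' @return Named list: term -> character vector (sorted, unique) of annotated
#'   genes after propagation. Terms with no genes are omitted.
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "term_annotation"))
  anc <- term_ancestors(ann)
  acc <- new.env(parent = emptyenv())
  for (g in names(ann$gene2terms)) {
    terms <- ann$gene2terms[[g]]
    all_terms <- unique(c(terms, unlist(anc[terms], use.names = FALSE)))
    for (t in all_terms) acc[[t]] <- c(acc[[t]], g)
  }
  out <- lapply(as.list(acc), function(x) sort(unique(x)))
  out[order(names(out))]
}

#' Level of a term in its DAG
#'
#' The level is the shortest-path distance, counted in parent links, from the
#' term to a root of the DAG (a term with no parents). Roots have level 0.
#' Deeper levels correspond to more specific terms.
#'
#' @param ann a [term_annotation] object.
#' @param term term identifier.
#' @return Integer level.
#' @export
term_level <- function(ann, term) {
  stopifnot(inherits(ann, "term_annotation"))
  if (!term %in% ann$terms)
    stop("unknown term: ", term, call. = FALSE)
  # BFS upward over parent links
  frontier <- term
  level <- 0L
  visited <- character()
  while (length(frontier) > 0L) {
    if (any(frontier %in% ann$roots)) return(level)
    visited <- c(visited, frontier)
    frontier <- setdiff(
      unique(unlist(ann$parents[frontier], use.names = FALSE)), visited)
    level <- level + 1L
  }
  stop("term ", term, " has no path to a root", call. = FALSE)
}

#' @export
print.term_annotation <- function(x, ...) {
  cat(sprintf("Term annotation: %d terms, %d DAG edges, %d annotated genes, %d roots\n",
              length(x$terms), nrow(x$dag_edges), length(x$gene2terms),
              length(x$roots)))
  invisible(x)
}
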