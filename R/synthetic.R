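# Synthetic benchmark generators with known ground truth.
#
# Real interactome releases age quickly; the generators emulate the
# statistical structure the pipeline consumes instead: (i) a sparse
# heavy-tailed scaffold (preferential attachment; Erdos-Renyi kept for
# calibration settings where the uniform null is exact), (ii) cohesive
# planted modules with elevated internal edge density, (iii) unstructured
# uniform gene lists, and (iv) modules whose two halves reconnect only
# through one non-member hub.

#' Specification of a synthetic benchmark
#'
#' @param n_nodes scaffold size.
#' @param mean_degree target mean degree of the scaffold.
#' @param model `"preferential_attachment"` (heavy-tailed, the default) or
#'   `"erdos_renyi"`.
#' @param module_size planted-module and signature size.
#' @param internal_density target induced edge density of planted functional
#'   modules, in `(0, 1]`.
#' @param n_modules_per_class number of functional and of signature modules.
#' @param n_linker number of linker (two cliques + hub) modules.
#' @param evidence_frac fraction of scaffold edges tagged with two evidence
#'   categories (so they survive the filtered-scaffold rule); the rest get
#'   one.
#' @param seed integer seed; all generators are bit-reproducible.
#' @return A `synth_spec` object (validated list).
#' @export
synth_spec <- function(n_nodes = 2000, mean_degree = 4,
                       model = c("preferential_attachment", "erdos_renyi"),
                       module_size = 20, internal_density = 0.3,
                       n_modules_per_class = 20, n_linker = 2,
                       evidence_frac = 0.5, seed = 1) {
  model <- match.arg(model)
  if (mean_degree < 1) stop("`mean_degree` must be >= 1", call. = FALSE)
  if (mean_degree >= n_nodes)
    stop("infeasible scaffold: mean_degree >= n_nodes", call. = FALSE)
  if (!(internal_density > 0 && internal_density <= 1))
    stop("`internal_density` must be in (0, 1]", call. = FALSE)
  if (module_size < 3) stop("`module_size` must be >= 3", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), mean_degree = mean_degree,
                 model = model, module_size = as.integer(module_size),
                 internal_density = internal_density,
                 n_modules_per_class = as.integer(n_modules_per_class),
                 n_linker = as.integer(n_linker),
                 evidence_frac = evidence_frac, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic scaffold interactome
#'
#' @param spec a [synth_spec].
#' @return A `ppi_scaffold` with nodes `g1 ... gN` and evidence tags
#'   (`expA;expB` on a `evidence_frac` share of edges, `expA` on the rest).
#' @export
generate_scaffold <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    g <- switch(spec$model,
      preferential_attachment = igraph::sample_pa(
        spec$n_nodes, m = max(1L, round(spec$mean_degree / 2)),
        directed = FALSE),
      erdos_renyi = igraph::sample_gnm(
        spec$n_nodes, round(spec$n_nodes * spec$mean_degree / 2))
    )
    g <- igraph::simplify(g)
    igraph::V(g)$name <- paste0("g", seq_len(igraph::vcount(g)))
    two <- stats::runif(igraph::ecount(g)) < spec$evidence_frac
    igraph::E(g)$evidence <- ifelse(two, "expA;expB", "expA")
    scaffold_from_graph(g)
  })
}

# Add edges (tagged with two evidence categories so they survive filtering)
# to an igraph; `pairs` is a 2-column character matrix of endpoints.
add_tagged_edges <- function(g, pairs) {
  if (nrow(pairs) == 0L) return(g)
  idx <- rbind(match(pairs[, 1L], igraph::V(g)$name),
               match(pairs[, 2L], igraph::V(g)$name))
  igraph::add_edges(g, as.vector(idx),
                    attr = list(evidence = rep("expA;expB", nrow(pairs))))
}

#' Plant a cohesive functional-like module into a scaffold
#'
#' Chooses `size` nodes and adds internal edges until the induced edge
#' density reaches `internal_density`; added edges carry two evidence
#' categories so the planted structure survives the filtered-scaffold rule.
#'
#' @param scaffold a `ppi_scaffold`; returned modified.
#' @param size module size.
#' @param internal_density target density of the induced subgraph, `(0, 1]`.
#' @param seed integer seed.
#' @param module_id module identifier; default derived from the seed.
#' @param members optional fixed node set to plant on (length `size` wins
#'   over `size`); chosen uniformly at random when `NULL`.
#' @return List with the planted [gene_module] (`module`, collection
#'   `"functional"`) and the modified `scaffold`.
#' @export
plant_module <- function(scaffold, size, internal_density, seed,
                         module_id = sprintf("func_s%d", seed),
                         members = NULL) {
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  if (!(internal_density > 0 && internal_density <= 1))
    stop("density target unreachable: `internal_density` must be in (0, 1]",
         call. = FALSE)
  g <- scaffold$graph
  if (size > igraph::vcount(g))
    stop("`size` exceeds the scaffold size", call. = FALSE)
  with_seed(seed, {
    nodes <- if (is.null(members)) sort(sample(igraph::V(g)$name, size))
             else sort(unique(as.character(members)))
    if (!all(nodes %in% igraph::V(g)$name))
      stop("`members` must be scaffold nodes", call. = FALSE)
    pairs <- t(utils::combn(nodes, 2L))
    sub <- igraph::induced_subgraph(g, nodes)
    existing <- canonical_edges(sub)
    have <- paste(existing$node_a, existing$node_b, sep = "\r")
    all_keys <- paste(pmin(pairs[, 1L], pairs[, 2L]),
                      pmax(pairs[, 1L], pairs[, 2L]), sep = "\r")
    target <- ceiling(internal_density * nrow(pairs))
    need <- target - length(have)
    if (need > 0L) {
      missing <- which(!(all_keys %in% have))
      pick <- missing[sample.int(length(missing), need)]
      g <- add_tagged_edges(g, pairs[pick, , drop = FALSE])
    }
    list(module = new_gene_module(module_id, nodes, "functional",
                                  list(planted = "yes",
                                       internal_density = format(internal_density))),
         scaffold = new_scaffold(g, filtered = scaffold$filtered,
                                 report = scaffold$report))
  })
}

#' Draw a signature-like uniform random gene list
#'
#' @param scaffold a `ppi_scaffold`.
#' @param size list size.
#' @param seed integer seed.
#' @param module_id module identifier; default derived from the seed.
#' @return A [gene_module] (collection `"signature"`); the scaffold is not
#'   modified.
#' @export
make_signature_list <- function(scaffold, size, seed,
                                module_id = sprintf("sig_s%d", seed)) {
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  if (size > igraph::vcount(scaffold$graph))
    stop("`size` exceeds the scaffold size", call. = FALSE)
  with_seed(seed, {
    new_gene_module(module_id,
                    sort(sample(scaffold_nodes(scaffold), size)),
                    "signature")
  })
}

#' Build a module whose halves reconnect only through one linker hub
#'
#' Chooses `2 * clique_size + 1` nodes, strips their pre-existing scaffold
#' edges, wires two complete cliques, and connects a non-member hub to one
#' node of each clique. The base MCN of the module then has exactly two
#' components, and the extended MCN is one component with the hub flagged
#' external -- and the hub is provably the only node able to rejoin the two
#' halves.
#'
#' @param scaffold a `ppi_scaffold`; returned modified.
#' @param clique_size nodes per clique.
#' @param seed integer seed.
#' @param module_id module identifier; default derived from the seed.
#' @return List with the [gene_module] (`module`, collection `"linker"`,
#'   ground-truth hub in `attrs$linker`) and the modified `scaffold`.
#' @export
make_linker_module <- function(scaffold, clique_size, seed,
                               module_id = sprintf("link_s%d", seed)) {
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  g <- scaffold$graph
  if (2L * clique_size + 1L > igraph::vcount(g))
    stop("scaffold too small for two cliques plus a hub", call. = FALSE)
  with_seed(seed, {
    picked <- sample(igraph::V(g)$name, 2L * clique_size + 1L)
    a <- sort(picked[seq_len(clique_size)])
    b <- sort(picked[clique_size + seq_len(clique_size)])
    hub <- picked[2L * clique_size + 1L]

    # isolate the construction from the surrounding scaffold so that the
    # hub is the unique bridge between the two halves
    old <- unlist(igraph::incident_edges(
      g, match(picked, igraph::V(g)$name)), use.names = FALSE)
    if (length(old) > 0L) g <- igraph::delete_edges(g, unique(old))

    g <- add_tagged_edges(g, t(utils::combn(a, 2L)))
    g <- add_tagged_edges(g, t(utils::combn(b, 2L)))
    g <- add_tagged_edges(g, rbind(c(hub, a[1L]), c(hub, b[1L])))

    list(module = new_gene_module(module_id, c(a, b), "linker",
                                  list(linker = hub)),
         scaffold = new_scaffold(g, filtered = scaffold$filtered,
                                 report = scaffold$report))
  })
}

#' Generate a full benchmark: scaffold, labelled modules and annotations
#'
#' Emits a mixed module collection -- `n_modules_per_class` planted
#' functional modules, as many uniform signature lists, and `n_linker`
#' linker modules -- together with a small GO-like DAG in which every
#' functional module has a dedicated term annotated with its members, so
#' that over-representation analysis and the ORA-vs-network classification
#' can be exercised with known truth. Functional modules are planted
#' sequentially, so the returned scaffold contains all of them.
#'
#' @param spec a [synth_spec].
#' @return List with `scaffold`, `modules` (named list of [gene_module]s),
#'   `annotation` (a [term_annotation]) and `truth` (data frame of module
#'   id, class and ground-truth linker hub where applicable).
#' @export
generate_benchmark_collection <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  scaffold <- generate_scaffold(spec)
  n_total <- spec$n_modules_per_class * 2L + spec$n_linker
  seeds <- derive_seeds(spec$seed, n_total + 1L)

  modules <- list()
  truth <- list()
  si <- 0L
  for (i in seq_len(spec$n_modules_per_class)) {
    si <- si + 1L
    pl <- plant_module(scaffold, spec$module_size, spec$internal_density,
                       seeds[si], module_id = sprintf("T:func%02d", i))
    scaffold <- pl$scaffold
    modules[[pl$module$module_id]] <- pl$module
    truth[[length(truth) + 1L]] <-
      data.frame(module_id = pl$module$module_id, class = "functional",
                 linker = NA_character_, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_modules_per_class)) {
    si <- si + 1L
    m <- make_signature_list(scaffold, spec$module_size, seeds[si],
                             module_id = sprintf("sig%02d", i))
    modules[[m$module_id]] <- m
    truth[[length(truth) + 1L]] <-
      data.frame(module_id = m$module_id, class = "signature",
                 linker = NA_character_, stringsAsFactors = FALSE)
  }
  if (spec$n_linker > 0L) {
    k <- max(3L, spec$module_size %/% 2L)
    for (i in seq_len(spec$n_linker)) {
      si <- si + 1L
      lk <- make_linker_module(scaffold, k, seeds[si],
                               module_id = sprintf("link%02d", i))
      scaffold <- lk$scaffold
      modules[[lk$module$module_id]] <- lk$module
      truth[[length(truth) + 1L]] <-
        data.frame(module_id = lk$module$module_id, class = "linker",
                   linker = lk$module$attrs$linker, stringsAsFactors = FALSE)
    }
  }

  func_ids <- names(modules)[startsWith(names(modules), "T:func")]
  dag <- rbind(
    data.frame(child = c("T:midA", "T:midB"), parent = "T:root",
               stringsAsFactors = FALSE),
    data.frame(child = func_ids,
               parent = ifelse(seq_along(func_ids) %% 2L == 0L,
                               "T:midA", "T:midB"),
               stringsAsFactors = FALSE)
  )
  anno <- do.call(rbind, lapply(func_ids, function(t) {
    data.frame(gene = modules[[t]]$members, term = t,
               stringsAsFactors = FALSE)
  }))
  ns <- stats::setNames(rep("biological_process",
                            length(func_ids) + 3L),
                        c("T:root", "T:midA", "T:midB", func_ids))
  ann <- term_annotation(dag, anno, ns)

  list(scaffold = scaffold, modules = modules, annotation = ann,
       truth = do.call(rbind, truth))
}
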