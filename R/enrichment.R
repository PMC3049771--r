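# Network enrichment testing.
#
# The random expectation of an MCN's parameters at list size N is built by
# resampling: N nodes are drawn uniformly without replacement from the
# scaffold, the MCN is rebuilt with the same external-node mode as the
# observed analysis, and node-level parameter values (pooled over all
# repetitions) plus per-repetition component counts are collected. The
# observed node-level distributions are then compared to the pooled null by
# one-sided two-sample Kolmogorov-Smirnov tests (alternative: observed
# greater) and the observed component count by an empirical lower-tail test.

#' Build an empirical null distribution by random node sampling
#'
#' @param scaffold a `ppi_scaffold`.
#' @param list_size N, the number of nodes sampled per repetition (matched to
#'   the number of mapped members of the module under test).
#' @param allow_external whether random MCNs admit external linker nodes; must
#'   match the observed analysis.
#' @param reps number of repetitions R (the reference analysis used 10,000;
#'   the package default is 1,000).
#' @param seed integer seed; the null is bit-reproducible from
#'   `(scaffold, list_size, allow_external, reps, seed)`.
#' @param degree_matched if `TRUE`, nodes are sampled with probability
#'   proportional to their scaffold degree instead of uniformly (off by
#'   default; sensitivity analysis only).
#' @return An `mcn_null` object: `pooled` (named list of sorted numeric
#'   vectors for `degree`, `clustering`, `rel_betweenness`, pooled over all
#'   repetitions), `component_counts` (one integer per repetition) and the
#'   generating arguments.
#' @export
sample_null <- function(scaffold, list_size, allow_external = FALSE,
                        reps = 1000, seed = 1, degree_matched = FALSE) {
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  n_nodes <- igraph::vcount(scaffold$graph)
  list_size <- as.integer(list_size)
  reps <- as.integer(reps)
  if (is.na(list_size) || list_size < 1L || list_size > n_nodes)
    stop("`list_size` must be in [1, ", n_nodes, "]", call. = FALSE)
  if (is.na(reps) || reps < 1L) stop("`reps` must be >= 1", call. = FALSE)

  vnames <- igraph::V(scaffold$graph)$name
  prob <- if (isTRUE(degree_matched))
    igraph::degree(scaffold$graph) + 1e-9 else NULL

  deg <- vector("list", reps)
  clu <- vector("list", reps)
  btw <- vector("list", reps)
  comp <- integer(reps)
  with_seed(seed, {
    for (r in seq_len(reps)) {
      nodes <- sample(vnames, list_size, replace = FALSE, prob = prob)
      m <- build_mcn(nodes, scaffold, allow_external = allow_external)
      p <- node_params(m)
      deg[[r]] <- unname(p$degree)
      clu[[r]] <- unname(p$clustering)
      btw[[r]] <- unname(p$rel_betweenness)
      comp[r] <- p$n_components
    }
  })
  structure(list(
    list_size = list_size, allow_external = isTRUE(allow_external),
    reps = reps, seed = seed, degree_matched = isTRUE(degree_matched),
    pooled = list(degree = sort(as.numeric(unlist(deg))),
                  clustering = sort(as.numeric(unlist(clu))),
                  rel_betweenness = sort(as.numeric(unlist(btw)))),
    component_counts = comp
  ), class = "mcn_null")
}

#' One-sided two-sample Kolmogorov-Smirnov test (observed greater)
#'
#' Tests whether `observed` is stochastically greater than `null`:
#' `D+ = sup_x (F_null(x) - F_obs(x))` with the asymptotic one-sided p-value
#' `p = exp(-2 m D+^2)`, `m = n_obs n_null / (n_obs + n_null)`, clipped to
#' `(0, 1]`.
#'
#' @param observed,null non-empty numeric vectors.
#' @return A list with `statistic` (D+), `p.value`, and the sample sizes.
#' @export
ks_greater <- function(observed, null) {
  observed <- as.numeric(observed)
  null <- as.numeric(null)
  if (length(observed) == 0L || length(null) == 0L)
    stop("`observed` and `null` must be non-empty", call. = FALSE)
  if (anyNA(observed) || anyNA(null))
    stop("missing values in KS input", call. = FALSE)
  so <- sort(observed)
  sn <- if (is.unsorted(null)) sort(null) else null
  no <- length(so); nn <- length(sn)
  z <- unique(c(so, sn))
  dplus <- max(0, findInterval(z, sn) / nn - findInterval(z, so) / no)
  m <- no * nn / (no + nn)
  p <- min(1, exp(-2 * m * dplus^2))
  list(statistic = c(`D^+` = dplus), p.value = p, n_observed = no,
       n_null = nn)
}

#' Empirical lower-tail test for component counts
#'
#' A cohesive list should produce fewer components than random lists of the
#' same size. The p-value is the add-one-corrected empirical lower tail,
#' `p = (1 + #\{c in null : c <= observed\}) / (R + 1)`.
#'
#' @param observed observed component count.
#' @param null_counts integer vector of component counts from [sample_null()].
#' @return p-value in `(0, 1]`.
#' @export
components_p <- function(observed, null_counts) {
  if (length(null_counts) == 0L)
    stop("`null_counts` must be non-empty", call. = FALSE)
  (1 + sum(null_counts <= observed)) / (length(null_counts) + 1)
}

#' Cache for null distributions
#'
#' Null distributions depend only on the scaffold, the list size, the
#' external-node mode, the repetition count and the seed; modules of equal
#' mapped size share one null. `null_cache()` creates an in-memory cache
#' (an environment); pass it to [analyze_module()] / [analyze_collection()]
#' to reuse nulls across modules.
#'
#' @return An environment used as a key-value store.
#' @export
null_cache <- function() new.env(parent = emptyenv())

#' Cache key of a null distribution
#'
#' Deterministic string key; identical arguments give identical keys and a
#' cache hit returns the bit-identical null.
#'
#' @param scaffold_hash scaffold digest (see the internal canonical edge-list
#'   md5) or any stable scaffold identifier.
#' @param list_size,allow_external,reps,seed generating arguments.
#' @param degree_matched sampling mode flag.
#' @return Character key, prefixed with a cache format version tag.
#' @export
null_cache_key <- function(scaffold_hash, list_size, allow_external, reps,
                           seed, degree_matched = FALSE) {
  paste("mcnnull-v1", scaffold_hash, as.integer(list_size),
        as.integer(isTRUE(allow_external)), as.integer(reps),
        format(seed, scientific = FALSE),
        as.integer(isTRUE(degree_matched)), sep = "|")
}

get_null <- function(scaffold, list_size, allow_external, reps, seed,
                     cache = NULL, degree_matched = FALSE,
                     scaffold_digest = NULL) {
  if (is.null(cache))
    return(sample_null(scaffold, list_size, allow_external, reps, seed,
                       degree_matched))
  if (is.null(scaffold_digest)) scaffold_digest <- scaffold_hash(scaffold)
  key <- null_cache_key(scaffold_digest, list_size, allow_external, reps,
                        seed, degree_matched)
  if (!is.null(cache[[key]])) return(cache[[key]])
  nd <- sample_null(scaffold, list_size, allow_external, reps, seed,
                    degree_matched)
  cache[[key]] <- nd
  nd
}

new_mcn_enrich <- function(module_id, collection = "modules", attrs = list(),
                           mapped_n = NA_integer_, n_unmapped = NA_integer_,
                           allow_external = NA, reps = NA_integer_,
                           alpha = 0.05, seed = NA_integer_, p = NULL,
                           observed = NULL, mcn = NULL,
                           skipped_reason = NULL) {
  significant <- if (is.null(p)) NULL else p < alpha
  structure(list(module_id = module_id, collection = collection,
                 attrs = attrs, mapped_n = mapped_n, n_unmapped = n_unmapped,
                 allow_external = allow_external, reps = reps, alpha = alpha,
                 seed = seed, p = p, significant = significant,
                 observed = observed, mcn = mcn,
                 skipped_reason = skipped_reason),
            class = "mcn_enrich")
}

#' Network enrichment analysis of a single gene module
#'
#' Maps the module onto the scaffold, builds its MCN, and tests connection
#' degree, clustering coefficient and relative betweenness (one-sided KS,
#' alternative "observed greater") plus the component count (empirical lower
#' tail) against a resampling null of matched list size. Modules whose mapped
#' member count falls outside `[size_min, size_max]` are skipped (empirical
#' nulls are unreliable outside that range), as are modules with no member in
#' the scaffold.
#'
#' @param module a [gene_module] or a character vector of identifiers.
#' @param scaffold a `ppi_scaffold`.
#' @param allow_external admit external linker nodes (the "+node" analysis);
#'   applied identically to the observed MCN and the null.
#' @param reps null repetitions R.
#' @param alpha significance level for the `significant` flags.
#' @param seed seed for the null sampler.
#' @param size_min,size_max inclusive bounds on the mapped member count;
#'   defaults 3 and 200.
#' @param null optional precomputed [sample_null()] result (must match
#'   `mapped_n`, `allow_external` and `reps`).
#' @param cache optional [null_cache()] environment for reuse across modules.
#' @param degree_matched null sampling mode, see [sample_null()].
#' @param scaffold_digest internal: precomputed scaffold hash.
#' @return An `mcn_enrich` object with p-values (`p`: `degree`, `clustering`,
#'   `betweenness`, `components`), `significant` flags at `alpha`, mapping
#'   statistics, the observed node-level values (`observed`), the `mcn`
#'   itself, or a `skipped_reason` when no test was performed.
#' @export
analyze_module <- function(module, scaffold, allow_external = TRUE,
                           reps = 1000, alpha = 0.05, seed = 1,
                           size_min = 3, size_max = 200, null = NULL,
                           cache = NULL, degree_matched = FALSE,
                           scaffold_digest = NULL) {
  stopifnot(inherits(scaffold, "ppi_scaffold"))
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (inherits(module, "gene_module")) {
    module_id <- module$module_id
    collection <- module$collection
    attrs <- module$attrs
    members <- module$members
  } else {
    module_id <- "module"
    collection <- "modules"
    attrs <- list()
    members <- unique(as.character(module))
  }

  mcn <- tryCatch(build_mcn(members, scaffold, allow_external),
                  error = function(e) e)
  if (inherits(mcn, "error"))
    return(new_mcn_enrich(module_id, collection, attrs,
                          mapped_n = 0L, n_unmapped = length(members),
                          allow_external = allow_external, reps = reps,
                          alpha = alpha, seed = seed,
                          skipped_reason = "no members in scaffold"))

  mapped_n <- mcn$source_list_size
  if (mapped_n < size_min || mapped_n > size_max)
    return(new_mcn_enrich(module_id, collection, attrs,
                          mapped_n = mapped_n,
                          n_unmapped = length(mcn$unmapped),
                          allow_external = allow_external, reps = reps,
                          alpha = alpha, seed = seed, mcn = mcn,
                          skipped_reason = "size out of range"))

  if (!is.null(null)) {
    if (null$list_size != mapped_n || null$allow_external != isTRUE(allow_external) ||
        null$reps != reps)
      stop("supplied null does not match the module (list size, external mode or reps)",
           call. = FALSE)
    nd <- null
  } else {
    nd <- get_null(scaffold, mapped_n, allow_external, reps, seed, cache,
                   degree_matched, scaffold_digest)
  }

  obs <- node_params(mcn)
  p <- c(
    degree = ks_greater(obs$degree, nd$pooled$degree)$p.value,
    clustering = ks_greater(obs$clustering, nd$pooled$clustering)$p.value,
    betweenness = ks_greater(obs$rel_betweenness,
                             nd$pooled$rel_betweenness)$p.value,
    components = components_p(obs$n_components, nd$component_counts)
  )
  new_mcn_enrich(module_id, collection, attrs, mapped_n = mapped_n,
                 n_unmapped = length(mcn$unmapped),
                 allow_external = isTRUE(allow_external), reps = reps,
                 alpha = alpha, seed = seed, p = p,
                 observed = list(degree = unname(obs$degree),
                                 clustering = unname(obs$clustering),
                                 rel_betweenness = unname(obs$rel_betweenness),
                                 n_components = obs$n_components),
                 mcn = mcn)
}

#' @export
print.mcn_enrich <- function(x, ...) {
  cat(sprintf("Network enrichment of module '%s' [%s]\n", x$module_id,
              x$collection))
  if (!is.null(x$skipped_reason)) {
    cat(sprintf("  skipped: %s (mapped members: %s)\n", x$skipped_reason,
                x$mapped_n))
    return(invisible(x))
  }
  cat(sprintf("  %d mapped members (%d unmapped), external nodes %s, R = %d\n",
              x$mapped_n, x$n_unmapped,
              if (x$allow_external) "allowed" else "not allowed", x$reps))
  for (par in names(x$p))
    cat(sprintf("  %-12s p = %.4g%s\n", par, x$p[[par]],
                if (x$significant[[par]]) " *" else ""))
  cat(sprintf("  (* significant at alpha = %g)\n", x$alpha))
  invisible(x)
}

#' @export
print.mcn_null <- function(x, ...) {
  cat(sprintf("Empirical null: N = %d, R = %d, external nodes %s, seed %s\n",
              x$list_size, x$reps,
              if (x$allow_external) "allowed" else "not allowed",
              format(x$seed)))
  cat(sprintf("  pooled node values: %d; component counts: median %g [%g, %g]\n",
              length(x$pooled$degree), stats::median(x$component_counts),
              min(x$component_counts), max(x$component_counts)))
  invisible(x)
}
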