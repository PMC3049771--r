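# Batch analysis over module collections and the comparative summaries:
# percent-significant tables, namespace/level stratification, pooled
# class-vs-class distribution comparisons, over-representation analysis and
# the ORA-vs-network cross-classification.

PARAMS <- c("degree", "betweenness", "clustering", "components")

#' Network enrichment analysis of a module collection
#'
#' Runs [analyze_module()] on every module, sharing null distributions across
#' modules of equal mapped size through a [null_cache()].
#'
#' @inheritParams analyze_module
#' @param modules list of [gene_module] objects (e.g. from [read_gmt()]).
#' @param cache optional [null_cache()]; one is created when `NULL`.
#' @return An `mcn_enrich_set`: list of per-module `mcn_enrich` results
#'   (`results`), a per-module data frame (`table`, see
#'   [as.data.frame.mcn_enrich_set()]) and the run configuration (`config`).
#' @export
analyze_collection <- function(modules, scaffold, allow_external = TRUE,
                               reps = 1000, alpha = 0.05, seed = 1,
                               size_min = 3, size_max = 200, cache = NULL,
                               degree_matched = FALSE) {
  if (inherits(modules, "gene_module")) modules <- list(modules)
  stopifnot(length(modules) > 0L)
  if (is.null(cache)) cache <- null_cache()
  digest <- scaffold_hash(scaffold)
  results <- lapply(modules, analyze_module, scaffold = scaffold,
                    allow_external = allow_external, reps = reps,
                    alpha = alpha, seed = seed, size_min = size_min,
                    size_max = size_max, cache = cache,
                    degree_matched = degree_matched,
                    scaffold_digest = digest)
  names(results) <- vapply(results, `[[`, "", "module_id")
  out <- structure(list(results = results,
                        config = list(allow_external = allow_external,
                                      reps = reps, alpha = alpha, seed = seed,
                                      size_min = size_min,
                                      size_max = size_max,
                                      degree_matched = degree_matched,
                                      scaffold_hash = digest)),
                   class = "mcn_enrich_set")
  out$table <- as.data.frame(out)
  out
}

#' Per-module results table of an enrichment set
#'
#' @param x an `mcn_enrich_set`.
#' @param ... ignored.
#' @return Data frame with one row per module: identifiers, mapping counts,
#'   the four p-values, significance flags and skip reasons.
#' @export
as.data.frame.mcn_enrich_set <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    p <- r$p %||% stats::setNames(rep(NA_real_, 4), PARAMS)
    s <- r$significant %||% stats::setNames(rep(NA, 4), PARAMS)
    data.frame(module_id = r$module_id, collection = r$collection,
               mapped_n = r$mapped_n, n_unmapped = r$n_unmapped,
               allow_external = r$allow_external,
               p_degree = unname(p[["degree"]]),
               p_betweenness = unname(p[["betweenness"]]),
               p_clustering = unname(p[["clustering"]]),
               p_components = unname(p[["components"]]),
               sig_degree = unname(s[["degree"]]),
               sig_betweenness = unname(s[["betweenness"]]),
               sig_clustering = unname(s[["clustering"]]),
               sig_components = unname(s[["components"]]),
               skipped_reason = r$skipped_reason %||% "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

result_attr <- function(r, what) {
  if (what == "collection") return(r$collection)
  as.character(r$attrs[[what]] %||% NA_character_)
}

#' Percent-significant summary of a collection
#'
#' For each parameter, the percentage of analyzed (non-skipped) modules with
#' p-value below `alpha`, optionally stratified by a module attribute
#' (e.g. GO `namespace`, signature `direction` or `disease`).
#'
#' @param x an `mcn_enrich_set` or list of `mcn_enrich` results.
#' @param alpha significance level (defaults to the one used at analysis
#'   time).
#' @param stratify_by optional attribute name to split on.
#' @return Data frame with one row per stratum: `collection`, `stratum`,
#'   `n_analyzed`, `n_skipped` and `pct_degree`, `pct_betweenness`,
#'   `pct_clustering`, `pct_components` (NA when nothing was analyzed).
#' @export
summarize_collection <- function(x, alpha = NULL, stratify_by = NULL) {
  results <- if (inherits(x, "mcn_enrich_set")) x$results else x
  stopifnot(length(results) > 0L)
  if (is.null(alpha))
    alpha <- if (inherits(x, "mcn_enrich_set")) x$config$alpha else 0.05
  strata <- if (is.null(stratify_by)) rep("all", length(results))
            else vapply(results, result_attr, "", what = stratify_by)
  rows <- lapply(split(results, strata), function(rs) {
    skipped <- vapply(rs, function(r) !is.null(r$skipped_reason), NA)
    analyzed <- rs[!skipped]
    pcts <- if (length(analyzed) == 0L) {
      stats::setNames(rep(NA_real_, 4), PARAMS)
    } else {
      vapply(PARAMS, function(par) {
        100 * mean(vapply(analyzed, function(r) r$p[[par]] < alpha, NA))
      }, 0)
    }
    data.frame(collection = rs[[1L]]$collection,
               stratum = result_attr(rs[[1L]], stratify_by %||% "collection"),
               n_analyzed = length(analyzed), n_skipped = sum(skipped),
               pct_degree = pcts[["degree"]],
               pct_betweenness = pcts[["betweenness"]],
               pct_clustering = pcts[["clustering"]],
               pct_components = pcts[["components"]],
               stringsAsFactors = FALSE)
  })
  if (is.null(stratify_by)) rows[[1L]]$stratum <- NA_character_
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool node-level parameter values across modules
#'
#' Concatenates the observed node-level values of a parameter over all
#' analyzed modules (for `"components"`, one count per module), the input to
#' class-vs-class distribution comparisons.
#'
#' @param x an `mcn_enrich_set` or list of `mcn_enrich` results.
#' @param parameter one of `"degree"`, `"clustering"`, `"betweenness"`,
#'   `"components"`.
#' @param ids optional module ids to restrict to.
#' @return Numeric vector.
#' @export
pool_parameter <- function(x, parameter = c("degree", "clustering",
                                            "betweenness", "components"),
                           ids = NULL) {
  parameter <- match.arg(parameter)
  results <- if (inherits(x, "mcn_enrich_set")) x$results else x
  if (!is.null(ids))
    results <- results[vapply(results, `[[`, "", "module_id") %in% ids]
  results <- Filter(function(r) is.null(r$skipped_reason) &&
                      !is.null(r$observed), results)
  if (length(results) == 0L)
    stop("no analyzed modules to pool", call. = FALSE)
  field <- switch(parameter, betweenness = "rel_betweenness",
                  components = "n_components", parameter)
  as.numeric(unlist(lapply(results, function(r) r$observed[[field]]),
                    use.names = FALSE))
}

#' Compare pooled parameter distributions of two module classes
#'
#' Two-tailed two-sample Kolmogorov-Smirnov test ([stats::ks.test()]) on the
#' pooled node-level values, with a direction call based on the medians:
#' `greater`/`less` when the test is significant at `alpha` and the median of
#' `pool_a` is above/below that of `pool_b`, else `none`.
#'
#' @param pool_a,pool_b numeric vectors from [pool_parameter()].
#' @param class_a,class_b class labels for the report.
#' @param parameter parameter label for the report.
#' @param alpha significance level for the direction call.
#' @return One-row data frame: `class_a`, `class_b`, `parameter`, `ks_d`,
#'   `ks_p`, `direction`.
#' @export
compare_classes <- function(pool_a, pool_b, class_a = "A", class_b = "B",
                            parameter = "parameter", alpha = 0.05) {
  stopifnot(length(pool_a) > 0L, length(pool_b) > 0L)
  kt <- suppressWarnings(stats::ks.test(pool_a, pool_b))
  direction <- if (kt$p.value >= alpha) "none"
    else if (stats::median(pool_a) > stats::median(pool_b)) "greater"
    else if (stats::median(pool_a) < stats::median(pool_b)) "less"
    else "none"
  data.frame(class_a = class_a, class_b = class_b, parameter = parameter,
             ks_d = unname(kt$statistic), ks_p = max(kt$p.value, .Machine$double.xmin),
             direction = direction, stringsAsFactors = FALSE)
}

#' Aggregate network parameters by term hierarchy level
#'
#' For collections whose module ids are terms of a DAG (GO-like), aggregates
#' per level: number of modules, mean of the per-module mean node-level
#' values, and percent significant per parameter. Levels supported by fewer
#' than three modules are flagged `low_support`.
#'
#' @param x an `mcn_enrich_set` or list of `mcn_enrich` results.
#' @param ann a [term_annotation]; module levels come from [term_level()]
#'   (falling back to a `go_level` module attribute when the id is not in the
#'   DAG).
#' @param alpha significance level.
#' @return Data frame with one row per level.
#' @export
level_profile <- function(x, ann, alpha = NULL) {
  results <- if (inherits(x, "mcn_enrich_set")) x$results else x
  if (is.null(alpha))
    alpha <- if (inherits(x, "mcn_enrich_set")) x$config$alpha else 0.05
  results <- Filter(function(r) is.null(r$skipped_reason), results)
  if (length(results) == 0L)
    return(data.frame(level = integer(), n_modules = integer()))
  lev <- vapply(results, function(r) {
    if (r$module_id %in% ann$terms) term_level(ann, r$module_id)
    else if (!is.null(r$attrs$go_level)) as.integer(r$attrs$go_level)
    else NA_integer_
  }, 0L)
  keep <- !is.na(lev)
  if (!all(keep))
    warning(sum(!keep), " module(s) without a computable level dropped")
  results <- results[keep]; lev <- lev[keep]
  rows <- lapply(split(results, lev), function(rs) {
    data.frame(
      level = NA_integer_,  # filled from the split names below
      n_modules = length(rs),
      mean_degree = mean(vapply(rs, function(r) mean(r$observed$degree), 0)),
      mean_clustering = mean(vapply(rs, function(r) mean(r$observed$clustering), 0)),
      mean_betweenness = mean(vapply(rs, function(r) mean(r$observed$rel_betweenness), 0)),
      mean_components = mean(vapply(rs, function(r) r$observed$n_components, 0)),
      pct_degree = 100 * mean(vapply(rs, function(r) r$p[["degree"]] < alpha, NA)),
      pct_betweenness = 100 * mean(vapply(rs, function(r) r$p[["betweenness"]] < alpha, NA)),
      pct_clustering = 100 * mean(vapply(rs, function(r) r$p[["clustering"]] < alpha, NA)),
      pct_components = 100 * mean(vapply(rs, function(r) r$p[["components"]] < alpha, NA)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$level <- as.integer(names(rows))
  out$low_support <- out$n_modules < 3L
  out <- out[order(out$level), ]
  rownames(out) <- NULL
  out
}

#' Over-representation analysis of a gene list against annotated terms
#'
#' One-sided Fisher exact test (hypergeometric upper tail) per term on the
#' 2x2 table of membership in the list and in the term, within a background
#' universe, with Benjamini-Hochberg correction across terms. Terms without
#' annotated genes in the background are skipped.
#'
#' @param members character vector of list identifiers (must be contained in
#'   `background`).
#' @param term2genes named list term -> genes, typically the propagated map
#'   from [propagate_annotations()].
#' @param background character vector: the gene universe.
#' @return Data frame ordered by p: `term`, `overlap`, `term_size`,
#'   `module_size`, `background_size`, `p`, `q`.
#' @export
ora_fisher <- function(members, term2genes, background) {
  members <- unique(as.character(members))
  background <- unique(as.character(background))
  if (!all(members %in% background))
    stop("`members` must be a subset of `background`", call. = FALSE)
  N <- length(background)
  n <- length(members)
  rows <- lapply(names(term2genes), function(t) {
    genes <- intersect(term2genes[[t]], background)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, overlap = k, term_size = K, module_size = n,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), module_size = integer(),
                      background_size = integer(), p = numeric(),
                      q = numeric()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}

#' Cross-classify modules by network significance and term enrichment
#'
#' A module is net-significant when any of the four network parameter
#' p-values is below `alpha`, and GO-significant when any term reaches
#' `q < q_alpha` in its over-representation analysis. Each module receives
#' one of the labels `net_and_go`, `only_net`, `only_go`, `nothing`.
#'
#' @param net_results an `mcn_enrich_set` or list of `mcn_enrich` results.
#' @param ora_results named list (module id -> [ora_fisher()] data frame);
#'   must cover exactly the same modules.
#' @param alpha network significance level.
#' @param q_alpha ORA q-value threshold.
#' @return Data frame: `module_id`, `net_significant`, `go_significant`,
#'   `label`.
#' @export
classify_modules <- function(net_results, ora_results, alpha = 0.05,
                             q_alpha = 0.05) {
  results <- if (inherits(net_results, "mcn_enrich_set")) net_results$results
             else net_results
  ids <- vapply(results, `[[`, "", "module_id")
  if (!setequal(ids, names(ora_results)) || length(ids) != length(ora_results))
    stop("network and ORA results must cover the same modules", call. = FALSE)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    net <- !is.null(r$p) && any(r$p < alpha)
    ora <- ora_results[[r$module_id]]
    go <- nrow(ora) > 0L && any(ora$q < q_alpha)
    label <- if (net && go) "net_and_go" else if (net) "only_net"
             else if (go) "only_go" else "nothing"
    data.frame(module_id = r$module_id, net_significant = net,
               go_significant = go, label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mcn_enrich_set <- function(x, ...) {
  skipped <- sum(vapply(x$results, function(r) !is.null(r$skipped_reason), NA))
  cat(sprintf("Network enrichment over %d modules (%d analyzed, %d skipped); R = %d, alpha = %g, external nodes %s\n",
              length(x$results), length(x$results) - skipped, skipped,
              x$config$reps, x$config$alpha,
              if (x$config$allow_external) "allowed" else "not allowed"))
  invisible(x)
}

#' Summary of an enrichment set
#'
#' @param object an `mcn_enrich_set`.
#' @param ... passed to [summarize_collection()] (`alpha`, `stratify_by`).
#' @export
summary.mcn_enrich_set <- function(object, ...) {
  bycoll <- split(object$results,
                  vapply(object$results, `[[`, "", "collection"))
  out <- do.call(rbind, lapply(bycoll, summarize_collection,
                               alpha = object$config$alpha, ...))
  rownames(out) <- NULL
  out
}
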