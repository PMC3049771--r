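# File-in/file-out drivers: read inputs, run the analysis, write the report
# TSVs plus a metadata JSON sufficient to reproduce the run (config, seed,
# input hashes). A thin command-line wrapper over these functions lives in
# inst/cli/ppienrich.R.

#' Configuration of an analysis run
#'
#' @param scaffold_path interactome edge-list TSV.
#' @param modules_path GMT file of modules.
#' @param out_dir output directory (created if missing).
#' @param dag_path,anno_path,namespace_path optional term-annotation TSVs.
#' @param collection collection label for the modules.
#' @param alpha significance level (default 0.05).
#' @param reps null repetitions (default 1000).
#' @param allow_external admit external linker nodes (default `TRUE`).
#' @param min_evidence evidence filter for the scaffold (0 = non-filtered;
#'   2 = the filtered, at-least-two-categories scaffold).
#' @param size_min,size_max mapped-size window, default 3 to 200.
#' @param seed integer seed.
#' @param stratify_by optional module attribute for stratified summaries.
#' @return A validated `run_config` list.
#' @export
run_config <- function(scaffold_path, modules_path, out_dir,
                       dag_path = NULL, anno_path = NULL,
                       namespace_path = NULL, collection = "modules",
                       alpha = 0.05, reps = 1000, allow_external = TRUE,
                       min_evidence = 0, size_min = 3, size_max = 200,
                       seed = 1, stratify_by = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0,1)", call. = FALSE)
  if (size_min < 1) stop("`size_min` must be >= 1", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  structure(list(scaffold_path = scaffold_path, modules_path = modules_path,
                 out_dir = out_dir, dag_path = dag_path,
                 anno_path = anno_path, namespace_path = namespace_path,
                 collection = collection, alpha = alpha,
                 reps = as.integer(reps),
                 allow_external = isTRUE(allow_external),
                 min_evidence = as.integer(min_evidence),
                 size_min = as.integer(size_min),
                 size_max = as.integer(size_max), seed = seed,
                 stratify_by = stratify_by),
            class = "run_config")
}

run_metadata <- function(config, scaffold = NULL, extra = list()) {
  meta <- c(list(
    package = "ppienrich",
    version = as.character(utils::packageVersion("ppienrich"))),
    config[setdiff(names(config), "out_dir")],
    if (!is.null(scaffold)) list(scaffold_hash = scaffold_hash(scaffold)),
    extra)
  meta[!vapply(meta, is.null, NA)]
}

write_metadata <- function(meta, out_dir) {
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run a full network-enrichment analysis from files
#'
#' Reads the scaffold and module collection, analyzes every module, and
#' writes `results.tsv` (one row per module), `summary.tsv`
#' (percent-significant per collection/stratum) and `metadata.json` into the
#' output directory.
#'
#' @param config a [run_config].
#' @return The `mcn_enrich_set`, invisibly.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scaffold <- read_interactome(config$scaffold_path,
                               min_evidence = config$min_evidence)
  modules <- read_gmt(config$modules_path, collection = config$collection)
  if (length(modules) == 0L) stop("no modules to analyze", call. = FALSE)
  set <- analyze_collection(modules, scaffold,
                            allow_external = config$allow_external,
                            reps = config$reps, alpha = config$alpha,
                            seed = config$seed, size_min = config$size_min,
                            size_max = config$size_max)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(set$table, file.path(config$out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary(set, stratify_by = config$stratify_by),
                     file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metadata(run_metadata(config, scaffold), config$out_dir)
  invisible(set)
}

#' Write a synthetic benchmark to disk
#'
#' Serializes a [generate_benchmark_collection()] run in the same formats the
#' loaders read: `scaffold.tsv`, `modules.gmt`, `dag.tsv`,
#' `annotations.tsv`, `namespaces.tsv`, `truth.tsv` and `metadata.json`.
#'
#' @param spec a [synth_spec].
#' @param out_dir output directory (created if missing).
#' @return The benchmark list, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synth_spec"))
  bench <- generate_benchmark_collection(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_interactome(bench$scaffold, file.path(out_dir, "scaffold.tsv"))
  # carry the class label through the GMT description field
  mods <- lapply(bench$modules, function(m) {
    m$attrs$class <- m$collection
    m
  })
  write_gmt(mods, file.path(out_dir, "modules.gmt"))
  ann <- bench$annotation
  utils::write.table(ann$dag_edges, file.path(out_dir, "dag.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  anno <- data.frame(
    gene = rep(names(ann$gene2terms), lengths(ann$gene2terms)),
    term = unlist(ann$gene2terms, use.names = FALSE))
  utils::write.table(anno, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(
    data.frame(term = names(ann$namespaces), namespace = ann$namespaces),
    file.path(out_dir, "namespaces.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(bench$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_metadata(run_metadata(unclass(spec), bench$scaffold), out_dir)
  invisible(bench)
}

#' Compare module classes of an analyzed collection
#'
#' Writes all pairwise two-tailed KS comparisons of pooled parameter
#' distributions between module classes (`comparisons.tsv`) and, when ORA
#' inputs are available, the ORA-vs-network cross-classification
#' (`classification.tsv`).
#'
#' @param set an `mcn_enrich_set` from [analyze_collection()] /
#'   [run_analyze()].
#' @param out_dir output directory (created if missing).
#' @param class_by module attribute holding the class label (`"collection"`
#'   to use the collection field, the default; `"class"` for benchmarks
#'   written by [run_simulate()]).
#' @param ann optional [term_annotation] for the ORA arm.
#' @param background gene universe for ORA (defaults to all genes annotated
#'   anywhere when `ann` is given plus all module members).
#' @param alpha significance level.
#' @return List with `comparisons` (data frame) and optionally
#'   `classification`, invisibly.
#' @export
run_compare <- function(set, out_dir, class_by = "collection", ann = NULL,
                        background = NULL, alpha = 0.05) {
  stopifnot(inherits(set, "mcn_enrich_set"))
  classes <- vapply(set$results, result_attr, "", what = class_by)
  ok <- !is.na(classes)
  usable <- split(set$results[ok], classes[ok])
  usable <- Filter(function(rs) any(vapply(rs, function(r)
    is.null(r$skipped_reason), NA)), usable)
  if (length(usable) < 2L)
    stop("need at least two module classes with analyzed modules",
         call. = FALSE)
  pairs <- utils::combn(names(usable), 2L)
  comparisons <- do.call(rbind, unlist(lapply(seq_len(ncol(pairs)), function(i) {
    ca <- pairs[1L, i]; cb <- pairs[2L, i]
    lapply(c("degree", "clustering", "betweenness", "components"),
           function(par) {
             compare_classes(pool_parameter(usable[[ca]], par),
                             pool_parameter(usable[[cb]], par),
                             class_a = ca, class_b = cb, parameter = par,
                             alpha = alpha)
           })
  }), recursive = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(comparisons, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  classification <- NULL
  if (!is.null(ann)) {
    term2genes <- propagate_annotations(ann)
    members <- lapply(set$results, function(r)
      if (!is.null(r$mcn)) c(r$mcn$mapped, r$mcn$unmapped) else character())
    if (is.null(background))
      background <- unique(c(unlist(term2genes, use.names = FALSE),
                             unlist(members, use.names = FALSE)))
    ora <- lapply(set$results, function(r) {
      mem <- intersect(c(r$mcn$mapped %||% character(),
                         r$mcn$unmapped %||% character()), background)
      ora_fisher(mem, term2genes, background)
    })
    names(ora) <- names(set$results)
    classification <- classify_modules(set, ora, alpha = alpha)
    utils::write.table(classification,
                       file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_metadata(list(package = "ppienrich",
                      version = as.character(utils::packageVersion("ppienrich")),
                      class_by = class_by, alpha = alpha,
                      analysis_config = set$config), out_dir)
  invisible(list(comparisons = comparisons, classification = classification))
}
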