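# Gene-module collections in GMT format.
#
# One module per line: module_id TAB description TAB member1 TAB member2 ...
# The description field doubles as a metadata carrier: when it matches the
# "key=value;key=value" convention it is parsed into an attribute map
# (namespace, direction, disease, go_level, ...), otherwise it is stored
# verbatim under `description`.

new_gene_module <- function(module_id, members, collection = "modules",
                            attrs = list()) {
  members <- unique(as.character(members))
  if (length(members) == 0L)
    stop("gene module '", module_id, "' has no members", call. = FALSE)
  structure(list(module_id = as.character(module_id), members = members,
                 collection = as.character(collection), attrs = attrs),
            class = "gene_module")
}

#' Create a gene module
#'
#' @param module_id module identifier (unique within a collection).
#' @param members character vector of gene/protein identifiers; duplicates
#'   are removed.
#' @param collection collection label (e.g. `"GO"`, `"signature"`,
#'   `"coexpression"`).
#' @param attrs named list of string metadata (e.g. `namespace`, `direction`,
#'   `disease`, `go_level`).
#' @return A `gene_module` object.
#' @export
gene_module <- function(module_id, members, collection = "modules",
                        attrs = list()) {
  new_gene_module(module_id, members, collection, attrs)
}

parse_gmt_description <- function(desc) {
  desc <- trimws(desc)
  if (grepl("^[^=;]+=[^=;]*(;[^=;]+=[^=;]*)*;?$", desc)) {
    kv <- strsplit(desc, ";", fixed = TRUE)[[1L]]
    kv <- kv[nzchar(kv)]
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(
      as.list(trimws(vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", ""))),
      trimws(vapply(parts, `[[`, "", 1L))
    )
  } else {
    list(description = desc)
  }
}

format_gmt_description <- function(attrs) {
  if (length(attrs) == 0L) return("NA")
  if (identical(names(attrs), "description")) return(attrs$description)
  paste(paste0(names(attrs), "=", unlist(attrs)), collapse = ";")
}

#' Read a gene-module collection from a GMT file
#'
#' @param path path to a GMT file (`module_id TAB description TAB members...`).
#' @param collection collection label attached to every module.
#' @return A list of [gene_module] objects (empty, with a warning, for an
#'   empty file). Duplicate member identifiers within a row are removed;
#'   descriptions following the `key=value;...` convention are parsed into
#'   the module attribute map.
#' @export
read_gmt <- function(path, collection = "modules") {
  if (!is_string(path) || !file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed GMT row at line %d: expected >= 3 tab-separated fields, found %d",
                 lineno[bad[1L]], nf[bad[1L]]), call. = FALSE)
  mods <- lapply(fields, function(f) {
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    new_gene_module(trimws(f[[1L]]), members, collection,
                    parse_gmt_description(f[[2L]]))
  })
  ids <- vapply(mods, `[[`, "", "module_id")
  if (anyDuplicated(ids))
    stop("duplicate module_id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  stats::setNames(mods, ids)
}

#' Write gene modules to a GMT file
#'
#' @param modules a list of [gene_module] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(c(m$module_id, format_gmt_description(m$attrs), m$members),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf("Gene module '%s' [%s]: %d members\n", x$module_id,
              x$collection, length(x$members)))
  if (length(x$attrs) > 0L)
    cat("  attrs: ", paste(paste0(names(x$attrs), "=", unlist(x$attrs)),
                           collapse = "; "), "\n", sep = "")
  invisible(x)
}
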