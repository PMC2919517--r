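#' Load a local identifier mapping table
#'
#' Reads a tab-separated alias table that plays the role of a local name
#' server for gene identifiers: every known alias (gene symbol, ORF name,
#' database accession, ...) is mapped to one unique internal identifier.
#' The file must have a header with columns `alias` and `internal_id` and
#' may carry an optional `namespace` column recording which identifier
#' scheme an alias belongs to.
#'
#' An alias may appear on several rows (e.g. in several namespaces) only
#' if all rows agree on the internal identifier; aliases pointing at two
#' different genes are rejected at load time, with the offending aliases
#' listed, rather than resolved by guessing.  Internal identifiers are
#' implicitly valid aliases of themselves unless an explicit row says
#' otherwise.
#'
#' @param path path to the mapping TSV (`alias<TAB>internal_id[<TAB>namespace]`).
#' @param species free-text species label carried along for reporting.
#' @return A `mapping_table` object.
#' @seealso [normalize_identifiers()]
#' @export
load_mapping <- function(path, species = "unspecified") {
  df <- read_tsv_chr(path, required = c("alias", "internal_id"))
  if (is.null(df[["namespace"]])) df$namespace <- "default"
  new_mapping_table(df[, c("alias", "internal_id", "namespace")],
                    species = species, origin = path)
}

# shared constructor for file-loaded and generated tables
new_mapping_table <- function(entries, species = "unspecified",
                              origin = "in-memory") {
  alias <- trimws(entries$alias)
  id <- trimws(entries$internal_id)
  ns <- trimws(entries$namespace %||% rep("default", length(alias)))
  bad <- which(alias == "" | id == "" | is.na(alias) | is.na(id))
  if (length(bad)) {
    stop_user("malformed mapping row(s) with empty alias or internal_id: row %s",
              paste(bad, collapse = ", "))
  }
  n_targets <- tapply(id, alias, function(x) length(unique(x)))
  amb <- names(n_targets)[n_targets > 1L]
  if (length(amb)) {
    stop_user("ambiguous alias(es) mapping to more than one internal id: %s",
              paste(sort(amb), collapse = ", "))
  }
  keep <- !duplicated(paste(alias, id, ns, sep = "\r"))
  entries <- data.frame(alias = alias[keep], internal_id = id[keep],
                        namespace = ns[keep], stringsAsFactors = FALSE)
  ids <- sort(unique(id))
  exact <- stats::setNames(id, alias)
  exact <- exact[!duplicated(names(exact))]
  self <- setdiff(ids, names(exact))
  exact <- c(exact, stats::setNames(self, self))
  # case-insensitive fallback keys, kept only where folding is unambiguous
  low <- tolower(names(exact))
  folded <- tapply(unname(exact), low, function(x) {
    u <- unique(x)
    if (length(u) == 1L) u else NA_character_
  })
  ci <- stats::setNames(as.character(folded), names(folded))
  ci <- ci[!is.na(ci)]
  structure(list(entries = entries, species = species, ids = ids,
                 exact = exact, ci = ci, origin = origin),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> %d alias entries -> %d internal ids (%s)\n",
              nrow(x$entries), length(x$ids), x$species))
  invisible(x)
}

#' Validate and normalize a vector of gene identifiers
#'
#' Cleans a raw identifier list the way a dataset is validated on entry:
#' null entries (empty or whitespace-only tokens) are dropped and counted;
#' the remaining tokens are resolved against the mapping table, first by
#' exact match and only then case-insensitively (an exact match is never
#' shadowed by a case-folded one); tokens resolving to the same internal
#' identifier are collapsed and counted as removed duplicates.  Tokens
#' that cannot be resolved are returned verbatim, in input order -- they
#' are data for the caller to report, not an error.
#'
#' The operation is idempotent: re-normalizing the mapped set returns it
#' unchanged with zero removals, and the mapped set does not depend on
#' the input order.
#'
#' @param raw character vector of identifiers as supplied by the user.
#' @param table a `mapping_table` from [load_mapping()].
#' @return A `normalization_report` list with elements `mapped` (sorted
#'   unique internal ids), `unmapped` (unresolved tokens, input order),
#'   `n_duplicates_removed` and `n_nulls_removed`.
#' @export
normalize_identifiers <- function(raw, table) {
  if (!inherits(table, "mapping_table")) {
    stop_user("`table` must be a mapping_table (see load_mapping())")
  }
  raw <- as.character(raw)
  trimmed <- trimws(raw)
  is_null <- is.na(raw) | trimmed == ""
  tokens <- raw[!is_null]
  keys <- trimmed[!is_null]
  hit <- unname(table$exact[keys])
  miss <- is.na(hit)
  if (any(miss)) hit[miss] <- unname(table$ci[tolower(keys[miss])])
  resolved <- !is.na(hit)
  mapped <- sort(unique(hit[resolved]))
  structure(list(mapped = mapped,
                 unmapped = tokens[!resolved],
                 n_duplicates_removed = sum(resolved) - length(mapped),
                 n_nulls_removed = sum(is_null)),
            class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf(paste0("<normalization_report> %d mapped, %d unmapped, ",
                     "%d duplicates removed, %d null entries removed\n"),
              length(x$mapped), length(x$unmapped),
              x$n_duplicates_removed, x$n_nulls_removed))
  if (length(x$unmapped)) {
    cat("  unmapped:", paste(utils::head(x$unmapped, 10), collapse = ", "))
    if (length(x$unmapped) > 10) cat(" ...")
    cat("\n")
  }
  invisible(x)
}

#' Write a mapping table back to TSV
#'
#' @param table a `mapping_table`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_mapping <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  write_tsv_chr(table$entries, path)
}
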