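#' Construct a literature corpus
#'
#' A corpus maps document identifiers (e.g. PubMed ids) to a title and
#' the set of genes the document is annotated with.  Every document
#' must carry at least one gene.
#'
#' @param docs named list, one entry per document id, each a list with
#'   `title` (string) and `genes` (nonempty character vector).
#' @return A `corpus` object with documents in sorted id order.
#' @export
corpus <- function(docs) {
  ids <- names(docs)
  if (length(docs) && (is.null(ids) || anyDuplicated(ids) || any(ids == ""))) {
    stop_user("document ids must be unique, non-empty names of `docs`")
  }
  docs <- lapply(docs, function(d) {
    genes <- sort(unique(as.character(d$genes)))
    genes <- genes[genes != ""]
    if (!length(genes)) stop_user("every document must carry at least one gene")
    list(title = as.character(d$title %||% ""), genes = genes)
  })
  structure(list(docs = docs[order(ids)]), class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d documents\n", length(x$docs)))
  invisible(x)
}

#' Load a paper-to-gene corpus from long TSV
#'
#' Expected layout: header `doc_id<TAB>title<TAB>gene`, one row per
#' (document, gene) association; the title must be consistent across a
#' document's rows.
#'
#' @param path TSV path.
#' @return A `corpus`.
#' @export
load_corpus <- function(path) {
  df <- read_tsv_chr(path, required = c("doc_id", "title", "gene"))
  if (!nrow(df)) return(corpus(list()))
  if (any(df$doc_id == "" | df$gene == "")) {
    stop_user("%s: malformed row(s) with empty doc_id or gene", path)
  }
  genes <- split(df$gene, df$doc_id)
  titles <- split(df$title, df$doc_id)
  docs <- stats::setNames(lapply(names(genes), function(id) {
    u <- unique(titles[[id]])
    if (length(u) > 1L) {
      stop_user("%s: document %s carries conflicting titles", path, id)
    }
    list(title = u, genes = genes[[id]])
  }), names(genes))
  corpus(docs)
}

#' Write a corpus to long TSV
#'
#' @param x a `corpus`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  rows <- do.call(rbind, c(list(
    data.frame(doc_id = character(), title = character(),
               gene = character(), stringsAsFactors = FALSE)),
    lapply(names(x$docs), function(id) {
      d <- x$docs[[id]]
      data.frame(doc_id = id, title = d$title, gene = d$genes,
                 stringsAsFactors = FALSE)
    })))
  write_tsv_chr(rows, path)
}

#' Tanimoto similarity of two gene sets
#'
#' The Tanimoto coefficient of the binary membership vectors of two
#' sets, `|A . B| / (|A| + |B| - |A . B|)` -- the intersection over the
#' union, identical to the Jaccard index.  It relates the three
#' quantities that drive literature relevance: the study list size, the
#' paper's gene count, and the genes shared by both.
#'
#' @param A,B character vectors (at least one nonempty).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(A, B) {
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  if (!length(A) && !length(B)) {
    stop_user("tanimoto: both sets are empty")
  }
  length(intersect(A, B)) / length(union(A, B))
}

#' Rank corpus documents against the study list
#'
#' Scores every document sharing at least `min_shared` genes with the
#' study list by the Tanimoto coefficient between its gene set and
#' `L1`, normalizes the scores so the best document scores 1, and sorts
#' by normalized score (descending) with ties broken by document id.
#' Documents with no overlap are omitted -- only related papers are
#' reported.
#'
#' @param L1 character vector of study genes (or a `gene_set_pair`).
#' @param corpus a `corpus`.
#' @param min_shared minimum number of shared genes (default 1).
#' @return A `ranked_documents` data frame with columns `doc_id`,
#'   `title`, `score_raw`, `score_norm`, `n_shared` and list-column
#'   `shared_genes`; zero rows when nothing overlaps.
#' @export
rank_papers <- function(L1, corpus, min_shared = 1L) {
  if (inherits(L1, "gene_set_pair")) L1 <- L1$L1
  stopifnot(inherits(corpus, "corpus"))
  L1 <- unique(as.character(L1))
  ids <- names(corpus$docs)
  shared <- lapply(corpus$docs, function(d) sort(intersect(d$genes, L1)))
  keep <- lengths(shared) >= max(1L, as.integer(min_shared))
  ids <- ids[keep]
  res <- data.frame(
    doc_id = ids,
    title = vapply(corpus$docs[keep], `[[`, "", "title"),
    score_raw = vapply(corpus$docs[keep],
                       function(d) tanimoto(d$genes, L1), 0),
    n_shared = unname(lengths(shared[keep])),
    stringsAsFactors = FALSE)
  res$score_norm <- if (nrow(res)) res$score_raw / max(res$score_raw) else numeric(0)
  res$shared_genes <- unname(shared[keep])
  res <- res[order(-res$score_norm, res$doc_id),
             c("doc_id", "title", "score_raw", "score_norm", "n_shared",
               "shared_genes"), drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ranked_documents", "data.frame")
  res
}

#' Write a ranked-document report
#'
#' TSV layout: `doc_id title score_raw score_norm n_shared
#' shared_genes` (comma-joined), rows in rank order; JSON mirrors the
#' same fields with gene arrays.
#'
#' @param results a `ranked_documents` data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_ranked <- function(results, path, format = c("tsv", "json")) {
  stopifnot(inherits(results, "ranked_documents"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(
      doc_id = results$doc_id,
      title = results$title,
      score_raw = fmt_num(results$score_raw),
      score_norm = fmt_num(results$score_norm),
      n_shared = results$n_shared,
      shared_genes = vapply(results$shared_genes, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write_tsv_chr(df, path)
  } else {
    rows <- lapply(seq_len(nrow(results)), function(i) {
      list(doc_id = results$doc_id[i], title = results$title[i],
           score_raw = results$score_raw[i],
           score_norm = results$score_norm[i],
           n_shared = results$n_shared[i],
           shared_genes = results$shared_genes[[i]])
    })
    write_json_stable(rows, path)
  }
  invisible(path)
}
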