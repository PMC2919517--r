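VOCABULARIES <- c("gene_ontology", "pathway", "homology", "chromosome", "custom")

#' Construct an annotation table
#'
#' An annotation table maps each term of one vocabulary (a Gene Ontology
#' class, a metabolic pathway, a homology family, a chromosome, ...) to
#' the set of genes annotated to it, plus a human-readable term name.
#'
#' @param vocabulary one of `"gene_ontology"`, `"pathway"`, `"homology"`,
#'   `"chromosome"`, `"custom"`.
#' @param terms named list, one entry per term id, each a list with
#'   elements `name` (string) and `genes` (nonempty character vector).
#' @param source_label free-text provenance label.
#' @param propagated logical; marks tables produced by
#'   [propagate_annotations()].
#' @return An `annotation_table` object (term ids kept in sorted order,
#'   gene sets sorted and unique).
#' @export
annotation_table <- function(vocabulary, terms, source_label = "in-memory",
                             propagated = FALSE) {
  vocabulary <- match.arg(vocabulary, VOCABULARIES)
  ids <- names(terms)
  if (length(terms) && (is.null(ids) || anyDuplicated(ids) || any(ids == ""))) {
    stop_user("term ids must be unique, non-empty names of `terms`")
  }
  terms <- lapply(terms, function(t) {
    genes <- sort(unique(as.character(t$genes)))
    genes <- genes[genes != ""]
    if (!length(genes)) stop_user("every term must annotate at least one gene")
    list(name = as.character(t$name %||% ""), genes = genes)
  })
  terms <- terms[order(ids)]
  structure(list(vocabulary = vocabulary, terms = terms,
                 source_label = source_label),
            class = "annotation_table", propagated = propagated)
}

#' @export
print.annotation_table <- function(x, ...) {
  ng <- length(unique(unlist(lapply(x$terms, `[[`, "genes"), use.names = FALSE)))
  cat(sprintf("<annotation_table> %s: %d terms over %d genes (%s%s)\n",
              x$vocabulary, length(x$terms), ng, x$source_label,
              if (isTRUE(attr(x, "propagated"))) ", propagated" else ""))
  invisible(x)
}

#' Load a term-to-gene annotation file
#'
#' Two plain-text layouts are accepted.  GMT, the de-facto gene-set
#' format: one term per line, `term_id<TAB>name<TAB>gene1<TAB>gene2...`.
#' Long TSV: a header `term_id<TAB>gene[<TAB>term_name]` followed by one
#' row per (term, gene) association.  `format = "auto"` recognizes the
#' long layout by its header.  Genes are not restricted to any
#' background at load time.
#'
#' @param path annotation file path.
#' @param vocabulary vocabulary label, see [annotation_table()].
#' @param format `"auto"`, `"gmt"` or `"tsv"`.
#' @return An `annotation_table`.
#' @export
load_annotations <- function(path, vocabulary = "custom",
                             format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_user("file not found: %s", path)
  if (format == "auto") {
    first <- strsplit(readLines(path, n = 1L, warn = FALSE), "\t",
                      fixed = TRUE)[[1]]
    format <- if (length(first) >= 2 && first[1] == "term_id" &&
                  first[2] == "gene") "tsv" else "gmt"
  }
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short)) {
      stop_user("%s: malformed GMT line(s) with fewer than 3 fields: line %s",
                path, paste(short, collapse = ", "))
    }
    ids <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(ids)) {
      stop_user("%s: duplicate term id(s): %s", path,
                paste(sort(unique(ids[duplicated(ids)])), collapse = ", "))
    }
    terms <- stats::setNames(lapply(parts, function(p) {
      list(name = p[2], genes = p[-c(1L, 2L)])
    }), ids)
  } else {
    df <- read_tsv_chr(path, required = c("term_id", "gene"))
    if (!nrow(df)) {
      return(annotation_table(vocabulary, list(), source_label = basename(path)))
    }
    if (any(df$gene == "" | df$term_id == "")) {
      stop_user("%s: malformed row(s) with empty term_id or gene", path)
    }
    nm <- df[["term_name"]]
    split_genes <- split(df$gene, df$term_id)
    names_by_term <- if (is.null(nm)) NULL else split(nm, df$term_id)
    terms <- lapply(names(split_genes), function(id) {
      name <- id
      if (!is.null(names_by_term)) {
        u <- setdiff(unique(names_by_term[[id]]), "")
        if (length(u) > 1L) {
          stop_user("%s: term %s carries conflicting names: %s",
                    path, id, paste(u, collapse = " / "))
        }
        if (length(u) == 1L) name <- u
      }
      list(name = name, genes = split_genes[[id]])
    })
    terms <- stats::setNames(terms, names(split_genes))
  }
  annotation_table(vocabulary, terms, source_label = basename(path))
}

#' Write an annotation table to GMT or long TSV
#'
#' Inverse of [load_annotations()]: loading a written table recovers the
#' original table in either format.
#'
#' @param table an `annotation_table`.
#' @param path output path.
#' @param format `"gmt"` or `"tsv"`.
#' @return The path, invisibly.
#' @export
write_annotations <- function(table, path, format = c("gmt", "tsv")) {
  stopifnot(inherits(table, "annotation_table"))
  format <- match.arg(format)
  if (format == "gmt") {
    lines <- vapply(names(table$terms), function(id) {
      t <- table$terms[[id]]
      paste(c(id, t$name, t$genes), collapse = "\t")
    }, "")
    writeLines(lines, path)
  } else {
    rows <- do.call(rbind, c(list(
      data.frame(term_id = character(), gene = character(),
                 term_name = character(), stringsAsFactors = FALSE)),
      lapply(names(table$terms), function(id) {
        t <- table$terms[[id]]
        data.frame(term_id = id, gene = t$genes, term_name = t$name,
                   stringsAsFactors = FALSE)
      })))
    write_tsv_chr(rows, path)
  }
  invisible(path)
}

#' Pair a study gene list with its background
#'
#' Builds the central study object: `L1`, the genes of interest, and
#' `L2`, all genes under study (by default the whole genome).  `L1` must
#' be contained in `L2`; under the default `"augment"` policy, study
#' genes missing from the background are added to it with a warning
#' (mirroring the convention that the background is genome-wide), while
#' `"strict"` turns the violation into an error naming the offenders.
#'
#' @param L1,L2 character vectors of normalized internal identifiers.
#' @param name dataset name.
#' @param species species label.
#' @param policy `"augment"` (default) or `"strict"`.
#' @return A `gene_set_pair` with sorted unique `L1` and `L2` and the
#'   count `n_added` of background genes added by augmentation.
#' @export
make_pair <- function(L1, L2, name = "study", species = "unspecified",
                      policy = c("augment", "strict")) {
  policy <- match.arg(policy)
  L1 <- sort(unique(as.character(L1)))
  L2 <- sort(unique(as.character(L2)))
  if (!length(L1)) stop_user("L1 (the study list) is empty")
  extra <- setdiff(L1, L2)
  n_added <- length(extra)
  if (n_added) {
    if (policy == "strict") {
      stop_user("L1 gene(s) missing from the background L2: %s",
                paste(extra, collapse = ", "))
    }
    L2 <- sort(c(L2, extra))
    warning(sprintf("%d L1 gene(s) were absent from L2 and added to the background",
                    n_added), call. = FALSE)
  }
  structure(list(L1 = L1, L2 = L2, name = name, species = species,
                 n_added = n_added),
            class = "gene_set_pair")
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat(sprintf("<gene_set_pair> '%s' (%s): |L1| = %d, |L2| = %d\n",
              x$name, x$species, length(x$L1), length(x$L2)))
  invisible(x)
}

#' Load a gene list file and normalize it
#'
#' Reads a plain-text gene list (one identifier per line; lines starting
#' with `#` are ignored) and normalizes it with
#' [normalize_identifiers()].  An empty result after normalization is an
#' error -- a dataset cannot be created from a list with no valid genes.
#'
#' @param path gene list file.
#' @param table a `mapping_table`.
#' @return List with `ids` (sorted internal identifiers) and `report`
#'   (the `normalization_report`).
#' @export
load_gene_list <- function(path, table) {
  if (!file.exists(path)) stop_user("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  report <- normalize_identifiers(lines, table)
  if (!length(report$mapped)) {
    stop_user("%s: no valid genes after normalization (%d unmapped, %d null)",
              path, length(report$unmapped), report$n_nulls_removed)
  }
  list(ids = report$mapped, report = report)
}

#' Filter the study list by an annotation criterion
#'
#' Returns the subset of `L1` annotated to one term of one vocabulary --
#' e.g. all study genes on a chromosome, in a pathway, or under a Gene
#' Ontology class.  For the Gene Ontology, supplying the ontology DAG
#' extends the criterion to the term's descendants, so a gene annotated
#' to any more specific child class is also returned.
#'
#' @param pair a `gene_set_pair`.
#' @param tables one `annotation_table` or a list of them.
#' @param criterion list (or length-2 character vector) with elements
#'   `vocabulary` and `term_id`.
#' @param dag optional `ontology_dag`, used when
#'   `vocabulary == "gene_ontology"`.
#' @return Sorted character vector, always a subset of `pair$L1`.
#' @export
filter_genes <- function(pair, tables, criterion, dag = NULL) {
  stopifnot(inherits(pair, "gene_set_pair"))
  if (inherits(tables, "annotation_table")) tables <- list(tables)
  if (is.character(criterion) && length(criterion) == 2L) {
    criterion <- list(vocabulary = criterion[[1]], term_id = criterion[[2]])
  }
  vocab <- criterion$vocabulary
  term <- criterion$term_id
  vocabs <- vapply(tables, `[[`, "", "vocabulary")
  idx <- match(vocab, vocabs)
  if (is.na(idx)) stop_user("no annotation table for vocabulary '%s'", vocab)
  tbl <- tables[[idx]]
  use_dag <- identical(vocab, "gene_ontology") && !is.null(dag)
  if (is.null(tbl$terms[[term]]) &&
      !(use_dag && term %in% dag$terms$id)) {
    stop_user("unknown term '%s' in the %s table", term, vocab)
  }
  genes <- tbl$terms[[term]]$genes %||% character(0)
  if (use_dag) {
    for (d in dag_descendants(dag, term)) {
      genes <- c(genes, tbl$terms[[d]]$genes %||% character(0))
    }
  }
  sort(intersect(unique(genes), pair$L1))
}

#' Load an experiment annotation snapshot
#'
#' The snapshot records, for prior expression studies, which genes were
#' called differentially expressed under which experimental condition:
#' TSV with header `experiment_id<TAB>factor<TAB>factor_value<TAB>gene`.
#' Duplicate rows are collapsed.
#'
#' @param path TSV path.
#' @return An `experiment_table` data frame.
#' @export
load_experiments <- function(path) {
  df <- read_tsv_chr(path, required = c("experiment_id", "factor",
                                        "factor_value", "gene"))
  df <- df[!duplicated(df[c("experiment_id", "factor", "factor_value",
                            "gene")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("experiment_table", "data.frame")
  df
}

#' Group prior experiments by factor and factor value
#'
#' For the study genes only, organizes prior-study rows into the nested
#' structure factor -> factor value -> (gene, experiment) pairs, with
#' every layer in deterministic lexicographic order.
#'
#' @param L1 character vector of study genes (or a `gene_set_pair`).
#' @param table an `experiment_table`.
#' @return Nested named list; leaves are data frames with columns
#'   `gene` and `experiment_id`.
#' @export
group_experiments <- function(L1, table) {
  if (inherits(L1, "gene_set_pair")) L1 <- L1$L1
  stopifnot(inherits(table, "experiment_table"))
  df <- table[table$gene %in% L1, , drop = FALSE]
  if (!nrow(df)) return(structure(list(), names = character(0)))
  df <- df[order(df$factor, df$factor_value, df$gene, df$experiment_id), ,
           drop = FALSE]
  out <- lapply(split(df, df$factor), function(f) {
    lapply(split(f, f$factor_value), function(v) {
      leaf <- data.frame(gene = v$gene, experiment_id = v$experiment_id,
                         stringsAsFactors = FALSE)
      rownames(leaf) <- NULL
      leaf
    })
  })
  out[order(names(out))]
}
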