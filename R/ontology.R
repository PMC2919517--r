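#' Parse an OBO 1.2 ontology subset into a rooted DAG
#'
#' Reads `[Term]` stanzas and recognizes the tags `id`, `name`,
#' `namespace`, `is_a`, `relationship: part_of` and `is_obsolete`;
#' anything else (including other stanza types) is ignored.  Obsolete
#' terms are excluded together with their edges.  Edges are directed
#' child to parent.  The result must be acyclic, carry exactly one root
#' per namespace, and every term must reach its namespace root; a cycle
#' is reported with its member terms, and a parent reference to an
#' unknown (or obsolete) identifier is an error.
#'
#' @param path path to the OBO file.
#' @return An `ontology_dag` with fields `terms` (data frame `id`,
#'   `name`, `namespace`), `edges` (data frame `child`, `parent`,
#'   `relation`), `roots` (named character, one id per namespace) and
#'   the underlying `igraph` graph.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop_user("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  default_ns <- "default"
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      cur <- NULL
      in_term <- line == "[Term]"
      if (in_term) cur <- list(parents = list(), obsolete = FALSE)
      next
    }
    if (!in_term) {
      if (grepl("^default-namespace:", line)) {
        default_ns <- trimws(sub("^default-namespace:", "", line))
      }
      next
    }
    value <- trimws(sub("^[^:]+:", "", line))
    value <- trimws(sub("\\s+!.*$", "", value))  # strip trailing OBO comment
    if (grepl("^id:", line)) {
      cur$id <- value
    } else if (grepl("^name:", line)) {
      cur$name <- value
    } else if (grepl("^namespace:", line)) {
      cur$namespace <- value
    } else if (grepl("^is_a:", line)) {
      cur$parents[[length(cur$parents) + 1L]] <- c(value, "is_a")
    } else if (grepl("^relationship:", line)) {
      f <- strsplit(value, "\\s+")[[1]]
      if (length(f) >= 2 && f[1] == "part_of") {
        cur$parents[[length(cur$parents) + 1L]] <- c(f[2], "part_of")
      }
    } else if (grepl("^is_obsolete:", line)) {
      cur$obsolete <- identical(value, "true")
    }
  }
  flush()
  if (!length(terms)) stop_user("%s: no [Term] stanzas found", path)
  obsolete <- vapply(terms, `[[`, TRUE, "obsolete")
  kept <- terms[!obsolete]
  if (!length(kept)) stop_user("%s: all terms are obsolete", path)
  ids <- vapply(kept, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop_user("%s: duplicate term id(s): %s", path,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  terms_df <- data.frame(
    id = ids,
    name = vapply(kept, function(t) t$name %||% t$id, ""),
    namespace = vapply(kept, function(t) t$namespace %||% default_ns, ""),
    stringsAsFactors = FALSE)
  edges <- do.call(rbind, c(list(
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)),
    lapply(kept, function(t) {
      if (!length(t$parents)) return(NULL)
      p <- do.call(rbind, t$parents)
      data.frame(child = t$id, parent = p[, 1], relation = p[, 2],
                 stringsAsFactors = FALSE)
    })))
  unknown <- setdiff(edges$parent, ids)
  if (length(unknown)) {
    stop_user("%s: parent reference(s) to unknown or obsolete term(s): %s",
              path, paste(sort(unique(unknown)), collapse = ", "))
  }
  new_ontology_dag(terms_df, edges)
}

# validating constructor shared by parse_obo and the synthetic generator
new_ontology_dag <- function(terms, edges) {
  edges <- edges[!duplicated(edges[c("child", "parent")]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent", "relation")],
    directed = TRUE,
    vertices = data.frame(name = terms$id, stringsAsFactors = FALSE))
  if (any(edges$child == edges$parent) || !igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1L)]
    if (!length(cyc)) cyc <- unique(edges$child[edges$child == edges$parent])
    stop_user("ontology contains a cycle involving: %s",
              paste(sort(cyc), collapse = ", "))
  }
  outdeg <- igraph::degree(g, mode = "out")
  roots <- character(0)
  for (ns in sort(unique(terms$namespace))) {
    members <- terms$id[terms$namespace == ns]
    r <- members[outdeg[members] == 0L]
    if (length(r) != 1L) {
      stop_user("namespace '%s' must have exactly one root, found %d (%s)",
                ns, length(r), paste(sort(r), collapse = ", "))
    }
    d <- igraph::distances(g, v = r, to = members, mode = "in")
    unreachable <- members[is.infinite(d[1, ])]
    if (length(unreachable)) {
      stop_user("term(s) not connected to the '%s' root: %s", ns,
                paste(sort(unreachable), collapse = ", "))
    }
    roots[ns] <- r
  }
  rownames(terms) <- NULL
  rownames(edges) <- NULL
  structure(list(terms = terms, edges = edges, roots = roots, graph = g),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d edges, %d namespace(s): %s\n",
              nrow(x$terms), nrow(x$edges), length(x$roots),
              paste(names(x$roots), collapse = ", ")))
  invisible(x)
}

#' Descendants and ancestors of an ontology term
#'
#' Descendants are the terms from which `term_id` can be reached by
#' child-to-parent edges (its more specific classes); ancestors are the
#' terms it reaches (its more general classes).  The term itself is
#' excluded.
#'
#' @param dag an `ontology_dag`.
#' @param term_id a term identifier present in the DAG.
#' @return Sorted character vector of term ids.
#' @export
dag_descendants <- function(dag, term_id) {
  reachable(dag, term_id, mode = "in")
}

#' @rdname dag_descendants
#' @export
dag_ancestors <- function(dag, term_id) {
  reachable(dag, term_id, mode = "out")
}

reachable <- function(dag, term_id, mode) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!term_id %in% dag$terms$id) {
    stop_user("unknown ontology term: %s", term_id)
  }
  ids <- names(igraph::subcomponent(dag$graph, term_id, mode = mode))
  sort(setdiff(ids, term_id))
}

dag_children <- function(dag, term_id) {
  sort(names(igraph::neighbors(dag$graph, term_id, mode = "in")))
}

#' Compute ontology term levels
#'
#' The level of a term is the minimum number of edges from its namespace
#' root down to the term (roots sit at level 0), following both `is_a`
#' and `part_of` edges.  This min-depth convention places "response to
#' stress" at level 2 and "response to heat" at level 3 under the
#' biological-process chain root - response to stimulus - response to
#' stress - response to heat.
#'
#' @param dag an `ontology_dag`.
#' @return Named integer vector, one level per term id.
#' @export
compute_levels <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  lv <- stats::setNames(rep(NA_integer_, nrow(dag$terms)), dag$terms$id)
  for (ns in names(dag$roots)) {
    members <- dag$terms$id[dag$terms$namespace == ns]
    d <- igraph::distances(dag$graph, v = dag$roots[[ns]], to = members,
                           mode = "in")
    lv[members] <- as.integer(d[1, ])
  }
  lv
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to all of that
#' term's ancestors.  This operation makes the rule explicit: each
#' term's propagated gene set is the union of its own direct
#' annotations and those of all its descendants.  Terms that end up
#' with no genes are dropped.  Propagation is idempotent and monotone
#' (an ancestor's set always contains each descendant's set).
#'
#' @param dag an `ontology_dag`; every annotated term must exist in it.
#' @param direct an `annotation_table` of direct annotations.
#' @param use_part_of propagate over `part_of` edges as well as `is_a`
#'   (default `TRUE`, the Gene Ontology true-path convention).
#' @return A propagated `annotation_table` (term names taken from the
#'   ontology).
#' @export
propagate_annotations <- function(dag, direct, use_part_of = TRUE) {
  stopifnot(inherits(dag, "ontology_dag"),
            inherits(direct, "annotation_table"))
  unknown <- setdiff(names(direct$terms), dag$terms$id)
  if (length(unknown)) {
    stop_user("annotation(s) to term(s) absent from the ontology: %s",
              paste(sort(unknown), collapse = ", "))
  }
  g <- dag$graph
  if (!use_part_of) {
    g <- igraph::subgraph_from_edges(
      g, which(igraph::E(g)$relation == "is_a"), delete.vertices = FALSE)
  }
  ord <- names(igraph::topo_sort(g, mode = "out"))  # children before parents
  parents <- lapply(igraph::adjacent_vertices(g, ord, mode = "out"), names)
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(ord)) {
    v <- ord[[i]]
    genes <- unique(c(get0(v, envir = acc, ifnotfound = character(0)),
                      direct$terms[[v]]$genes))
    if (!length(genes)) next
    assign(v, genes, envir = acc)
    for (p in parents[[i]]) {
      assign(p, c(get0(p, envir = acc, ifnotfound = character(0)), genes),
             envir = acc)
    }
  }
  ids <- sort(names(acc))
  name_of <- stats::setNames(dag$terms$name, dag$terms$id)
  terms <- stats::setNames(lapply(ids, function(id) {
    list(name = unname(name_of[[id]]), genes = get(id, envir = acc))
  }), ids)
  annotation_table(direct$vocabulary, terms,
                   source_label = paste0(direct$source_label, " (propagated)"),
                   propagated = TRUE)
}

#' Prune propagated annotations to an ontology level
#'
#' Removes every term deeper than `level`.  Because the input is
#' propagated, each gene annotated below the cut already appears at all
#' of its ancestors at or above the cut, so pruned terms are enclosed in
#' their more general counterparts: pruning the stimulus/stress/heat
#' chain at level 2 removes "response to heat" while its genes persist
#' under "response to stress".
#'
#' @param dag an `ontology_dag`.
#' @param propagated output of [propagate_annotations()].
#' @param level maximum level to keep (root = 0); `Inf` keeps everything.
#' @param levels optional precomputed [compute_levels()] result.
#' @return A propagated `annotation_table` restricted to terms with
#'   level at most `level`.
#' @export
prune_to_level <- function(dag, propagated, level, levels = NULL) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!isTRUE(attr(propagated, "propagated"))) {
    stop_user("prune_to_level() expects a propagated annotation table")
  }
  if (length(level) != 1L || is.na(level) || level < 0) {
    stop_user("prune level must be a single non-negative number")
  }
  if (is.null(levels)) levels <- compute_levels(dag)
  ids <- names(propagated$terms)
  keep <- ids[levels[ids] <= level]
  annotation_table(propagated$vocabulary, propagated$terms[keep],
                   source_label = sprintf("%s (pruned to level %s)",
                                          propagated$source_label,
                                          format(level)),
                   propagated = TRUE)
}

#' Arrange enrichment results as an ontology tree
#'
#' Builds a navigable tree over the enriched terms and their ancestors,
#' rooted at each namespace root.  Every node carries the term id, name
#' and adjusted p-value (`NA` for ancestors that are present only for
#' structure); the children of every node are sorted by p-value and then
#' term id, and a term with several parents appears under each of them.
#'
#' @param dag an `ontology_dag`.
#' @param results an `enrichment_result` data frame (see [enrich()]).
#' @return An `ontology_tree_view`: a list of root nodes, each a list
#'   with `term_id`, `name`, `p_value` and `children`.
#' @seealso [format_tree_view()]
#' @export
tree_view <- function(dag, results) {
  stopifnot(inherits(dag, "ontology_dag"))
  pv <- stats::setNames(results$p_adj, results$term_id)
  nodeset <- unique(c(results$term_id,
                      unlist(lapply(results$term_id, dag_ancestors,
                                    dag = dag), use.names = FALSE)))
  name_of <- stats::setNames(dag$terms$name, dag$terms$id)
  build <- function(id) {
    kids <- intersect(dag_children(dag, id), nodeset)
    pk <- unname(pv[kids])
    kids <- kids[order(is.na(pk), pk, kids)]
    list(term_id = id,
         name = unname(name_of[[id]]),
         p_value = if (id %in% names(pv)) unname(pv[[id]]) else NA_real_,
         children = lapply(kids, build))
  }
  roots <- intersect(unname(dag$roots), nodeset)
  structure(lapply(roots, build), class = "ontology_tree_view")
}

#' Serialize a tree view as indented text or JSON
#'
#' @param tv an `ontology_tree_view`.
#' @return `format_tree_view()`: character vector of indented lines.
#'   `tree_view_json()`: a JSON string.
#' @export
format_tree_view <- function(tv) {
  walk <- function(node, depth) {
    p <- if (is.na(node$p_value)) "-" else fmt_num(node$p_value)
    line <- sprintf("%s%s %s [p_adj=%s]",
                    strrep("  ", depth), node$term_id, node$name, p)
    c(line, unlist(lapply(node$children, walk, depth = depth + 1L),
                   use.names = FALSE))
  }
  unlist(lapply(unclass(tv), walk, depth = 0L), use.names = FALSE)
}

#' @rdname format_tree_view
#' @export
tree_view_json <- function(tv) {
  jsonlite::toJSON(unclass(tv), auto_unbox = TRUE, digits = NA, na = "null",
                   pretty = TRUE)
}

#' @export
print.ontology_tree_view <- function(x, ...) {
  cat(format_tree_view(x), sep = "\n")
  invisible(x)
}
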