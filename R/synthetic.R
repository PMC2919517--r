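#' Specify a synthetic study
#'
#' Bundles the parameters of one simulated over-representation study:
#' genome size, ontology size and shape, the number of planted
#' (truly enriched) terms with their enrichment multiplier, and the
#' study-list size.  The defaults describe the simulation conditions
#' used throughout the validation suite: a 2000-gene genome annotated
#' over a 200-term ontology, a 50-gene study list, and five planted
#' terms whose genes are five times more likely to be selected into the
#' study list than background genes.
#'
#' @param n_genes background (genome) size `N`.
#' @param n_terms number of ontology terms.
#' @param n_planted number of terms to plant enrichment in (ignored
#'   when `planted_terms` is given).
#' @param fold enrichment multiplier `>= 1`; `fold = 1` is the null
#'   model (uniform sampling, nothing planted).
#' @param l1_size study-list size, at most `n_genes`.
#' @param dag_depth,dag_branching maximum depth and per-term branching
#'   of the generated ontology.
#' @param seed integer seed; every generator derives its own named
#'   substream from it, so outputs are pure functions of the spec.
#' @param planted_terms optional named numeric vector `term_id -> fold`
#'   selecting the planted terms explicitly.
#' @return A `study_spec` object.
#' @export
study_spec <- function(n_genes = 2000L, n_terms = 200L, n_planted = 5L,
                       fold = 5, l1_size = 50L, dag_depth = 5L,
                       dag_branching = 3L, seed = 1L,
                       planted_terms = NULL) {
  if (l1_size > n_genes) stop_user("l1_size must not exceed n_genes")
  if (fold < 1) stop_user("fold must be >= 1")
  if (n_terms < 1L || dag_depth < 1L || dag_branching < 1L) {
    stop_user("n_terms, dag_depth and dag_branching must be >= 1")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_terms = as.integer(n_terms),
                 n_planted = as.integer(n_planted),
                 fold = as.numeric(fold),
                 l1_size = as.integer(l1_size),
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 seed = as.integer(seed),
                 planted_terms = planted_terms),
            class = "study_spec")
}

#' Generate a synthetic rooted ontology DAG
#'
#' Grows a single-namespace DAG of `n_terms` terms: each new term
#' attaches below an existing term with spare branching capacity and
#' depth below `dag_depth`, and a fixed 20% fraction of terms receive a
#' second parent (one in four of those extra edges is a `part_of`
#' relation), producing multi-parent terms while remaining acyclic by
#' construction.  When the spec is large enough the first five terms
#' form the named chain root - "response to stimulus" - "response to
#' stress" - "response to heat", with "response to oxidative stress" as
#' a second child of the stress term, mirroring the classic pruning
#' walkthrough.  Output is a pure function of the spec's seed.
#'
#' @param spec a `study_spec`.
#' @return List with the `ontology_dag` (`dag`) and its
#'   [compute_levels()] map (`levels`).
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  with_seed(derive_seed(spec$seed, "ontology"), {
    n <- spec$n_terms
    ids <- sprintf("SYN:%07d", seq_len(n))
    nm <- sprintf("synthetic process %04d", seq_len(n))
    nm[1] <- "biological process"
    special <- n >= 5L && spec$dag_depth >= 3L
    if (special) {
      nm[2:5] <- c("response to stimulus", "response to stress",
                   "response to heat", "response to oxidative stress")
    }
    level <- integer(n)
    parent1 <- integer(n)
    n_children <- integer(n)
    if (n >= 2L) {
      for (i in 2:n) {
        if (special && i <= 5L) {
          p <- if (i == 5L) 3L else i - 1L
        } else {
          eligible <- which(level[seq_len(i - 1L)] < spec$dag_depth)
          # the named heat / oxidative-stress terms stay specific leaf
          # classes: nothing attaches below them
          if (special) eligible <- setdiff(eligible, c(4L, 5L))
          open <- eligible[n_children[eligible] < spec$dag_branching]
          pool <- if (length(open)) open else eligible
          p <- sample_vec(pool, 1L)
        }
        parent1[i] <- p
        level[i] <- level[p] + 1L
        n_children[p] <- n_children[p] + 1L
      }
    }
    edges <- data.frame(child = ids[seq_len(n)[-1]],
                        parent = ids[parent1[seq_len(n)[-1]]],
                        relation = "is_a", stringsAsFactors = FALSE)
    n_extra <- floor(0.2 * n)
    # terms with >= 2 candidate parents; the named chain keeps its exact
    # shape (and hence its levels), so it never gains extra parents
    cand <- seq_len(n)[-seq_len(min(n, if (special) 5L else 2L))]
    if (n_extra > 0L && length(cand)) {
      chosen <- sort(sample_vec(cand, min(n_extra, length(cand))))
      extra <- lapply(chosen, function(i) {
        pool <- setdiff(seq_len(i - 1L),
                        c(parent1[i], if (special) c(4L, 5L)))
        if (!length(pool)) return(NULL)
        p <- sample_vec(pool, 1L)
        data.frame(child = ids[i], parent = ids[p],
                   relation = if (stats::runif(1) < 0.25) "part_of" else "is_a",
                   stringsAsFactors = FALSE)
      })
      edges <- do.call(rbind, c(list(edges), extra))
    }
    dag <- new_ontology_dag(
      data.frame(id = ids, name = nm, namespace = "biological_process",
                 stringsAsFactors = FALSE),
      edges)
    list(dag = dag, levels = compute_levels(dag))
  })
}

#' Write an ontology DAG to OBO 1.2
#'
#' Deterministic serialization (terms in id order, edges sorted), so a
#' fixed spec always yields a byte-identical file.
#'
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  name_of <- stats::setNames(dag$terms$name, dag$terms$id)
  ord <- order(dag$terms$id)
  lines <- c("format-version: 1.2", "")
  for (i in ord) {
    id <- dag$terms$id[i]
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    e <- e[order(e$parent), , drop = FALSE]
    stanza <- c("[Term]",
                paste0("id: ", id),
                paste0("name: ", dag$terms$name[i]),
                paste0("namespace: ", dag$terms$namespace[i]))
    for (j in seq_len(nrow(e))) {
      stanza <- c(stanza, if (e$relation[j] == "is_a") {
        sprintf("is_a: %s ! %s", e$parent[j], name_of[[e$parent[j]]])
      } else {
        sprintf("relationship: part_of %s ! %s", e$parent[j],
                name_of[[e$parent[j]]])
      })
    }
    lines <- c(lines, stanza, "")
  }
  writeLines(lines, path)
  invisible(path)
}

# pick n_planted pairwise-disjoint mid-sized terms (propagated size
# within `band` as a fraction of the genome); widens the band once
# before giving up
choose_planted <- function(propagated, n_genes, n_planted,
                           band = c(0.02, 0.06)) {
  sizes <- vapply(propagated$terms, function(t) length(t$genes), 0L)
  pick_from <- function(lo, hi, already) {
    cand <- names(sizes)[sizes >= lo * n_genes & sizes <= hi * n_genes]
    cand <- setdiff(cand, names(already))
    cand <- sample_vec(cand)
    chosen <- already
    used <- unique(unlist(lapply(names(already),
                                 function(t) propagated$terms[[t]]$genes),
                          use.names = FALSE))
    for (t in cand) {
      if (length(chosen) >= n_planted) break
      g <- propagated$terms[[t]]$genes
      if (!length(intersect(g, used))) {
        chosen <- c(chosen, stats::setNames(TRUE, t))
        used <- c(used, g)
      }
    }
    chosen
  }
  chosen <- pick_from(band[1], band[2], stats::setNames(logical(0), character(0)))
  if (length(chosen) < n_planted) {
    chosen <- pick_from(band[1] / 2, band[2] * 2, chosen)
  }
  if (length(chosen) < n_planted) {
    stop_user("could not find %d disjoint mid-sized terms to plant (found %d)",
              n_planted, length(chosen))
  }
  names(chosen)
}

#' Generate a synthetic study with planted enrichment
#'
#' Creates genes `g00001 ... gN`, annotates each gene to one ontology
#' leaf chosen uniformly, propagates the annotations, and draws the
#' study list `L1` by weighted sampling without replacement in which a
#' gene annotated under a planted term is `fold` times more likely to
#' be selected than a background gene.  When the spec does not name the
#' planted terms they are chosen (seeded) among terms whose propagated
#' gene sets are pairwise disjoint and of intermediate size (2-6% of
#' the genome), i.e. specific-but-populated classes.
#'
#' Alongside the Gene Ontology table the generator emits three flat
#' vocabularies with one planted term each: a pathway and a homology
#' family biased to contain study genes, and a chromosome assignment in
#' which study genes concentrate on the first chromosome with
#' probability `fold / (fold + n_chr - 1)` (uniform when `fold = 1`).
#'
#' @param spec a `study_spec`.
#' @param dag the `ontology_dag` from [generate_ontology()].
#' @return List with `pair` (the `gene_set_pair`), `tables` (named list
#'   of `annotation_table`s: `gene_ontology` direct annotations,
#'   `pathway`, `homology`, `chromosome`), `go_propagated` (the
#'   propagated Gene Ontology table) and `planted` (named list of
#'   planted term ids per vocabulary).
#' @export
generate_study <- function(spec, dag) {
  stopifnot(inherits(spec, "study_spec"), inherits(dag, "ontology_dag"))
  with_seed(derive_seed(spec$seed, "study"), {
    N <- spec$n_genes
    genes <- sprintf("g%0*d", max(5L, nchar(N)), seq_len(N))
    leaves <- sort(setdiff(dag$terms$id, dag$edges$parent))
    leaf_of <- sample(leaves, N, replace = TRUE)
    name_of <- stats::setNames(dag$terms$name, dag$terms$id)
    by_leaf <- split(genes, leaf_of)
    direct <- annotation_table(
      "gene_ontology",
      stats::setNames(lapply(names(by_leaf), function(t) {
        list(name = unname(name_of[[t]]), genes = by_leaf[[t]])
      }), names(by_leaf)),
      source_label = "synthetic direct annotations")
    prop <- propagate_annotations(dag, direct)

    planted <- spec$planted_terms
    if (is.null(planted)) {
      planted <- if (spec$fold > 1 && spec$n_planted > 0L) {
        stats::setNames(rep(spec$fold, spec$n_planted),
                        choose_planted(prop, N, spec$n_planted))
      } else {
        stats::setNames(numeric(0), character(0))
      }
    }
    unknown <- setdiff(names(planted), names(prop$terms))
    if (length(unknown)) {
      stop_user("planted term(s) without propagated annotations: %s",
                paste(unknown, collapse = ", "))
    }
    w <- stats::setNames(rep(1, N), genes)
    for (t in names(planted)) {
      tg <- prop$terms[[t]]$genes
      w[tg] <- pmax(w[tg], planted[[t]])
    }
    l1 <- sample(genes, spec$l1_size, prob = w)
    pair <- make_pair(l1, genes,
                      name = sprintf("synthetic study (seed %d)", spec$seed),
                      species = "synthetic", policy = "strict")

    flat <- generate_flat_tables(spec, genes, pair$L1)
    list(pair = pair,
         tables = c(list(gene_ontology = direct), flat$tables),
         go_propagated = prop,
         planted = c(list(gene_ontology = names(planted)), flat$planted))
  })
}

# pathway / homology / chromosome vocabularies with one planted term
# each; called inside the "study" RNG stream
generate_flat_tables <- function(spec, genes, l1) {
  N <- length(genes)
  bg <- setdiff(genes, l1)
  planted_on <- spec$fold > 1
  rand_terms <- function(prefix, label, n_terms, size_range) {
    stats::setNames(lapply(seq_len(n_terms), function(i) {
      list(name = sprintf("synthetic %s %03d", label, i),
           genes = sample(genes, min(sample(size_range, 1L), N)))
    }), sprintf("%s%03d", prefix, seq_len(n_terms)))
  }
  pw <- rand_terms("PWY", "pathway", 30L, 10:80)
  fam <- rand_terms("FAM", "homology family", 25L, 5:40)
  planted_list <- list(pathway = NULL, homology = NULL, chromosome = NULL)
  if (planted_on) {
    pw[["PWY001"]]$genes <- unique(c(
      sample(l1, max(1L, round(0.5 * length(l1)))),
      sample(bg, min(40L, length(bg)))))
    fam[["FAM001"]]$genes <- unique(c(
      sample(l1, max(1L, round(0.4 * length(l1)))),
      sample(bg, min(20L, length(bg)))))
    planted_list$pathway <- "PWY001"
    planted_list$homology <- "FAM001"
  }
  n_chr <- 16L
  chr_ids <- sprintf("chr%s", as.character(utils::as.roman(seq_len(n_chr))))
  chr_of <- sample(chr_ids, N, replace = TRUE)
  names(chr_of) <- genes
  if (planted_on) {
    p_move <- spec$fold / (spec$fold + n_chr - 1)
    move <- stats::runif(length(l1)) < p_move
    chr_of[l1[move]] <- chr_ids[1]
    planted_list$chromosome <- chr_ids[1]
  }
  by_chr <- split(names(chr_of), unname(chr_of))
  chr_terms <- stats::setNames(lapply(names(by_chr), function(cid) {
    list(name = cid, genes = by_chr[[cid]])
  }), names(by_chr))
  list(tables = list(
         pathway = annotation_table("pathway", pw, "synthetic pathways"),
         homology = annotation_table("homology", fam, "synthetic homology families"),
         chromosome = annotation_table("chromosome", chr_terms,
                                       "synthetic chromosome assignment")),
       planted = planted_list)
}

#' Generate a synthetic literature corpus
#'
#' One hundred documents (by default) with gene sets of 5-50 genes
#' drawn from the background, plus one planted target document whose
#' gene set covers a stated fraction of the study list -- with the
#' default 0.8 overlap the target outranks every random document by a
#' wide margin.
#'
#' @param spec a `study_spec`.
#' @param pair the study's `gene_set_pair`.
#' @param n_docs corpus size.
#' @param target_overlap fraction of `L1` covered by the target
#'   document.
#' @return A `corpus`; the planted document's id is in
#'   `attr(, "target")`.
#' @export
generate_corpus <- function(spec, pair, n_docs = 100L, target_overlap = 0.8) {
  stopifnot(inherits(spec, "study_spec"), inherits(pair, "gene_set_pair"))
  with_seed(derive_seed(spec$seed, "corpus"), {
    ids <- sprintf("DOC%04d", seq_len(n_docs))
    target <- sample(ids, 1L)
    docs <- stats::setNames(lapply(ids, function(id) {
      if (id == target) {
        n_keep <- max(1L, round(target_overlap * length(pair$L1)))
        g <- unique(c(sample(pair$L1, n_keep),
                      sample(pair$L2, min(5L, length(pair$L2)))))
        list(title = "Regulatory modules of the planted stress response (synthetic)",
             genes = g)
      } else {
        list(title = sprintf("Synthetic expression study %s", sub("DOC", "", id)),
             genes = sample(pair$L2, sample(5:50, 1L)))
      }
    }), ids)
    structure(corpus(docs), target = target)
  })
}

#' Generate a synthetic identifier mapping table
#'
#' Gives every gene two alias styles on top of the implicit
#' self-mapping: an uppercase symbol (`SYM#####`) and an ORF-style
#' lowercase name (`orf#####`), with alias numbers decoupled from gene
#' numbers by a seeded permutation.
#'
#' @param genes character vector of internal gene identifiers.
#' @param seed integer seed.
#' @return A `mapping_table`.
#' @export
generate_mapping <- function(genes, seed = 1L) {
  with_seed(derive_seed(seed, "mapping"), {
    n <- length(genes)
    perm <- sample(n)
    entries <- data.frame(
      alias = c(sprintf("SYM%05d", perm), sprintf("orf%05d", perm)),
      internal_id = c(genes, genes),
      namespace = rep(c("symbol", "orf"), each = n),
      stringsAsFactors = FALSE)
    entries <- entries[order(entries$namespace, entries$alias), , drop = FALSE]
    new_mapping_table(entries, species = "synthetic",
                      origin = "generate_mapping")
  })
}

#' Generate a synthetic prior-experiment table
#'
#' Emulates a snapshot of earlier expression studies: a handful of
#' experiments, each tagged with an experimental factor and factor
#' value, listing the genes called differentially expressed there
#' (biased to include some study genes so the grouping view is
#' populated).
#'
#' @param spec a `study_spec`.
#' @param pair the study's `gene_set_pair`.
#' @param n_experiments number of experiments.
#' @return An `experiment_table`.
#' @export
generate_experiments <- function(spec, pair, n_experiments = 8L) {
  stopifnot(inherits(spec, "study_spec"), inherits(pair, "gene_set_pair"))
  with_seed(derive_seed(spec$seed, "experiments"), {
    factors <- list(
      "heat shock" = c("none", "20C delta"),
      "growth phase" = c("exponential", "stationary"),
      "disease state" = c("control", "perturbed"),
      "carbon source" = c("glucose", "galactose"))
    rows <- lapply(seq_len(n_experiments), function(i) {
      f <- sample(names(factors), 1L)
      v <- sample(factors[[f]], 1L)
      g <- unique(c(sample(pair$L2, sample(20:60, 1L)),
                    sample(pair$L1, min(length(pair$L1), sample(5:15, 1L)))))
      data.frame(experiment_id = sprintf("E-SYN-%04d", i),
                 factor = f, factor_value = v, gene = sort(g),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df <- df[!duplicated(df), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("experiment_table", "data.frame")
    df
  })
}

#' Write a gene list to a plain-text file
#'
#' @param ids character vector of identifiers.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

write_experiments <- function(table, path) {
  stopifnot(inherits(table, "experiment_table"))
  write_tsv_chr(as.data.frame(table), path)
}

#' Write the packaged demonstration fixture
#'
#' Materializes a self-contained "heat-shock-like" study in `dir`: a
#' 35-gene study list over a yeast-sized 6000-gene genome, a 300-term
#' ontology containing the named stimulus/stress/heat chain, planted
#' enrichment under "response to heat" and "response to oxidative
#' stress", flat pathway/homology/chromosome vocabularies, a mapping
#' table, a 100-document literature corpus with a planted heat-shock
#' paper, and a prior-experiment snapshot.  The study list file is
#' written in alias form and deliberately includes one duplicate, one
#' empty line and one bogus identifier, so the validation report of the
#' creation step has something to say.
#'
#' Every file is a pure function of `seed`: rewriting the fixture with
#' the same seed is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_demo_fixture <- function(dir, seed = 2010L) {
  # heat-shock induction is strong: the two planted response terms get a
  # 50-fold selection weight so the walkthrough, like a real heat-shock
  # study, shows clearly significant classes
  spec <- study_spec(n_genes = 6000L, n_terms = 300L, fold = 5,
                     l1_size = 35L, dag_depth = 6L, dag_branching = 3L,
                     seed = seed,
                     planted_terms = c("SYN:0000004" = 50, "SYN:0000005" = 50))
  ont <- generate_ontology(spec)
  study <- generate_study(spec, ont$dag)
  lit <- generate_corpus(spec, study$pair)
  mapping <- generate_mapping(study$pair$L2, seed)
  experiments <- generate_experiments(spec, study$pair)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    obo = file.path(dir, "ontology.obo"),
    go = file.path(dir, "go.tsv"),
    pathway = file.path(dir, "pathway.gmt"),
    homology = file.path(dir, "homology.gmt"),
    chromosome = file.path(dir, "chromosome.tsv"),
    mapping = file.path(dir, "mapping.tsv"),
    l1 = file.path(dir, "l1.txt"),
    l2 = file.path(dir, "l2.txt"),
    corpus = file.path(dir, "corpus.tsv"),
    experiments = file.path(dir, "experiments.tsv"))
  write_obo(ont$dag, paths[["obo"]])
  write_annotations(study$tables$gene_ontology, paths[["go"]], "tsv")
  write_annotations(study$tables$pathway, paths[["pathway"]], "gmt")
  write_annotations(study$tables$homology, paths[["homology"]], "gmt")
  write_annotations(study$tables$chromosome, paths[["chromosome"]], "tsv")
  write_mapping(mapping, paths[["mapping"]])

  # study list in alias form, with warts for the validation report
  alias_of <- with(mapping$entries[mapping$entries$namespace == "symbol", ],
                   stats::setNames(alias, internal_id))
  l1_lines <- c(unname(alias_of[study$pair$L1]),
                unname(alias_of[study$pair$L1[1]]),  # repeated entry
                "",                                   # null entry
                "NOT-A-GENE")                         # unmappable token
  writeLines(l1_lines, paths[["l1"]])
  write_gene_list(study$pair$L2, paths[["l2"]])
  write_corpus(lit, paths[["corpus"]])
  write_experiments(experiments, paths[["experiments"]])
  invisible(paths)
}
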