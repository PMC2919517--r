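test_that("OBO parsing handles roots, chains, obsoletes and bad references", {
  one <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: T:1",
               "name: root", "namespace: test"), one)
  dag1 <- parse_obo(one)
  expect_equal(nrow(dag1$terms), 1L)
  expect_equal(nrow(dag1$edges), 0L)
  expect_equal(unname(dag1$roots), "T:1")

  dag <- parse_obo(chain_obo())
  expect_equal(nrow(dag$terms), 5L)
  expect_equal(sum(dag$edges$relation == "is_a"), 4L)
  expect_equal(unname(dag$roots["biological_process"]), "GO:0008150")

  # obsolete terms are dropped together with their edges
  obs <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "namespace: x", "",
               "[Term]", "id: B", "name: b", "namespace: x", "is_a: A", "",
               "[Term]", "id: C", "name: c", "namespace: x", "is_a: A",
               "is_obsolete: true"), obs)
  dago <- parse_obo(obs)
  expect_equal(sort(dago$terms$id), c("A", "B"))

  # a parent reference to an unknown id is an error
  bad <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "namespace: x", "",
               "[Term]", "id: B", "name: b", "namespace: x",
               "is_a: MISSING"), bad)
  expect_error(parse_obo(bad), "MISSING", class = "funset_user_error")

  # a 3-term is_a cycle is detected and its members listed
  cyc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "namespace: x", "is_a: C", "",
               "[Term]", "id: B", "name: b", "namespace: x", "is_a: A", "",
               "[Term]", "id: C", "name: c", "namespace: x", "is_a: B"), cyc)
  expect_error(parse_obo(cyc), "cycle.*A.*B.*C", class = "funset_user_error")
})

test_that("levels follow the min-distance convention of the pruning walkthrough", {
  dag <- parse_obo(chain_obo())
  lv <- compute_levels(dag)
  expect_equal(unname(lv["GO:0008150"]), 0L)
  expect_equal(unname(lv["GO:0006950"]), 2L)  # response to stress
  expect_equal(unname(lv["GO:0009408"]), 3L)  # response to heat
  expect_equal(unname(lv["GO:0006979"]), 3L)  # response to oxidative stress
})

test_that("levels agree with a BFS oracle on random DAGs", {
  for (seed in 1:25) {
    rd <- random_obo(sample(5:50, 1), seed)
    dag <- parse_obo(rd$path)
    lv <- compute_levels(dag)
    want <- oracle_levels(rd$edges, rd$root, rd$ids)
    expect_equal(lv[rd$ids], want, info = paste("seed", seed))
    # shortest-path structure: every edge shortens by at most one level,
    # and some parent attains equality
    for (i in seq_len(nrow(dag$edges))) {
      expect_lte(lv[[dag$edges$child[i]]], lv[[dag$edges$parent[i]]] + 1L)
    }
  }
})

test_that("propagation applies the true-path rule", {
  dag <- parse_obo(chain_obo())
  # gene at the deepest chain term surfaces at every ancestor
  direct <- annotation_table("gene_ontology", list(
    "GO:0009408" = list(name = "response to heat", genes = "g1")))
  prop <- propagate_annotations(dag, direct)
  expect_setequal(names(prop$terms),
                  c("GO:0008150", "GO:0050896", "GO:0006950", "GO:0009408"))
  for (t in names(prop$terms)) expect_equal(prop$terms[[t]]$genes, "g1")

  # annotations only at the root stay put
  root_only <- annotation_table("gene_ontology", list(
    "GO:0008150" = list(name = "biological_process", genes = c("g1", "g2"))))
  expect_equal(propagate_annotations(dag, root_only)$terms[["GO:0008150"]]$genes,
               c("g1", "g2"))
  expect_equal(length(propagate_annotations(dag, root_only)$terms), 1L)

  # annotation to a term missing from the ontology is an error
  stray <- annotation_table("gene_ontology", list(
    "GO:9999999" = list(name = "?", genes = "g1")))
  expect_error(propagate_annotations(dag, stray), "absent",
               class = "funset_user_error")
})

test_that("propagation matches the reachability oracle and is idempotent/monotone", {
  for (seed in 1:15) {
    rd <- random_obo(sample(10:50, 1), seed + 100)
    dag <- parse_obo(rd$path)
    direct <- random_direct(rd$ids, 60, seed + 200)
    prop <- propagate_annotations(dag, direct)
    direct_genes <- lapply(direct$terms, `[[`, "genes")
    want <- oracle_propagate(rd$edges, rd$ids, direct_genes)
    want <- want[lengths(want) > 0]
    expect_equal(lapply(prop$terms, `[[`, "genes"), want[names(prop$terms)])
    expect_setequal(names(prop$terms), names(want))
    # idempotence
    prop2 <- propagate_annotations(dag, prop)
    expect_equal(lapply(prop2$terms, `[[`, "genes"),
                 lapply(prop$terms, `[[`, "genes"))
    # ancestor monotonicity
    for (e in seq_len(nrow(dag$edges))) {
      child <- dag$edges$child[e]; parent <- dag$edges$parent[e]
      if (!is.null(prop$terms[[child]])) {
        expect_true(all(prop$terms[[child]]$genes %in%
                          prop$terms[[parent]]$genes))
      }
    }
  }
})

test_that("pruning drops deep terms whose genes persist at enclosing ancestors", {
  dag <- parse_obo(chain_obo())
  direct <- annotation_table("gene_ontology", list(
    "GO:0009408" = list(name = "response to heat", genes = c("g1", "g2")),
    "GO:0006979" = list(name = "response to oxidative stress", genes = "g3"),
    "GO:0006950" = list(name = "response to stress", genes = "g4")))
  prop <- propagate_annotations(dag, direct)
  pruned <- prune_to_level(dag, prop, 2)
  # the level-3 terms are gone ...
  expect_false(any(c("GO:0009408", "GO:0006979") %in% names(pruned$terms)))
  # ... and their genes are enclosed in the more general level-2 term
  expect_equal(pruned$terms[["GO:0006950"]]$genes, c("g1", "g2", "g3", "g4"))

  # pruning at or above the max level is the identity
  expect_equal(prune_to_level(dag, prop, Inf)$terms, prop$terms)
  expect_equal(prune_to_level(dag, prop, 3)$terms, prop$terms)

  expect_error(prune_to_level(dag, prop, -1), "non-negative",
               class = "funset_user_error")
  expect_error(prune_to_level(dag, direct, 2), "propagated",
               class = "funset_user_error")
})

test_that("pruning equals filtering the propagated table by level", {
  for (seed in 1:10) {
    rd <- random_obo(40, seed + 300)
    dag <- parse_obo(rd$path)
    prop <- propagate_annotations(dag, random_direct(rd$ids, 70, seed + 400))
    lv <- compute_levels(dag)
    L <- sample(0:4, 1)
    pruned <- prune_to_level(dag, prop, L)
    keep <- names(prop$terms)[lv[names(prop$terms)] <= L]
    expect_equal(pruned$terms, prop$terms[sort(keep)])
  }
})

test_that("the tree view spans enriched terms plus ancestors, children p-sorted", {
  dag <- parse_obo(chain_obo())
  genes <- sprintf("g%02d", 1:50)
  pair <- make_pair(genes[1:10], genes, policy = "strict")
  direct <- annotation_table("gene_ontology", list(
    "GO:0009408" = list(name = "response to heat", genes = genes[1:5]),
    "GO:0006979" = list(name = "response to oxidative stress",
                        genes = genes[c(6, 30:40)])))
  res <- enrich(pair, propagate_annotations(dag, direct))
  tv <- tree_view(dag, res)
  expect_s3_class(tv, "ontology_tree_view")
  expect_equal(length(tv), 1L)             # one namespace root
  expect_equal(tv[[1]]$term_id, "GO:0008150")
  # depth: root -> stimulus -> stress -> {heat, oxidative stress}
  stress <- tv[[1]]$children[[1]]$children[[1]]
  expect_equal(stress$term_id, "GO:0006950")
  kids <- vapply(stress$children, `[[`, "", "term_id")
  expect_setequal(kids, c("GO:0009408", "GO:0006979"))
  ps <- vapply(stress$children, `[[`, 0, "p_value")
  expect_equal(ps, sort(ps))
  # serializations carry every node
  txt <- format_tree_view(tv)
  expect_equal(length(txt), 5L)
  expect_match(txt[1], "GO:0008150")

  # property: children sorted by p then id on random enrichments
  check_sorted <- function(node) {
    if (length(node$children) > 1) {
      pv <- vapply(node$children, `[[`, 0, "p_value")
      idv <- vapply(node$children, `[[`, "", "term_id")
      expect_false(is.unsorted(order(is.na(pv), pv, idv)))
      ord <- order(is.na(pv), pv, idv)
      expect_equal(ord, seq_along(ord))
    }
    lapply(node$children, check_sorted)
    invisible(NULL)
  }
  for (seed in 1:5) {
    rd <- random_obo(30, seed + 500)
    rdag <- parse_obo(rd$path)
    rgenes <- sprintf("g%03d", 1:100)
    rpair <- make_pair(rgenes[1:30], rgenes, policy = "strict")
    rres <- enrich(rpair, propagate_annotations(
      rdag, random_direct(rd$ids, 100, seed + 600)))
    lapply(tree_view(rdag, rres), check_sorted)
  }
})
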