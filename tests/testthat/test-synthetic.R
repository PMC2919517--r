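# exact inclusion moments for successive weighted sampling without
# replacement of 2 items: enumeration over ordered pairs
exact_planted_moments <- function(w, planted) {
  W <- sum(w)
  n <- length(w)
  ids <- names(w)
  w <- unname(w)
  EX <- 0; EX2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      pr <- (w[i] / W) * (w[j] / (W - w[i]))
      x <- (ids[i] %in% planted) + (ids[j] %in% planted)
      EX <- EX + pr * x
      EX2 <- EX2 + pr * x^2
    }
  }
  c(mean = EX, var = EX2 - EX^2)
}

test_that("generators are pure functions of the spec seed", {
  spec <- study_spec(n_genes = 300, n_terms = 40, l1_size = 20,
                     dag_depth = 4, seed = 42)
  f1 <- tempfile(); f2 <- tempfile()
  write_obo(generate_ontology(spec)$dag, f1)
  write_obo(generate_ontology(spec)$dag, f2)
  expect_identical(readLines(f1), readLines(f2))

  ont <- generate_ontology(spec)
  s1 <- generate_study(spec, ont$dag)
  s2 <- generate_study(spec, ont$dag)
  expect_identical(s1$pair$L1, s2$pair$L1)
  expect_identical(s1$tables$gene_ontology$terms,
                   s2$tables$gene_ontology$terms)
  expect_identical(generate_corpus(spec, s1$pair)$docs,
                   generate_corpus(spec, s1$pair)$docs)
  # a different seed moves the draw
  spec2 <- study_spec(n_genes = 300, n_terms = 40, l1_size = 20,
                      dag_depth = 4, seed = 43)
  expect_false(identical(generate_study(spec2, generate_ontology(spec2)$dag)$pair$L1,
                         s1$pair$L1))
})

test_that("generated ontologies are acyclic, rooted, and contain the named chain", {
  # degenerate spec: a two-node chain
  tiny <- study_spec(n_genes = 10, n_terms = 2, l1_size = 2,
                     dag_depth = 1, dag_branching = 1, seed = 1)
  ont0 <- generate_ontology(tiny)
  expect_equal(nrow(ont0$dag$terms), 2L)
  expect_equal(nrow(ont0$dag$edges), 1L)

  for (seed in 1:30) {
    spec <- study_spec(n_genes = 100, n_terms = sample(5:60, 1),
                       l1_size = 10, seed = seed)
    ont <- generate_ontology(spec)
    expect_true(igraph::is_dag(ont$dag$graph))
    expect_equal(unname(ont$dag$roots), "SYN:0000001")
    expect_true(all(ont$levels <= spec$dag_depth + 1))
    # named walkthrough chain at the expected levels
    nm <- stats::setNames(ont$dag$terms$name, ont$dag$terms$id)
    expect_equal(unname(nm["SYN:0000003"]), "response to stress")
    expect_equal(unname(ont$levels["SYN:0000003"]), 2L)
    expect_equal(unname(ont$levels["SYN:0000004"]), 3L)
  }
})

test_that("null planting draws L1 uniformly and saturation confines it", {
  spec <- study_spec(n_genes = 150, n_terms = 20, l1_size = 15,
                     fold = 1, seed = 5)
  ont <- generate_ontology(spec)
  st <- generate_study(spec, ont$dag)
  expect_equal(length(st$planted$gene_ontology), 0L)
  expect_null(st$planted$pathway)
  expect_equal(length(st$pair$L1), 15L)

  # near-infinite fold on a term covering at least l1_size genes
  sizes <- vapply(st$go_propagated$terms, function(t) length(t$genes), 0L)
  big <- names(sizes)[sizes >= 15][1]
  spec_sat <- study_spec(n_genes = 150, n_terms = 20, l1_size = 15,
                         seed = 5,
                         planted_terms = stats::setNames(1e6, big))
  st_sat <- generate_study(spec_sat, ont$dag)
  expect_true(all(st_sat$pair$L1 %in% st$go_propagated$terms[[big]]$genes))
})

test_that("planted genes are selected at the exact weighted-sampling rate", {
  total_obs <- 0; total_mean <- 0; total_var <- 0
  skipped <- 0
  for (seed in 1:500) {
    spec <- study_spec(n_genes = 12, n_terms = 3, n_planted = 1, fold = 6,
                       l1_size = 2, dag_depth = 2, dag_branching = 2,
                       seed = seed,
                       planted_terms = c("SYN:0000002" = 6))
    ont <- generate_ontology(spec)
    st <- tryCatch(generate_study(spec, ont$dag),
                   funset_user_error = function(e) NULL)
    if (is.null(st)) { skipped <- skipped + 1; next }  # term drew no genes
    planted_genes <- st$go_propagated$terms[["SYN:0000002"]]$genes
    w <- stats::setNames(rep(1, 12), st$pair$L2)
    w[planted_genes] <- 6
    m <- exact_planted_moments(w, planted_genes)
    total_obs <- total_obs + sum(st$pair$L1 %in% planted_genes)
    total_mean <- total_mean + m[["mean"]]
    total_var <- total_var + m[["var"]]
  }
  expect_lt(skipped, 10)
  expect_lt(abs(total_obs - total_mean), 3 * sqrt(total_var))
})

test_that("flat vocabularies carry one planted term each, chromosomes partition", {
  spec <- study_spec(n_genes = 400, n_terms = 50, n_planted = 2, fold = 5,
                     l1_size = 30, seed = 9)
  st <- generate_study(spec, generate_ontology(spec)$dag)
  expect_setequal(names(st$tables),
                  c("gene_ontology", "pathway", "homology", "chromosome"))
  expect_equal(st$planted$pathway, "PWY001")
  expect_equal(st$planted$homology, "FAM001")
  expect_equal(st$planted$chromosome, "chrI")
  # planted pathway holds about half the study list
  pw <- st$tables$pathway$terms[["PWY001"]]$genes
  expect_gte(length(intersect(pw, st$pair$L1)), 10)
  # chromosomes partition the genome
  chr_genes <- unlist(lapply(st$tables$chromosome$terms, `[[`, "genes"),
                      use.names = FALSE)
  expect_setequal(chr_genes, st$pair$L2)
  expect_equal(anyDuplicated(chr_genes), 0L)
  # GO planted terms are pairwise disjoint mid-sized classes
  planted_sets <- lapply(st$planted$gene_ontology,
                         function(t) st$go_propagated$terms[[t]]$genes)
  expect_equal(length(planted_sets), 2L)
  expect_equal(length(intersect(planted_sets[[1]], planted_sets[[2]])), 0L)
})

test_that("the planted corpus document outranks random documents", {
  for (seed in 1:20) {
    spec <- study_spec(n_genes = 500, n_terms = 40, l1_size = 30, seed = seed)
    ont <- generate_ontology(spec)
    st <- generate_study(spec, ont$dag)
    cp <- generate_corpus(spec, st$pair, target_overlap = 0.8)
    expect_equal(length(cp$docs), 100L)
    ranked <- rank_papers(st$pair, cp)
    expect_equal(ranked$doc_id[1], attr(cp, "target"))
  }
  # a corpus fully disjoint from L1 yields an empty ranking
  null_spec <- study_spec(n_genes = 100, n_terms = 20, l1_size = 10,
                          fold = 1, seed = 3)
  st <- generate_study(null_spec, generate_ontology(null_spec)$dag)
  off_pool <- paste0("x", seq_len(50))
  cp0 <- corpus(stats::setNames(lapply(1:10, function(i) {
    list(title = "off-target", genes = sample(off_pool, 5))
  }), sprintf("D%02d", 1:10)))
  expect_equal(nrow(rank_papers(st$pair, cp0)), 0L)
})

test_that("the demonstration fixture is complete, loadable and reproducible", {
  d1 <- file.path(tempdir(), "fixture-a")
  d2 <- file.path(tempdir(), "fixture-b")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- write_demo_fixture(d1)
  p2 <- write_demo_fixture(d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]), info = f)
  }
  # loaders accept every file
  dag <- parse_obo(p1[["obo"]])
  expect_equal(unname(dag$roots), "SYN:0000001")
  map <- load_mapping(p1[["mapping"]])
  l1 <- load_gene_list(p1[["l1"]], map)
  l2 <- load_gene_list(p1[["l2"]], map)
  expect_equal(length(l1$ids), 35L)         # study-list size of the walkthrough
  expect_equal(length(l2$ids), 6000L)       # yeast-sized genome
  expect_equal(l1$report$n_duplicates_removed, 1L)
  expect_equal(l1$report$n_nulls_removed, 1L)
  expect_equal(l1$report$unmapped, "NOT-A-GENE")
  go <- load_annotations(p1[["go"]], "gene_ontology")
  expect_true(all(names(go$terms) %in% dag$terms$id))
  expect_gt(length(load_annotations(p1[["pathway"]], "pathway")$terms), 0L)
  expect_gt(length(load_corpus(p1[["corpus"]])$docs), 0L)
  expect_gt(nrow(load_experiments(p1[["experiments"]])), 0L)
})
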