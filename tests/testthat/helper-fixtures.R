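# In-code fixture builders shared across test files.

write_mapping_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  lines <- c("alias\tinternal_id\tnamespace",
             vapply(rows, function(r) {
               paste(c(r, if (length(r) == 2) "default"), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  path
}

# minimal two-alias yeast-style table: symbol and ORF name for one gene
hsp12_mapping <- function() {
  load_mapping(write_mapping_file(list(c("HSP12", "YFL014W"),
                                       c("YFL014W", "YFL014W"))))
}

# the four-term biological-process chain of the pruning walkthrough,
# plus "response to oxidative stress" as a stress sibling of heat
chain_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0008150", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0050896", "name: response to stimulus",
    "namespace: biological_process",
    "is_a: GO:0008150 ! biological_process", "",
    "[Term]", "id: GO:0006950", "name: response to stress",
    "namespace: biological_process",
    "is_a: GO:0050896 ! response to stimulus", "",
    "[Term]", "id: GO:0009408", "name: response to heat",
    "namespace: biological_process",
    "is_a: GO:0006950 ! response to stress", "",
    "[Term]", "id: GO:0006979", "name: response to oxidative stress",
    "namespace: biological_process",
    "is_a: GO:0006950 ! response to stress", ""), path)
  path
}

# random rooted single-namespace DAG written as OBO text; every term's
# parents have smaller indices, so the file is acyclic by construction
random_obo <- function(n, seed, p_extra = 0.25,
                       path = tempfile(fileext = ".obo")) {
  set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(n))
  lines <- c("format-version: 1.2", "")
  edges <- data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    stanza <- c("[Term]", paste0("id: ", ids[i]),
                paste0("name: random term ", i), "namespace: test")
    if (i > 1) {
      parents <- unique(c(sample(i - 1L, 1L),
                          if (i > 2 && stats::runif(1) < p_extra)
                            sample(i - 2L, 1L)))
      for (p in parents) {
        stanza <- c(stanza, paste0("is_a: ", ids[p]))
        edges <- rbind(edges, data.frame(child = ids[i], parent = ids[p],
                                         stringsAsFactors = FALSE))
      }
    }
    lines <- c(lines, stanza, "")
  }
  writeLines(lines, path)
  list(path = path, ids = ids, edges = edges, root = ids[1])
}

# random direct annotation table over the terms of a DAG
random_direct <- function(ids, n_genes, seed,
                          vocabulary = "gene_ontology") {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  assigned <- sample(ids, n_genes, replace = TRUE)
  by_term <- split(genes, assigned)
  annotation_table(vocabulary, stats::setNames(lapply(names(by_term), function(t) {
    list(name = t, genes = by_term[[t]])
  }), names(by_term)))
}

# a tiny pair + table with known counts for enrichment examples
planted_pair_table <- function() {
  genes <- sprintf("g%03d", 1:100)
  l1 <- genes[1:20]
  term_genes <- genes[c(1:8, 51:52)]  # K = 10, k = 8
  pair <- make_pair(l1, genes, policy = "strict")
  tbl <- annotation_table("custom", list(
    TERM1 = list(name = "planted term", genes = term_genes),
    TERM2 = list(name = "background-only term", genes = genes[60:79])))
  list(pair = pair, table = tbl)
}
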