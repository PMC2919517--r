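#' Binomial upper-tail probability
#'
#' The significance measure behind the over-representation analysis:
#' the probability of observing at least `k` annotated genes in a draw
#' of `n` study genes just by chance, when the term covers a fraction
#' `p` of the background.  Computes `P(X >= k)` for
#' `X ~ Binomial(n, p)` through the regularized incomplete beta
#' function (via [stats::pbinom()]), accurate well beyond 12
#' significant digits.  All arguments recycle.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials.
#' @param p per-trial success probability in `[0, 1]`.
#' @return Numeric vector of upper-tail probabilities.
#' @export
binomial_upper_tail <- function(k, n, p) {
  if (!length(k) || !length(n) || !length(p)) {
    stop_user("binomial_upper_tail: empty argument")
  }
  r <- suppressWarnings(cbind(k, n, p))  # recycle with length check below
  k <- r[, 1]; n <- r[, 2]; p <- r[, 3]
  if (any(is.na(k) | is.na(n) | is.na(p))) {
    stop_user("binomial_upper_tail: missing values are not allowed")
  }
  if (any(k != floor(k) | n != floor(n))) {
    stop_user("binomial_upper_tail: k and n must be integers")
  }
  if (any(k < 0 | n < 0 | k > n)) {
    stop_user("binomial_upper_tail: need 0 <= k <= n")
  }
  if (any(p < 0 | p > 1)) {
    stop_user("binomial_upper_tail: p must lie in [0, 1]")
  }
  unname(stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Benjamini-Yekutieli false discovery rate adjustment
#'
#' Step-up FDR correction valid under arbitrary dependence between the
#' tests: with order statistics `p(1) <= ... <= p(m)` and
#' `c(m) = sum(1/j, j = 1..m)`, the adjusted value at rank `i` is
#' `min(1, min over j >= i of p(j) * m * c(m) / j)`, returned in the
#' input order.  The `c(m)` inflation is what distinguishes this
#' procedure from the Benjamini-Hochberg one and makes it conservative
#' for the heavily dependent term families produced by propagating
#' annotations up an ontology.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
by_adjust <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) return(numeric(0))
  if (any(is.na(p) | p < 0 | p > 1)) {
    stop_user("by_adjust: p-values must lie in [0, 1]")
  }
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  scaled <- p[o] * m * cm / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(scaled))))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' Over-representation analysis of a gene-list pair
#'
#' For each term `t` of the vocabulary, counts the associated genes in
#' the study list `L1` (`k`) and in the background `L2` (`K`), and
#' scores the accumulation with the one-sided binomial upper tail
#' `P(X >= k)` for `X ~ Binomial(n, K/N)` where `n = |L1|` and
#' `N = |L2|`.  Genes without any annotation still count in `N`: the
#' background is all genes under study, not all annotated genes.
#'
#' The multiple-testing family is every term with `K >= 1` (terms with
#' `k = 0` enter the Benjamini-Yekutieli correction with a raw p-value
#' of 1 but are omitted from the report).  Results carry only terms
#' with `k >= 1`, sorted by `(p_adj, p_raw, term_id)`.
#'
#' For the Gene Ontology, pass a table propagated with
#' [propagate_annotations()] so that each class accumulates the genes
#' of its descendants; flat vocabularies (pathway, homology,
#' chromosome) are used as loaded.
#'
#' @param pair a `gene_set_pair`.
#' @param table an `annotation_table`.
#' @return An `enrichment_result` data frame with columns `term_id`,
#'   `term_name`, `k`, `n`, `K`, `N`, `p_raw`, `p_adj` and a
#'   list-column `genes` holding the `k` study genes of each term.
#' @export
enrich <- function(pair, table) {
  stopifnot(inherits(pair, "gene_set_pair"),
            inherits(table, "annotation_table"))
  N <- length(pair$L2)
  n <- length(pair$L1)
  genes_l2 <- lapply(table$terms, function(t) intersect(t$genes, pair$L2))
  K <- lengths(genes_l2)
  fam <- which(K >= 1L)
  if (!length(fam)) {
    stop_user("no %s term annotates any background gene", table$vocabulary)
  }
  ids <- names(table$terms)[fam]
  genes_l1 <- lapply(genes_l2[fam], function(g) sort(intersect(g, pair$L1)))
  k <- lengths(genes_l1)
  if (!any(k >= 1L)) {
    stop_user("none of the %d study genes is annotated in the %s table",
              n, table$vocabulary)
  }
  p_raw <- rep(1, length(fam))
  has <- k >= 1L
  p_raw[has] <- binomial_upper_tail(k[has], n, K[fam][has] / N)
  p_adj <- by_adjust(p_raw)
  res <- data.frame(
    term_id = ids,
    term_name = vapply(table$terms[fam], `[[`, "", "name"),
    k = unname(k),
    n = n,
    K = unname(K[fam]),
    N = N,
    p_raw = p_raw,
    p_adj = p_adj,
    stringsAsFactors = FALSE)
  res$genes <- unname(genes_l1)
  res <- res[has, , drop = FALSE]
  res <- res[order(res$p_adj, res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "vocabulary") <- table$vocabulary
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Order chromosomes by significance
#'
#' Chromosome-vocabulary results re-sorted the way a locus view lists
#' them: ascending adjusted p-value, ties broken by the number of
#' accumulated genes (descending) and then by name.
#'
#' @param results an `enrichment_result` from the chromosome vocabulary.
#' @return The reordered `enrichment_result`.
#' @export
order_chromosomes <- function(results) {
  stopifnot(inherits(results, "enrichment_result"))
  out <- results[order(results$p_adj, -results$k, results$term_name,
                       results$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep significant enrichment results
#'
#' @param results an `enrichment_result`.
#' @param alpha significance threshold on the adjusted p-value, in
#'   `(0, 1]`; the conventional cut-off is 0.05.
#' @return Rows with `p_adj < alpha`.
#' @export
significant <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "enrichment_result"))
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop_user("alpha must lie in (0, 1]")
  }
  # alpha = 1 keeps everything (capped p_adj values included)
  out <- results[results$p_adj < alpha | alpha == 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment report
#'
#' TSV layout: `term_id term_name k n K N p_raw p_adj genes`, the gene
#' column comma-joined, rows in the order of `results`.  The JSON
#' mirror keeps genes as arrays.
#'
#' @param results an `enrichment_result`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_enrichment <- function(results, path, format = c("tsv", "json")) {
  stopifnot(inherits(results, "enrichment_result"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(
      term_id = results$term_id,
      term_name = results$term_name,
      k = results$k, n = results$n, K = results$K, N = results$N,
      p_raw = fmt_num(results$p_raw),
      p_adj = fmt_num(results$p_adj),
      genes = vapply(results$genes, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write_tsv_chr(df, path)
  } else {
    rows <- lapply(seq_len(nrow(results)), function(i) {
      list(term_id = results$term_id[i], term_name = results$term_name[i],
           k = results$k[i], n = results$n[i], K = results$K[i],
           N = results$N[i], p_raw = results$p_raw[i],
           p_adj = results$p_adj[i], genes = results$genes[[i]])
    })
    write_json_stable(list(vocabulary = attr(results, "vocabulary"),
                           results = rows), path)
  }
  invisible(path)
}
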