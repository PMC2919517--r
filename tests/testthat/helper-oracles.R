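# Independent brute-force oracles. Each is deliberately written from the
# definition, without reusing the package's code paths.

# upper-tail binomial probability by log-space pmf summation
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Benjamini-Yekutieli step-up, direct double-loop over the sorted values
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) ps[j] * m * cm / j, 0)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# shortest edge distance from `root` following parent -> child direction,
# by plain breadth-first search over the edge list
oracle_levels <- function(edges, root, ids) {
  children_of <- split(edges$child, edges$parent)
  lv <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  lv[root] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children_of[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lv[nxt])]
    lv[nxt] <- d
    frontier <- nxt
  }
  lv
}

# all terms from which `id` is reachable via child -> parent edges
# (i.e. its descendants), by fixed-point iteration
oracle_descendants <- function(edges, id) {
  desc <- character(0)
  repeat {
    new <- edges$child[edges$parent %in% c(id, desc)]
    new <- setdiff(unique(new), c(desc, id))
    if (!length(new)) break
    desc <- c(desc, new)
  }
  sort(desc)
}

# propagated gene set of every term: union of direct annotations over the
# term and its descendants
oracle_propagate <- function(edges, ids, direct_genes) {
  out <- lapply(ids, function(t) {
    members <- c(t, oracle_descendants(edges, t))
    sort(unique(unlist(direct_genes[members], use.names = FALSE)))
  })
  stats::setNames(out, ids)
}

# straightforward dictionary lookup mirror of identifier normalization
oracle_normalize <- function(raw, exact, ci) {
  trimmed <- trimws(raw)
  nulls <- trimmed == ""
  tok <- raw[!nulls]
  key <- trimmed[!nulls]
  hits <- character(0)
  unmapped <- character(0)
  for (i in seq_along(key)) {
    if (key[i] %in% names(exact)) {
      hits <- c(hits, exact[[key[i]]])
    } else if (tolower(key[i]) %in% names(ci)) {
      hits <- c(hits, ci[[tolower(key[i])]])
    } else {
      unmapped <- c(unmapped, tok[i])
    }
  }
  list(mapped = sort(unique(hits)), unmapped = unmapped,
       n_duplicates_removed = length(hits) - length(unique(hits)),
       n_nulls_removed = sum(nulls))
}

# score-then-sort literature ranking oracle
oracle_rank <- function(L1, docs, min_shared = 1) {
  L1 <- unique(L1)
  rows <- lapply(sort(names(docs)), function(id) {
    g <- unique(docs[[id]]$genes)
    inter <- length(intersect(g, L1))
    if (inter < min_shared) return(NULL)
    data.frame(doc_id = id,
               score_raw = inter / length(union(g, L1)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) return(character(0))
  df$score_norm <- df$score_raw / max(df$score_raw)
  df$doc_id[order(-df$score_norm, df$doc_id)]
}
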