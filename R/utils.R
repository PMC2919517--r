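`%||%` <- function(x, y) if (is.null(x)) y else x

# user-facing errors carry a dedicated condition class so the CLI can
# separate bad input (exit 1) from internal failures (exit 2)
stop_user <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("funset_user_error", "error", "condition")))
}

# Evaluate `code` under a fixed seed, then restore the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# One user-facing seed drives a named substream per generator, so the
# ontology, study, corpus, mapping and experiment draws are decoupled.
# The derived value stays below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream) {
  streams <- c(ontology = 11L, study = 23L, corpus = 37L,
               mapping = 41L, experiments = 43L, misc = 53L)
  if (!stream %in% names(streams)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1048576L) * 1024L + streams[[stream]]
}

read_tsv_chr <- function(path, required = character()) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_user("file not found: %s", paste(path, collapse = ", "))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          comment.char = "", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          blank.lines.skip = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop_user("%s: missing required column(s): %s",
              path, paste(miss, collapse = ", "))
  }
  df
}

write_tsv_chr <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# sample() without the scalar-x surprise: always draws from the elements
# of x, even when length(x) == 1
sample_vec <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

# fixed-format numbers for byte-stable reports
fmt_num <- function(x) sprintf("%.10g", x)

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
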