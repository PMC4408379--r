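# Internal helpers shared across modules.

ptm_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ptmenrich_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

collapse_ws <- function(x) trimws(gsub("[[:space:]]+", " ", x))

# slug ids: lowercase, non-alphanumerics collapsed to "-"
slugify <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "-", s)
  s <- gsub("^-+|-+$", "", s)
  s[!nzchar(s)] <- "term"
  s
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# md5 of a character vector, via a temporary file (tools::md5sum is file-based)
md5_of_lines <- function(lines) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(lines, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == trunc(x)
}
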