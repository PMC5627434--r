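# Internal helpers shared across modules.

# Canonical chromosome spelling: "M" is accepted as an alias of "MT".
normalize_chromosome <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "unknown"
  x[x == "M"] <- "MT"
  x
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# Keeps deterministic internals (k-means restarts) from consuming or
# clobbering the user's random stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Compact one-line rendering of a parameter list for provenance records.
format_params <- function(params) {
  if (length(params) == 0L) return("")
  vals <- vapply(params, function(p) {
    if (is.null(p)) return("NULL")
    if (length(p) > 6L) p <- c(p[1:6], "...")
    paste(as.character(p), collapse = ",")
  }, character(1))
  paste(sprintf("%s=%s", names(params), vals), collapse = "; ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
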