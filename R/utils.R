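`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a deterministic sub-seed from a master seed and a stream tag, so each
# generator owns an independent stream and adding one never perturbs another.
# Kept below 2^31 - 1.
substream_seed <- function(seed, tag) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (c in utf8ToInt(tag)) s <- (s * 31 + c) %% m
  as.integer(s)
}

# md5 of an R object via its canonical JSON serialization (used for stage
# resumption keys).
config_hash <- function(x) {
  if (is.list(x)) x <- unclass(x)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

# Text connection that transparently reads gzip or plain files.
read_lines_any <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
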