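# Internal helpers: deterministic seed substreams and small utilities.

# 31-bit string hash (polynomial rolling hash, stays exact in doubles).
hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(as.character(s))) h <- (h * 31 + c) %% 2147483647
  h
}

# Derive a child seed from a parent seed and any number of string tags.
# Keeps results strictly below 2^31 so they are valid R integer seeds.
substream_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tag in list(...)) h <- (h * 48271 + hash_string(tag)) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0
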