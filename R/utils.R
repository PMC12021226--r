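# Internal helpers shared across the pipeline.

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length sequences")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Substitute `n` positions of `seq_chars` (character vector of bases) at
# `positions`, always to a base different from the current one.
mutate_positions <- function(seq_chars, positions) {
  for (p in positions) {
    seq_chars[p] <- sample(setdiff(DNA_BASES, seq_chars[p]), 1L)
  }
  seq_chars
}

random_sequence <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Percent rounded to 1 decimal with ties rounded up (half-up, the convention
# the published tables use: 6.25 -> 6.3), not R's round-half-even.
pct1 <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

`%||%` <- function(a, b) if (is.null(a)) b else a
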