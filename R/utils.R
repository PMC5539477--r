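# Seed the global RNG when a seed is supplied; NULL leaves the stream alone.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647L))
  invisible(seed)
}

# Derive a stream-specific child seed from a base seed (kept within 32-bit range).
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
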