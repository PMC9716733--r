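# Internal helpers shared across modules.

# Deterministic sub-seed for a named random stream, derived from the master
# seed. Keeps every stream reproducible and independent of evaluation order.
# Result stays below 2^31 - 1 so it is a valid R integer seed.
.subSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name))
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)))
  invisible(TRUE)
}

# Window identifiers use 0-based half-open coordinates ("chrom:start-end"),
# the convention of BED and of the tiling contract; GRanges itself is
# 1-based closed, so the id shifts start by one.
.windowIds <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
}

.sameWindowUniverse <- function(a, b) {
  length(a) == length(b) && all(a == b)
}
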