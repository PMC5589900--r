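# internal helpers shared across modules

# GRanges from 0-based half-open columns (chrom, start, end)
.granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

.granges_pos <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

# comparison fuzz: strict inequalities on derived floats need an ulp guard
.EPS <- 1e-12

.clip01 <- function(x) pmin(1, pmax(0, x))

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# deterministic per-(sample, region) seed; unique for i < 2^20, j < 10007
.pair_seed <- function(seed, i, j, stream = 0L) {
  ((abs(seed) + 1) * 1000003 + stream * 479001599 + i * 10007 + j) %%
    2147483647
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0
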