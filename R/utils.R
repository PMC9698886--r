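# Internal helpers shared across modules.

# Round half away from zero (the convention behind printed integer percentages).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Centered moving average with partial windows at the edges, so no positions
# are dropped. `window` must be odd.
moving_average <- function(x, window = 11L) {
  stopifnot(window %% 2 == 1, window >= 1)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Validate a 0-based half-open interval table (chrom/start/end columns).
validate_intervals <- function(x, what = "interval", lines = NULL) {
  bad <- which(is.na(x$chrom) | x$chrom == "" |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    where <- if (is.null(lines)) bad[1] else lines[bad[1]]
    abort(sprintf(
      "invalid %s at line %d: need non-empty chrom, start >= 0, end > start (got %s:%s-%s)",
      what, where, x$chrom[bad[1]], format(x$start[bad[1]]), format(x$end[bad[1]])
    ))
  }
  invisible(x)
}

# Convert an interval tibble to an IRanges (1-based closed) per chromosome.
# Returns a list keyed by chromosome.
split_iranges <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(idx) {
    list(idx = idx,
         ranges = IRanges::IRanges(start = x$start[idx] + 1L, end = x$end[idx]))
  })
}

# sample() without the length-1 surprise.
sample_from <- function(x, size) {
  x[sample.int(length(x), size)]
}

# Format integers without scientific notation for file output.
fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

`%||%` <- rlang::`%||%`
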