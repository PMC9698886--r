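#' Reciprocal-overlap merge predicate
#'
#' Two intervals are mergeable when they sit on the same chromosome and their
#' overlap covers at least `min_frac` of *both* interval lengths (reciprocal
#' rule, boundary inclusive). Vectorized over rows.
#'
#' @param a,b Tibbles (or one-row data frames, recycled) with `chrom`,
#'   `start`, `end`.
#' @param min_frac Minimum reciprocal overlap fraction, in (0, 1]; default
#'   0.75.
#' @return Logical vector.
#' @export
peaks_mergeable <- function(a, b, min_frac = 0.75) {
  if (min_frac <= 0 || min_frac > 1) abort("min_frac must be in (0, 1]")
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  a$chrom == b$chrom &
    ov >= min_frac * (a$end - a$start) &
    ov >= min_frac * (b$end - b$start)
}

#' Build a cross-condition peak atlas by iterative merging
#'
#' Concatenates all peak calls, sorts by (chrom, start, end) and repeatedly
#' scans left to right: whenever the working interval and the next one
#' satisfy [peaks_mergeable()], both are replaced by their union span
#' (member lists concatenated) and the scan continues with the union. Passes
#' repeat until one completes with no merge (fixpoint), so no pair of output
#' peaks is mergeable. The sorted scan makes the result deterministic.
#'
#' @param peak_calls A named list of per-condition peak-call tibbles
#'   (`chrom`, `start`, `end`, ...), or a single tibble with a `source`
#'   column.
#' @param min_frac Reciprocal overlap fraction for merging (default 0.75).
#' @return An atlas tibble: `peak_id` (`chrom:start-end` at the fixpoint),
#'   `chrom`, `start`, `end`, `n_members`, `sources` (list-column of source
#'   labels) and `members` (list-column of member-interval tibbles).
#' @export
build_atlas <- function(peak_calls, min_frac = 0.75) {
  if (is.data.frame(peak_calls)) {
    if (!"source" %in% names(peak_calls)) peak_calls$source <- "peaks"
    calls <- peak_calls
  } else {
    if (length(peak_calls) == 0) abort("need at least one peak-call set")
    nms <- names(peak_calls) %||% as.character(seq_along(peak_calls))
    calls <- bind_rows(purrr::map2(peak_calls, nms,
                                   function(x, nm) mutate(x, source = nm)))
  }
  calls <- select(calls, "chrom", "start", "end", "source")
  validate_intervals(calls, what = "peak call")
  if (nrow(calls) == 0) {
    return(tibble(peak_id = character(), chrom = character(), start = integer(),
                  end = integer(), n_members = integer(),
                  sources = list(), members = list()))
  }
  chrom <- calls$chrom; start <- calls$start; end <- calls$end
  members <- as.list(seq_len(nrow(calls)))
  # Passes over the sorted list: the working interval is compared with every
  # following interval that can still overlap it (start < working end); a
  # merge replaces both with their union span and the scan continues with
  # the union. Merges in one pass can enable new ones, so passes repeat
  # until one completes with no merge -- then no pair anywhere is mergeable
  # (non-overlapping pairs never are).
  repeat {
    o <- order(chrom, start, end)
    chrom <- chrom[o]; start <- start[o]; end <- end[o]; members <- members[o]
    merged_any <- FALSE
    i <- 1L
    while (i <= length(chrom)) {
      j <- i + 1L
      while (j <= length(chrom) && chrom[j] == chrom[i] && start[j] < end[i]) {
        ov <- min(end[i], end[j]) - max(start[i], start[j])
        if (ov >= min_frac * (end[i] - start[i]) &&
            ov >= min_frac * (end[j] - start[j])) {
          start[i] <- min(start[i], start[j])
          end[i] <- max(end[i], end[j])
          members[[i]] <- c(members[[i]], members[[j]])
          chrom <- chrom[-j]; start <- start[-j]; end <- end[-j]
          members <- members[-j]
          merged_any <- TRUE
        } else {
          j <- j + 1L
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  o <- order(chrom, start, end)
  tibble(
    peak_id = sprintf("%s:%s-%s", chrom[o], fmt_int(start[o]), fmt_int(end[o])),
    chrom = chrom[o], start = as.integer(start[o]), end = as.integer(end[o]),
    n_members = lengths(members[o]),
    sources = lapply(members[o], function(idx) unique(calls$source[idx])),
    members = lapply(members[o], function(idx)
      calls[idx, c("source", "chrom", "start", "end")])
  )
}

#' Write an atlas as BED6
#'
#' `name` is the peak id and `score` the member count.
#'
#' @param atlas Atlas tibble from [build_atlas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  write_bed(tibble(chrom = atlas$chrom, start = atlas$start, end = atlas$end,
                   name = atlas$peak_id, score = atlas$n_members,
                   strand = "."), path)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param path Path to the BED6 atlas.
#' @return Tibble with `peak_id`, `chrom`, `start`, `end`, `n_members`.
#' @export
read_atlas <- function(path) {
  bed <- read_bed(path, expected_columns = 6)
  tibble(peak_id = bed$name, chrom = bed$chrom, start = bed$start,
         end = bed$end, n_members = as.integer(bed$score))
}

#' Count fragments over atlas peaks
#'
#' `counts[i, j]` is the number of fragments of sample `j` overlapping atlas
#' peak `i` by at least `min_overlap_bp` (half-open semantics). A fragment
#' overlapping several peaks contributes to all of them. Fragments on
#' chromosomes absent from the atlas are counted nowhere and tallied in the
#' `unassigned` attribute.
#'
#' @param atlas Atlas tibble from [build_atlas()].
#' @param fragments Named list of per-sample fragment tibbles
#'   (`chrom`, `start`, `end`).
#' @param min_overlap_bp Minimum overlap in bp to count (default 1).
#' @return A tibble with `peak_id` and one integer column per sample, of
#'   class `atac_counts`, with attributes `unassigned` (named integer vector)
#'   and `min_overlap_bp`.
#' @export
count_matrix <- function(atlas, fragments, min_overlap_bp = 1L) {
  if (nrow(atlas) == 0) abort("empty atlas")
  if (is.data.frame(fragments)) fragments <- list(sample = fragments)
  samples <- names(fragments)
  if (is.null(samples) || anyDuplicated(samples)) {
    abort("fragments must be a uniquely named list of per-sample tibbles")
  }
  peaks_by_chrom <- split_iranges(atlas)
  counts <- matrix(0L, nrow = nrow(atlas), ncol = length(samples),
                   dimnames = list(NULL, samples))
  unassigned <- setNames(integer(length(samples)), samples)
  for (j in seq_along(samples)) {
    fr <- fragments[[j]]
    if (nrow(fr) == 0) next
    off_chrom <- !fr$chrom %in% names(peaks_by_chrom)
    unassigned[j] <- sum(off_chrom)
    fr_by_chrom <- split(which(!off_chrom), fr$chrom[!off_chrom])
    for (chrom in names(fr_by_chrom)) {
      idx <- fr_by_chrom[[chrom]]
      fir <- IRanges::IRanges(start = fr$start[idx] + 1L, end = fr$end[idx])
      pk <- peaks_by_chrom[[chrom]]
      counts[pk$idx, j] <- counts[pk$idx, j] +
        IRanges::countOverlaps(pk$ranges, fir, minoverlap = min_overlap_bp)
    }
  }
  out <- bind_cols(tibble(peak_id = atlas$peak_id), as_tibble(counts))
  structure(out, class = c("atac_counts", class(out)),
            unassigned = unassigned, min_overlap_bp = min_overlap_bp)
}

#' Write / read a count matrix as TSV
#'
#' @param counts Count tibble from [count_matrix()].
#' @param path File path.
#' @return `path` (write) or the count tibble (read).
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  structure(out, class = c("atac_counts", class(out)))
}
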