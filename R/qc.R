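#' Fragment-length distribution with nucleosome-band mode detection
#'
#' Histograms fragment lengths into 1-bp bins over 20-800 bp (lengths outside
#' the range are tallied in an `overflow` count), smooths the histogram with
#' a centered 11-bin moving average, and reports at most one mode per
#' nucleosome band -- nucleosome-free (under 120 bp), mono-nucleosome
#' (120-250 bp) and di-nucleosome (250-500 bp) -- as the smoothed
#' argmax within the band, kept only if it exceeds 10% of the global smoothed
#' maximum. A mono-nucleosome mode near 200 bp and (for heavily amplified
#' libraries) a di-nucleosome mode near 400 bp are the expected signatures of
#' an intact ATAC library.
#'
#' @param fragments Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param smooth_window Odd moving-average window in bins (default 11).
#' @return A `length_histogram` object: list with `hist` (tibble: `length`,
#'   `count`, `smoothed`), `modes` (tibble: `band`, `length`, `height`),
#'   `overflow`, `n_fragments`.
#' @export
fragment_length_distribution <- function(fragments, smooth_window = 11L) {
  if (nrow(fragments) == 0) abort("no fragments supplied")
  len <- fragments$end - fragments$start
  if (any(len < 1)) abort("fragment with non-positive length")
  lo <- 20L; hi <- 800L
  inside <- len >= lo & len <= hi
  overflow <- sum(!inside)
  counts <- tabulate(len[inside] - lo + 1L, nbins = hi - lo + 1L)
  smoothed <- moving_average(counts, smooth_window)
  lengths_at <- lo:hi
  bands <- list("nucleosome-free" = lengths_at < 120,
                "mono-nucleosome" = lengths_at >= 120 & lengths_at <= 250,
                "di-nucleosome" = lengths_at > 250 & lengths_at <= 500)
  floor_h <- 0.10 * max(smoothed)
  modes <- purrr::imap(bands, function(sel, band) {
    if (!any(sel)) return(NULL)
    idx <- which(sel)
    top <- idx[smoothed[idx] == max(smoothed[idx])]
    # smoothing can flatten a sharp spike into a plateau: break ties by the
    # raw count, then take the middle of what remains
    top <- top[counts[top] == max(counts[top])]
    i <- top[ceiling(length(top) / 2)]
    if (smoothed[i] <= floor_h || smoothed[i] == 0) return(NULL)
    tibble(band = band, length = lengths_at[i], height = smoothed[i])
  })
  modes <- bind_rows(modes)
  if (nrow(modes) > 0) modes <- arrange(modes, .data$length)
  structure(list(hist = tibble(length = lengths_at, count = counts,
                               smoothed = smoothed),
                 modes = modes, overflow = overflow,
                 n_fragments = nrow(fragments)),
            class = "length_histogram")
}

#' @export
print.length_histogram <- function(x, ...) {
  cat(sprintf("<length_histogram> %d fragments (%d outside [20, 800])\n",
              x$n_fragments, x$overflow))
  if (nrow(x$modes) > 0) {
    cat("modes:\n"); print(as.data.frame(x$modes))
  } else cat("no modes above the 10% floor\n")
  invisible(x)
}

#' TSS enrichment profile and score
#'
#' Aggregates transposition cut sites (both fragment endpoints) around
#' transcription start sites, strand-oriented (offsets are negated for
#' `-` strand genes), over offsets -1000..+1000. The enrichment score is the
#' maximum of the smoothed profile within +/- 50 bp of the TSS divided by the
#' mean raw signal over the outermost 100-bp flanks (offsets -1000..-901 and
#' +901..+1000); an all-zero flank yields `Inf` with a warning. Values well
#' above 1 indicate a TSS-enriched (open-chromatin) library.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`.
#' @param genes Gene model tibble (`gene_id`, `chrom`, `tss`, `strand`), as
#'   from [read_gene_model()].
#' @param flank Half-window around the TSS in bp (default 1000).
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   require full flanks; when `NULL` the maximum fragment end per chromosome
#'   is used.
#' @param smooth_window Odd moving-average window (default 11).
#' @return A `tss_profile` object: list with `profile` (tibble: `offset`,
#'   `mean_signal`, `smoothed`), `enrichment_score`, `n_genes`.
#' @export
tss_enrichment <- function(fragments, genes, flank = 1000L,
                           chrom_sizes = NULL, smooth_window = 11L) {
  flank <- as.integer(flank)
  if (nrow(genes) == 0) abort("empty gene model")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(fragments$end, fragments$chrom, max)
  }
  ok <- genes$tss - flank >= 0 &
    genes$chrom %in% names(chrom_sizes) &
    genes$tss + flank < chrom_sizes[genes$chrom]
  genes <- genes[which(ok), , drop = FALSE]
  if (nrow(genes) == 0) abort("no gene has full flanks inside its chromosome")
  # cut sites: both fragment endpoints (the two transposition events)
  cuts <- split(c(fragments$start, fragments$end - 1L),
                rep(fragments$chrom, 2L))
  cuts <- lapply(cuts, sort)
  width <- 2L * flank + 1L
  signal <- numeric(width)
  for (i in seq_len(nrow(genes))) {
    cc <- cuts[[genes$chrom[i]]]
    if (is.null(cc)) next
    lo <- genes$tss[i] - flank; hi <- genes$tss[i] + flank
    sel <- cc[cc >= lo & cc <= hi]
    if (length(sel) == 0) next
    off <- sel - genes$tss[i]
    if (genes$strand[i] == "-") off <- -off
    tb <- tabulate(off + flank + 1L, nbins = width)
    signal <- signal + tb
  }
  mean_signal <- signal / nrow(genes)
  smoothed <- moving_average(mean_signal, smooth_window)
  offsets <- -flank:flank
  core <- abs(offsets) <= 50
  edge <- abs(offsets) > flank - 100
  flank_mean <- mean(mean_signal[edge])
  if (flank_mean == 0) {
    warn("flank signal is zero; enrichment score reported as Inf")
    score <- Inf
  } else {
    score <- max(smoothed[core]) / flank_mean
  }
  structure(list(profile = tibble(offset = offsets, mean_signal = mean_signal,
                                  smoothed = smoothed),
                 enrichment_score = score, n_genes = nrow(genes)),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("<tss_profile> %d genes, enrichment score %.3g\n",
              x$n_genes, x$enrichment_score))
  invisible(x)
}
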