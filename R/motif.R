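pwm_logodds <- function(pwm, background) {
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  log2(pwm$probs / background)
}

pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$probs))), drop = FALSE]
  rownames(probs) <- c("A", "C", "G", "T")
  pwm(name = pwm$name, probs = probs, pseudocount = pwm$pseudocount,
      consensus = revcomp_string(pwm$consensus), threshold = pwm$threshold)
}

seq_to_code <- function(sequence) {
  x <- utf8ToInt(toupper(sequence))
  code <- rep(NA_integer_, length(x))
  code[x == utf8ToInt("A")] <- 1L
  code[x == utf8ToInt("C")] <- 2L
  code[x == utf8ToInt("G")] <- 3L
  code[x == utf8ToInt("T")] <- 4L
  code
}

# Log-odds scores at every offset of one strand; NA where the window touches
# an N. Returns numeric(0) when the motif is longer than the sequence.
scan_scores <- function(code, lo) {
  L <- ncol(lo)
  n <- length(code) - L + 1L
  if (n < 1) return(numeric(0))
  scores <- numeric(n)
  for (k in seq_len(L)) {
    scores <- scores + unname(lo[, k])[code[k:(n + k - 1L)]]
  }
  scores
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every offset on both strands with the log2-odds of the PWM against
#' a background base composition; windows containing `N` are skipped. Minus
#' strand matches are scored on the reverse complement and reported in plus
#' strand coordinates (the 0-based offset of the match's leftmost base).
#'
#' @param sequence A single DNA string (A/C/G/T/N).
#' @param pwm A [pwm()] object.
#' @param background Base frequencies (A, C, G, T), positive, summing to 1.
#' @param threshold Minimum score in bits to report; defaults to
#'   [default_threshold()] of the PWM.
#' @return Tibble with `offset`, `strand`, `score`, sorted by offset.
#' @export
scan_pwm <- function(sequence, pwm, background = rep(0.25, 4),
                     threshold = NULL) {
  threshold <- threshold %||% default_threshold(pwm, background)
  lo <- pwm_logodds(pwm, background)
  lo_rc <- pwm_logodds(pwm_revcomp(pwm), background)
  code <- seq_to_code(sequence)
  hits <- purrr::map2(list(lo, lo_rc), c("+", "-"), function(mat, strand) {
    sc <- scan_scores(code, mat)
    keep <- which(!is.na(sc) & sc >= threshold)
    tibble(offset = keep - 1L, strand = strand, score = sc[keep])
  })
  arrange(bind_rows(hits), .data$offset, .data$strand)
}

#' Default scan threshold as a fraction of the consensus score
#'
#' The maximum attainable log2-odds score (sum of per-column maxima) times
#' `fraction`. For HOMER-dialect motifs carrying their own threshold, pass
#' `source = "file"` to use the stored value instead.
#'
#' @param pwm A [pwm()] object.
#' @param background Base frequencies (A, C, G, T).
#' @param fraction Fraction of the consensus score, in (0, 1] (default 0.8).
#' @param source `"fraction"` (default) or `"file"` (use the threshold read
#'   from a HOMER motif file).
#' @return Threshold in bits.
#' @export
default_threshold <- function(pwm, background = rep(0.25, 4), fraction = 0.8,
                              source = c("fraction", "file")) {
  source <- match.arg(source)
  if (source == "file") {
    if (is.na(pwm$threshold)) {
      abort(sprintf("motif '%s' carries no file threshold", pwm$name))
    }
    return(pwm$threshold)
  }
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  lo <- pwm_logodds(pwm, background)
  fraction * sum(apply(lo, 2, max))
}

#' Extract peak sequences from a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Named character vector of peak sequences.
#' @export
peak_sequences <- function(genome, peaks) {
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing) > 0) {
    abort(sprintf("chromosome(s) absent from genome: %s",
                  paste(missing, collapse = ", ")))
  }
  setNames(substr(genome[peaks$chrom], peaks$start + 1L, peaks$end),
           peaks$peak_id)
}

gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0) return(NA_real_)
    (n - nchar(gsub("[GC]", "", s))) / n
  }, numeric(1))
}

# Downsample background peaks so their GC distribution matches the
# foreground's decile profile.
gc_match_background <- function(fg_gc, bg_gc) {
  breaks <- unique(quantile(fg_gc, probs = 0:10 / 10))
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  fg_bin <- cut(fg_gc, breaks); bg_bin <- cut(bg_gc, breaks)
  fg_prop <- table(fg_bin) / length(fg_gc)
  bg_n <- table(bg_bin)
  ok <- fg_prop > 0
  n_total <- floor(min(bg_n[ok] / fg_prop[ok]))
  keep <- unlist(lapply(levels(bg_bin), function(b) {
    want <- round(n_total * fg_prop[b])
    idx <- which(bg_bin == b)
    if (want >= length(idx)) idx else sample_from(idx, want)
  }))
  sort(keep)
}

#' Motif enrichment in foreground vs background peaks (ZOOPS)
#'
#' Scores each peak sequence for each motif and records presence/absence
#' (zero-or-one occurrence per sequence). Enrichment of presence in the
#' foreground is tested with the upper-tail hypergeometric distribution
#' (population = all peaks, successes = peaks with a hit, draws = foreground
#' peaks), adjusted across motifs by Benjamini-Hochberg, and ranked by
#' p-value.
#'
#' @param foreground,background Peak tibbles (`peak_id`, `chrom`, `start`,
#'   `end`); they must be disjoint by `peak_id`. A natural background is the
#'   atlas minus the foreground.
#' @param genome Named character vector of chromosome sequences.
#' @param pwms Named list of [pwm()] objects.
#' @param background_freqs Base composition for log-odds scoring (default
#'   uniform).
#' @param threshold_fraction Scan threshold as a fraction of each motif's
#'   consensus score (default 0.8).
#' @param threshold_source `"fraction"` or `"file"` (HOMER thresholds).
#' @param matching `"none"` (default) or `"gc"`: downsample the background to
#'   match the foreground GC decile profile before testing.
#' @param top Optionally keep only the `top` first-ranked motifs.
#' @return Tibble with `motif`, `fg_with_hit`, `fg_total`, `bg_with_hit`,
#'   `bg_total`, `p`, `fdr`, `rank` (contiguous from 1).
#' @export
motif_enrichment <- function(foreground, background, genome, pwms,
                             background_freqs = rep(0.25, 4),
                             threshold_fraction = 0.8,
                             threshold_source = c("fraction", "file"),
                             matching = c("none", "gc"), top = NULL) {
  matching <- match.arg(matching)
  threshold_source <- match.arg(threshold_source)
  if (nrow(foreground) == 0) abort("empty foreground peak set")
  if (length(intersect(foreground$peak_id, background$peak_id)) > 0) {
    abort("foreground and background peak sets must be disjoint")
  }
  fg_seq <- peak_sequences(genome, foreground)
  bg_seq <- peak_sequences(genome, background)
  if (matching == "gc" && length(bg_seq) > 0) {
    keep <- gc_match_background(gc_fraction(fg_seq), gc_fraction(bg_seq))
    bg_seq <- bg_seq[keep]
  }
  codes_fg <- lapply(fg_seq, seq_to_code)
  codes_bg <- lapply(bg_seq, seq_to_code)
  rows <- purrr::map(pwms, function(p) {
    thr <- default_threshold(p, background_freqs, threshold_fraction,
                             source = threshold_source)
    lo <- pwm_logodds(p, background_freqs)
    lo_rc <- pwm_logodds(pwm_revcomp(p), background_freqs)
    has_hit <- function(code) {
      for (mat in list(lo, lo_rc)) {
        sc <- scan_scores(code, mat)
        if (length(sc) > 0 && any(!is.na(sc) & sc >= thr)) return(TRUE)
      }
      FALSE
    }
    fg_hit <- sum(vapply(codes_fg, has_hit, logical(1)))
    bg_hit <- sum(vapply(codes_bg, has_hit, logical(1)))
    n_fg <- length(codes_fg); n_bg <- length(codes_bg)
    pval <- phyper(fg_hit - 1, fg_hit + bg_hit,
                   n_fg + n_bg - fg_hit - bg_hit, n_fg, lower.tail = FALSE)
    tibble(motif = p$name, fg_with_hit = fg_hit, fg_total = n_fg,
           bg_with_hit = bg_hit, bg_total = n_bg, p = pval)
  })
  out <- bind_rows(rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- arrange(out, .data$p, .data$fdr, .data$motif)
  out$rank <- seq_len(nrow(out))
  if (!is.null(top)) out <- filter(out, .data$rank <= top)
  out
}
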