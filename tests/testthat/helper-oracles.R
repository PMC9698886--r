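# Independent brute-force oracles used to verify the implementations.

# Upper-tail hypergeometric P(X >= q) by direct summation of the pmf via
# log-binomial coefficients (population = m + n, successes = m, draws = k).
oracle_hyper_upper <- function(q, m, n, k) {
  xs <- max(q, max(0, k - n)):min(k, m)
  if (length(xs) == 0 || q > min(k, m)) return(0)
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

# Benjamini-Hochberg step-up, written out longhand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# All fixpoints reachable by repeatedly merging ANY mergeable pair, in any
# order (union span, reciprocal min_frac rule). Returns a list of canonical
# matrices (sorted start/end per chrom label).
oracle_fixpoint_set <- function(df, min_frac = 0.75) {
  canon <- function(s) {
    o <- order(s$chrom, s$start, s$end)
    paste(s$chrom[o], s$start[o], s$end[o], sep = ":", collapse = ";")
  }
  seen <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  recurse <- function(s) {
    key <- canon(s)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    n <- nrow(s)
    merged_any <- FALSE
    if (n >= 2) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (s$chrom[i] != s$chrom[j]) next
        ov <- min(s$end[i], s$end[j]) - max(s$start[i], s$start[j])
        if (ov >= min_frac * (s$end[i] - s$start[i]) &&
            ov >= min_frac * (s$end[j] - s$start[j])) {
          merged_any <- TRUE
          s2 <- s[-c(i, j), , drop = FALSE]
          s2 <- rbind(s2, data.frame(chrom = s$chrom[i],
                                     start = min(s$start[i], s$start[j]),
                                     end = max(s$end[i], s$end[j])))
          recurse(s2)
        }
      }
    }
    if (!merged_any) results[[key]] <- s
    invisible()
  }
  recurse(as.data.frame(df[c("chrom", "start", "end")]))
  ls(results)
}

canon_intervals <- function(s) {
  o <- order(s$chrom, s$start, s$end)
  paste(s$chrom[o], s$start[o], s$end[o], sep = ":", collapse = ";")
}

# Brute-force count of fragments overlapping each peak by >= min_bp
# (half-open intervals).
oracle_count_overlaps <- function(peaks, frags, min_bp = 1) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ov <- pmin(peaks$end[i], frags$end) - pmax(peaks$start[i], frags$start)
    sum(frags$chrom == peaks$chrom[i] & ov >= min_bp)
  }, numeric(1))
}

# Brute-force nearest gene by absolute center-to-TSS distance with
# lexicographic tie-break.
oracle_nearest_gene <- function(peak, genes) {
  center <- (peak$start + peak$end) %/% 2
  gi <- which(genes$chrom == peak$chrom)
  if (length(gi) == 0) return(list(gene_id = "none", distance = NA_real_))
  d <- abs(center - genes$tss[gi])
  cand <- gi[d == min(d)]
  g <- cand[order(genes$gene_id[cand])][1]
  signed <- if (genes$strand[g] == "+") center - genes$tss[g]
            else genes$tss[g] - center
  list(gene_id = genes$gene_id[g], distance = signed)
}

random_intervals <- function(n, max_pos = 1500, min_w = 50, max_w = 250,
                             chroms = "chr1") {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample(0:max_pos, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE), start = s,
                 end = s + w)
}

# Small deterministic count fixture: peaks x samples tibble.
make_counts <- function(mat, samples = NULL, peaks = NULL) {
  samples <- samples %||% paste0("s", seq_len(ncol(mat)))
  peaks <- peaks %||% paste0("pk", seq_len(nrow(mat)))
  out <- tibble::as_tibble(setNames(as.data.frame(mat), samples))
  dplyr::bind_cols(tibble::tibble(peak_id = peaks), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small, fast simulation shared by several test files.
small_sim <- function(seed = 7) {
  tidyatac::simulate_atac(tidyatac::sim_config(
    seed = seed, n_chroms = 1L, chrom_length = 200000L, n_genes = 30L,
    n_regions = 60L, depth = 200 * 60, background_rate = 0.002))
}
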