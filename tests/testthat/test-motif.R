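two_col_pwm <- function() {
  # (A:0.85, rest 0.05) then (C:0.85, rest 0.05)
  pwm("AC_test", matrix(c(0.85, 0.05, 0.05, 0.05,
                          0.05, 0.85, 0.05, 0.05), nrow = 4))
}

test_that("plus-strand scores match hand arithmetic", {
  p <- two_col_pwm()
  hits <- scan_pwm("AC", p, threshold = 0)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(plus$offset, 0L)
  expect_equal(plus$score, 2 * log2(0.85 / 0.25), tolerance = 1e-12)
})

test_that("a reverse-complement site scores identically on the minus strand", {
  p <- two_col_pwm()
  hits <- scan_pwm("GT", p, threshold = 2)   # GT = revcomp(AC)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "-")
  expect_equal(hits$score, 2 * log2(0.85 / 0.25), tolerance = 1e-12)
})

test_that("scan handles thresholds, N windows and short sequences", {
  p <- two_col_pwm()
  expect_equal(nrow(scan_pwm("AC", p, threshold = 10)), 0)
  expect_equal(nrow(scan_pwm("A", p, threshold = 0)), 0)   # motif longer
  expect_equal(nrow(scan_pwm("ANC", p, threshold = 0)), 0) # N windows skipped
  hits <- scan_pwm("ACAC", p, threshold = 3)
  expect_equal(hits$offset[hits$strand == "+"], c(0L, 2L))
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  withr::with_seed(163, {
    sq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  })
  p <- default_motifs()$BZIP_like
  thr <- default_threshold(p, fraction = 0.6)
  fwd <- scan_pwm(sq, p, threshold = thr)
  rcq <- chartr("ACGT", "TGCA",
                paste(rev(strsplit(sq, "")[[1]]), collapse = ""))
  rev <- scan_pwm(rcq, p, threshold = thr)
  L <- ncol(p$probs)
  mirrored <- sort(nchar(sq) - L - rev$offset)
  expect_equal(sort(fwd$offset), mirrored)
  expect_equal(sort(fwd$score), sort(rev$score))
})

test_that("default thresholds scale the consensus score", {
  uni <- pwm("uniform", matrix(0.25, 4, 3))
  expect_equal(default_threshold(uni), 0)
  p <- two_col_pwm()
  maxsc <- 2 * log2(0.85 / 0.25)
  expect_equal(default_threshold(p, fraction = 0.8), 0.8 * maxsc)
  expect_error(default_threshold(p, fraction = 0), "fraction")
  # HOMER file threshold passthrough
  ph <- pwm("homer", p$probs, threshold = 6.25)
  expect_equal(default_threshold(ph, source = "file"), 6.25)
  expect_error(default_threshold(p, source = "file"), "no file threshold")
})

test_that("inserting a consensus site adds exactly one new hit at that offset", {
  # a non-palindromic motif, so only the + strand matches the insertion
  p <- default_motifs()$RUNX_like
  thr <- default_threshold(p)   # 0.8 of consensus, far above noise
  withr::with_seed(167, {
    sq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  })
  base_hits <- scan_pwm(sq, p, threshold = thr)
  at <- 120
  sq2 <- paste0(substr(sq, 1, at), p$consensus,
                substr(sq, at + nchar(p$consensus) + 1, nchar(sq)))
  new_hits <- scan_pwm(sq2, p, threshold = thr)
  expect_equal(nrow(new_hits), nrow(base_hits) + 1)
  expect_true(at %in% new_hits$offset)
})

test_that("ZOOPS enrichment matches the extreme-case combinatorics", {
  # 10 foreground peaks all with a planted site, 10 background without:
  # p = C(10,10) C(10,0) / C(20,10) = 1/184756
  p <- default_motifs()$BZIP_like
  withr::with_seed(173, {
    mk <- function(n, plant) {
      vapply(seq_len(n), function(i) {
        s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
        if (plant) s <- paste0(substr(s, 1, 25), p$consensus,
                               substr(s, 26 + nchar(p$consensus), 60))
        s
      }, character(1))
    }
    genome <- c(chrF = paste(mk(10, TRUE), collapse = ""),
                chrB = paste(mk(10, FALSE), collapse = ""))
  })
  w <- 60L
  fg <- tibble::tibble(peak_id = sprintf("f%02d", 1:10), chrom = "chrF",
                       start = (0:9) * w, end = (1:10) * w)
  bg <- tibble::tibble(peak_id = sprintf("b%02d", 1:10), chrom = "chrB",
                       start = (0:9) * w, end = (1:10) * w)
  res <- motif_enrichment(fg, bg, genome, list(BZIP_like = p))
  expect_equal(res$fg_with_hit, 10)
  if (res$bg_with_hit == 0) {
    expect_equal(res$p, 1 / choose(20, 10), tolerance = 1e-12)
  }
  expect_equal(res$p, oracle_hyper_upper(res$fg_with_hit,
                                         res$fg_with_hit + res$bg_with_hit,
                                         20 - res$fg_with_hit - res$bg_with_hit,
                                         10), tolerance = 1e-12)
  expect_error(motif_enrichment(fg[0, ], bg, genome, list(p)), "empty foreground")
  expect_error(motif_enrichment(fg, fg, genome, list(p)), "disjoint")
})

test_that("the planted motif ranks first against the rest of the atlas", {
  sim <- small_sim(seed = 179)
  atlas <- build_atlas(sim$peak_calls)
  truth_open <- sim$truth$region_id[sim$truth$class_AgS == "opening"]
  calls <- sim$peak_calls$N
  # map atlas peaks to regions via the emitted call names
  key <- dplyr::bind_rows(sim$peak_calls)
  ov <- dplyr::inner_join(atlas, key, by = "chrom", suffix = c("", ".c"),
                          relationship = "many-to-many")
  ov <- ov[ov$start.c < ov$end & ov$end.c > ov$start, c("peak_id", "name")]
  ov <- dplyr::distinct(ov)
  fg_ids <- unique(ov$peak_id[ov$name %in% truth_open])
  fg <- atlas[atlas$peak_id %in% fg_ids, ]
  bg <- atlas[!atlas$peak_id %in% fg_ids, ]
  res <- motif_enrichment(fg, bg, sim$genome, sim$config$motifs)
  expect_equal(res$motif[1], "BZIP_like")
  expect_lt(res$fdr[1], 1e-6)
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("GC matching downsamples the background toward the foreground profile", {
  withr::with_seed(181, {
    gc_rich <- vapply(1:40, function(i) paste(
      sample(c("G", "C", "A", "T"), 100, TRUE, prob = c(.4, .4, .1, .1)),
      collapse = ""), character(1))
    at_rich <- vapply(1:200, function(i) paste(
      sample(c("G", "C", "A", "T"), 100, TRUE,
             prob = sample(list(c(.1, .1, .4, .4), c(.4, .4, .1, .1)))[[1]]),
      collapse = ""), character(1))
    genome <- c(chrF = paste(gc_rich, collapse = ""),
                chrB = paste(at_rich, collapse = ""))
    fg <- tibble::tibble(peak_id = sprintf("f%02d", 1:40), chrom = "chrF",
                         start = (0:39) * 100L, end = (1:40) * 100L)
    bg <- tibble::tibble(peak_id = sprintf("b%03d", 1:200), chrom = "chrB",
                         start = (0:199) * 100L, end = (1:200) * 100L)
    res <- motif_enrichment(fg, bg, genome, default_motifs()["KLF_like"],
                            matching = "gc")
  })
  expect_lt(res$bg_total[1], 200)  # background was downsampled
})
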