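test_that("simulation is byte-identical under a fixed seed and changes with it", {
  cfg <- sim_config(seed = 3, n_chroms = 1L, chrom_length = 100000L,
                    n_genes = 10L, n_regions = 20L, depth = 2000)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(simulate_atac(cfg), d1)
  p2 <- write_simulation(simulate_atac(cfg), d2)
  for (k in names(p1)) {
    expect_equal(unname(tools::md5sum(p1[[k]])), unname(tools::md5sum(p2[[k]])),
                 label = k)
  }
  sim_other <- simulate_atac(sim_config(seed = 4, n_chroms = 1L,
                                        chrom_length = 100000L, n_genes = 10L,
                                        n_regions = 20L, depth = 2000))
  expect_false(identical(simulate_atac(cfg)$genome, sim_other$genome))
})

test_that("regions are non-overlapping with >= 500 bp gaps", {
  cfg <- sim_config(seed = 9, n_chroms = 2L, chrom_length = 1e6, n_regions = 200L)
  g <- generate_genome(cfg)
  r <- g$regions
  expect_equal(nrow(r), 200)
  gaps <- r |>
    dplyr::group_by(chrom) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(min_gap = if (dplyr::n() < 2) Inf else
      min(start[-1] - end[-dplyr::n()]))
  expect_true(all(gaps$min_gap >= 500))
  expect_true(all(r$start >= 0 & r$end <= cfg$chrom_length))
})

test_that("an infeasible region layout errors with advice", {
  cfg <- sim_config(seed = 1, n_chroms = 1L, chrom_length = 20000L,
                    n_regions = 100L, n_genes = 5L)
  expect_error(generate_genome(cfg), "chrom_length")
})

test_that("n_regions = 0 yields an empty truth table and no region fragments", {
  cfg <- sim_config(seed = 5, n_chroms = 1L, chrom_length = 50000L,
                    n_genes = 0L, n_regions = 0L, frac_diff = c(CytP = 0, AgS = 0),
                    depth = 1000, background_rate = 0.001)
  sim <- simulate_atac(cfg)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nrow(sim$peak_calls$N), 0)
  # only background fragments remain
  expect_gt(nrow(sim$fragments$N), 0)
})

test_that("fragment lengths follow the mixture (single component mean 75)", {
  withr::with_seed(21, {
    len <- sample_fragment_lengths(10000, list(weights = c(1, 0, 0),
                                               means = c(75, 200, 400),
                                               sds = c(15, 30, 40)))
  })
  expect_true(all(len >= 20 & len <= 800))
  expect_lt(abs(mean(len) - 75), 2)
})

test_that("planted log2FC = 2 shows up as a ~4x count ratio at high depth", {
  # keep the differential fraction tiny so library composition barely moves:
  # with many differential regions the fixed per-condition depth rescales
  # every mean and the raw ratio sits below 2^lfc (that is what size factors
  # correct downstream)
  cfg <- sim_config(seed = 13, n_chroms = 1L, chrom_length = 500000L,
                    n_genes = 20L, n_regions = 100L, depth = 2000 * 100,
                    frac_diff = c(CytP = 0, AgS = 0.02),
                    frac_opening = c(CytP = 0.3, AgS = 1),
                    nb_dispersion = 0, background_rate = 0)
  sim <- simulate_atac(cfg)
  counts <- purrr::map(sim$fragments, function(fr) {
    oracle_count_overlaps(sim$regions, fr)
  })
  open_ags <- sim$truth$class_AgS == "opening"
  expect_gte(sum(open_ags), 1)
  ratio <- sum(counts$AgS[open_ags]) / sum(counts$N[open_ags])
  expect_gt(ratio, 3.5)
  expect_lt(ratio, 4.5)
})

test_that("with no planted effects the conditions are exchangeable", {
  cfg <- sim_config(seed = 17, n_chroms = 1L, chrom_length = 300000L,
                    n_genes = 10L, n_regions = 50L,
                    frac_diff = c(CytP = 0, AgS = 0), depth = 10000,
                    background_rate = 0)
  sim <- simulate_atac(cfg)
  totals <- vapply(sim$fragments, nrow, integer(1))
  # NB totals: var = sum(mu + alpha mu^2) per condition
  mu <- cfg$depth * sim$truth$acc_N / sum(sim$truth$acc_N)
  sd_total <- sqrt(2 * sum(mu + cfg$nb_dispersion * mu^2))
  expect_lt(abs(totals[["CytP"]] - totals[["N"]]), 4 * sd_total)
  expect_lt(abs(totals[["AgS"]] - totals[["N"]]), 4 * sd_total)
})

test_that("truth-table accessibility is the exact bookkeeping used for sampling", {
  sim <- small_sim(seed = 23)
  cfg <- sim$config
  for (cond in cfg$conditions) {
    acc <- sim$truth[[paste0("acc_", cond)]]
    ref <- sim$truth$acc_N
    lfc <- if (cond == "N") 0 else sim$truth[[paste0("lfc_", cond)]]
    expect_equal(acc, ref * 2^lfc, tolerance = 1e-12)
  }
})

test_that("peak calls track regions: zero jitter is exact, floor drops regions", {
  cfg <- sim_config(seed = 31, n_chroms = 1L, chrom_length = 200000L,
                    n_genes = 10L, n_regions = 40L, peak_jitter_sd = 0)
  sim <- simulate_atac(cfg)
  calls <- sim$peak_calls$N
  idx <- match(calls$name, sim$regions$region_id)
  expect_equal(calls$start, sim$regions$start[idx])
  expect_equal(calls$end, sim$regions$end[idx])

  # a region closing in CytP (acc = acc_N / 4) can drop below the floor in
  # CytP while staying in the N file
  closing <- sim$truth$region_id[sim$truth$class_CytP == "closing" &
                                   sim$truth$acc_CytP < cfg$peak_call_floor]
  if (length(closing) > 0) {
    expect_false(any(closing %in% sim$peak_calls$CytP$name))
    expect_true(all(closing %in% sim$peak_calls$N$name))
  }
  # every emitted call satisfies the floor
  for (cond in cfg$conditions) {
    expect_true(all(sim$peak_calls[[cond]]$score >= cfg$peak_call_floor))
  }
})

test_that("same-region calls across conditions stay reciprocally mergeable", {
  sim <- small_sim(seed = 37)
  calls <- dplyr::bind_rows(sim$peak_calls)
  grp <- split(calls, calls$name)
  ok <- vapply(grp, function(g) {
    if (nrow(g) < 2) return(TRUE)
    all(utils::combn(nrow(g), 2, FUN = function(ij) {
      peaks_mergeable(g[ij[1], ], g[ij[2], ], 0.75)
    }))
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("planted motif consensus sits at the center of opening regions", {
  sim <- small_sim(seed = 41)
  planted <- sim$truth[!is.na(sim$truth$motif) & sim$truth$motif == "BZIP_like", ]
  expect_gt(nrow(planted), 0)
  cons <- sim$config$motifs$BZIP_like$consensus
  hitseq <- vapply(seq_len(nrow(planted)), function(i) {
    ctr <- (planted$start[i] + planted$end[i]) %/% 2
    at <- ctr - nchar(cons) %/% 2
    substr(sim$genome[[planted$chrom[i]]], at + 1, at + nchar(cons))
  }, character(1))
  rc <- chartr("ACGT", "TGCA", vapply(hitseq, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1)))
  expect_true(all(hitseq == cons | rc == cons))
})

test_that("config validation rejects bad fractions and unknown planted motifs", {
  expect_error(sim_config(frac_diff = c(CytP = -0.1, AgS = 0.4)), "fractions")
  expect_error(sim_config(motif_plant = c(CytP = "NOPE", AgS = "BZIP_like")),
               "NOPE")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(length_mixture = list(weights = c(0.5, 0.4),
                                                means = c(75, 200),
                                                sds = c(15, 30))), "sum to 1")
})
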