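#' Plumbing peak caller: Poisson windows against a genome-wide rate
#'
#' Counts fragment midpoints in sliding windows, tests each window against
#' the genome-wide Poisson rate (upper tail), adjusts across windows by
#' Benjamini-Hochberg, and merges overlapping or book-ended significant
#' windows into peaks. Deliberately simple: it stands in for a full
#' peak-calling pipeline so fragment input can be exercised end to end.
#'
#' @param fragments Tibble with `chrom`, `start`, `end`.
#' @param chrom_sizes Named vector of chromosome lengths (required: the
#'   genome-wide rate needs the genome length).
#' @param window,step Window width and step in bp.
#' @param fdr BH threshold on window q-values.
#' @return Peak tibble: `chrom`, `start`, `end`, `score` (maximum window
#'   midpoint count in the peak), `name`, `strand`.
#' @export
simple_peak_caller <- function(fragments, chrom_sizes, window = 200L,
                               step = 50L, fdr = 0.01) {
  if (nrow(fragments) == 0) abort("no fragments supplied")
  if (missing(chrom_sizes) || is.null(chrom_sizes) || is.null(names(chrom_sizes))) {
    abort("chrom_sizes (named vector of chromosome lengths) is required")
  }
  mids <- (fragments$start + fragments$end) %/% 2L
  genome_len <- sum(chrom_sizes)
  lambda <- nrow(fragments) / genome_len * window
  wins <- purrr::imap(as.list(chrom_sizes), function(size, chrom) {
    starts <- seq(0L, max(0L, size - window), by = step)
    cc <- sort(mids[fragments$chrom == chrom])
    cnt <- findInterval(starts + window - 1L, cc) - findInterval(starts - 1L, cc)
    tibble(chrom = chrom, start = starts, end = pmin(starts + window, size),
           count = cnt)
  })
  wins <- bind_rows(wins)
  wins$p <- ppois(wins$count - 1, lambda, lower.tail = FALSE)
  wins$q <- p.adjust(wins$p, method = "BH")
  sig <- filter(wins, .data$q <= fdr, .data$count > 0)
  if (nrow(sig) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  score = numeric(), name = character(), strand = character()))
  }
  merged <- sig |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(gap = .data$start > cummax(dplyr::lag(.data$end, default = first(.data$end))),
           grp = cumsum(dplyr::if_else(row_number() == 1, TRUE, .data$gap))) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              score = max(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$start)
  tibble(chrom = merged$chrom, start = merged$start, end = merged$end,
         score = merged$score,
         name = sprintf("%s:%s-%s", merged$chrom, fmt_int(merged$start),
                        fmt_int(merged$end)),
         strand = ".")
}

pipeline_stages <- c("simulate", "qc", "atlas", "count", "diff", "overlap",
                     "annotate", "motifs", "enrich")

#' Run the full synthetic-data pipeline
#'
#' Orchestrates simulate, qc, atlas, count, diff (size factors, dispersion,
#' rlog, classification, PCA, random split), overlap, annotate, motifs and
#' enrich in dependency order, writing every stage's outputs plus a run
#' manifest (config snapshot, seeds, thresholds, and an md5 digest per output
#' file) to `outdir`. Deterministic stages reproduce identical digests on
#' rerun with the same config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param stages Character vector of stages to run (default all, in order);
#'   later stages consume prior in-memory results, so a stage can only be
#'   skipped together with everything after it or rerun from a full run's
#'   objects.
#' @param min_frac Atlas reciprocal-overlap merge fraction.
#' @param threshold rlog fold-change threshold for classification.
#' @param top_n Peaks used for PCA.
#' @param threshold_fraction Motif scan threshold fraction.
#' @param top_motifs Rows kept in the per-class motif tables.
#' @param use_peak_caller If `TRUE`, derive peak calls from the simulated
#'   fragments with [simple_peak_caller()] instead of using the generator's
#'   emitted calls.
#' @param quiet Suppress progress messages.
#' @return An `atac_run` list with every stage's objects and the manifest,
#'   invisibly.
#' @export
run_pipeline <- function(config = sim_config(), outdir,
                         stages = pipeline_stages,
                         min_frac = 0.75, threshold = log2(1.5), top_n = 500,
                         threshold_fraction = 0.8, top_motifs = 20,
                         use_peak_caller = FALSE, quiet = FALSE) {
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown) > 0) {
    warn(sprintf("unknown stage(s) ignored: %s", paste(unknown, collapse = ", ")))
    stages <- intersect(stages, pipeline_stages)
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) inform(line)
  }
  outputs <- character()
  res <- list(config = config)
  ref <- config$conditions[1]
  stim <- config$conditions[-1]
  pairs <- lapply(stim, function(s) c(ref, s))

  if ("simulate" %in% stages) {
    say("simulate: seed %d, %d regions, depth %s", config$seed,
        config$n_regions, fmt_int(config$depth))
    res$sim <- simulate_atac(config)
    outputs <- c(outputs, write_simulation(res$sim, file.path(outdir, "sim")))
  }
  sim <- res$sim
  if (is.null(sim)) abort("stage 'simulate' is required to seed the pipeline")

  if ("qc" %in% stages) {
    say("qc: fragment-length and TSS-enrichment diagnostics")
    chrom_sizes <- nchar(sim$genome)
    res$qc <- lapply(sim$fragments, function(fr) {
      list(lengths = fragment_length_distribution(fr),
           tss = tss_enrichment(fr, sim$genes, chrom_sizes = chrom_sizes))
    })
    qc_summary <- purrr::imap_dfr(res$qc, function(q, cond) {
      tibble(condition = cond,
             n_fragments = q$lengths$n_fragments,
             overflow = q$lengths$overflow,
             modes = paste(sprintf("%s:%d", q$lengths$modes$band,
                                   q$lengths$modes$length), collapse = ";"),
             tss_enrichment = q$tss$enrichment_score)
    })
    f <- file.path(outdir, "qc_summary.tsv")
    readr::write_tsv(qc_summary, f)
    outputs <- c(outputs, f)
  }

  peak_calls <- sim$peak_calls
  if (use_peak_caller) {
    say("callpeaks: simple Poisson-window caller replaces generator calls")
    peak_calls <- lapply(sim$fragments, simple_peak_caller,
                         chrom_sizes = nchar(sim$genome))
  }

  if ("atlas" %in% stages) {
    say("atlas: iterative merge at reciprocal overlap >= %.2f", min_frac)
    res$atlas <- build_atlas(peak_calls, min_frac = min_frac)
    f <- file.path(outdir, "atlas.bed")
    write_atlas(res$atlas, f)
    outputs <- c(outputs, f)
    say("atlas: %d peaks", nrow(res$atlas))
  }

  if ("count" %in% stages) {
    say("count: fragments over atlas peaks (min overlap 1 bp)")
    res$counts <- count_matrix(res$atlas, sim$fragments)
    f <- file.path(outdir, "counts.tsv")
    write_counts(res$counts, f)
    outputs <- c(outputs, f)
  }

  if ("diff" %in% stages) {
    say("diff: rlog classification at |rlogFC| >= %.4f", threshold)
    res$size_factors <- size_factors(res$counts)
    res$dispersion <- fit_dispersion(res$counts, res$size_factors)
    res$rlog <- rlog_transform(res$counts, res$size_factors, res$dispersion)
    res$classes <- lapply(setNames(pairs, stim), classify_peaks,
                          rlog = res$rlog, threshold = threshold)
    diff_tab <- purrr::imap(res$classes, function(cl, cond) {
      out <- as_tibble(cl)[, c("peak_id", "rlog_fc", "class")]
      names(out)[2:3] <- paste0(c("rlog_fc_", "class_"), cond)
      out
    })
    diff_tab <- purrr::reduce(diff_tab, left_join, by = "peak_id")
    f <- file.path(outdir, "diff.tsv")
    readr::write_tsv(diff_tab, f)
    res$pca <- pca_samples(res$rlog, top_n = top_n)
    f2 <- file.path(outdir, "pca.tsv")
    readr::write_tsv(res$pca$coords, f2)
    res$split <- random_split(res$counts$peak_id, seed = config$seed + 6L)
    f3 <- file.path(outdir, "split.tsv")
    readr::write_tsv(res$split, f3)
    outputs <- c(outputs, f, f2, f3)
    for (cond in stim) {
      n_open <- sum(res$classes[[cond]]$class == "opening")
      n_close <- sum(res$classes[[cond]]$class == "closing")
      say("diff: %s vs %s -> %d opening, %d closing", cond, ref, n_open, n_close)
    }
  }

  if ("overlap" %in% stages && length(stim) >= 2) {
    say("overlap: shared differential peaks between %s and %s", stim[1], stim[2])
    res$overlap <- overlap_summary(res$classes[[stim[1]]], res$classes[[stim[2]]])
    f <- file.path(outdir, "overlap.tsv")
    readr::write_tsv(res$overlap, f)
    outputs <- c(outputs, f)
  }

  if ("annotate" %in% stages) {
    say("annotate: nearest TSS per atlas peak")
    res$annotation <- annotate_nearest(res$atlas, sim$genes)
    f <- file.path(outdir, "annotation.tsv")
    readr::write_tsv(res$annotation, f)
    outputs <- c(outputs, f)
  }

  if ("motifs" %in% stages) {
    res$motifs <- list()
    for (cond in stim) {
      for (direction in c("opening", "closing")) {
        fg_ids <- res$classes[[cond]]$peak_id[res$classes[[cond]]$class == direction]
        if (length(fg_ids) == 0) next
        say("motifs: %s %s peaks (%d) vs rest of atlas", cond, direction,
            length(fg_ids))
        fg <- filter(res$atlas, .data$peak_id %in% fg_ids)
        bg <- filter(res$atlas, !.data$peak_id %in% fg_ids)
        tab <- motif_enrichment(fg, bg, sim$genome, config$motifs,
                                threshold_fraction = threshold_fraction,
                                top = top_motifs)
        key <- paste(cond, direction, sep = "_")
        res$motifs[[key]] <- tab
        f <- file.path(outdir, sprintf("motifs_%s.tsv", key))
        readr::write_tsv(tab, f)
        outputs <- c(outputs, f)
      }
    }
  }

  if ("enrich" %in% stages) {
    say("enrich: gene-set overrepresentation of opening-peak genes")
    sets <- make_gene_sets(sim)
    f <- file.path(outdir, "gene_sets.gmt")
    write_gmt(sets, f)
    outputs <- c(outputs, f)
    universe <- sim$genes$gene_id
    res$enrichment <- list()
    for (cond in stim) {
      ids <- res$classes[[cond]]$peak_id[res$classes[[cond]]$class != "unchanged"]
      if (length(ids) == 0) next
      anno <- res$annotation[res$annotation$peak_id %in% ids, ]
      query <- intersect(unique(anno$gene_id), universe)
      if (length(query) == 0) next
      res$enrichment[[cond]] <- geneset_enrichment(query, universe, sets)
      f <- file.path(outdir, sprintf("enrichment_%s.tsv", cond))
      readr::write_tsv(res$enrichment[[cond]], f)
      outputs <- c(outputs, f)
    }
  }

  manifest <- list(
    tool = "tidyatac",
    version = as.character(utils::packageVersion("tidyatac")),
    seed = config$seed,
    stages = stages,
    thresholds = list(min_frac = min_frac, rlog_fc = threshold, top_n = top_n,
                      scan_fraction = threshold_fraction),
    config = {
      cfg <- unclass(config); cfg$motifs <- lapply(cfg$motifs, function(p) p$consensus)
      cfg
    },
    outputs = {
      digests <- tools::md5sum(unname(outputs))
      purrr::map2(names(digests), unname(digests),
                  function(pth, dg) list(path = pth, md5 = dg))
    }
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  say("done: %d output files, manifest at %s", length(outputs), manifest_path)
  res$manifest <- manifest
  invisible(structure(res, class = "atac_run"))
}

#' @export
print.atac_run <- function(x, ...) {
  cat(sprintf("<atac_run> stages: %s\n", paste(x$manifest$stages, collapse = ", ")))
  if (!is.null(x$atlas)) cat(sprintf("  atlas peaks: %d\n", nrow(x$atlas)))
  if (!is.null(x$overlap)) {
    cat("  overlap summary:\n"); print(as.data.frame(x$overlap))
  }
  invisible(x)
}
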