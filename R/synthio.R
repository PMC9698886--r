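#' Simulation configuration for the three-condition ATAC design
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate a naive (N) / cytokine-primed (CytP) / antigen-stimulated
#' (AgS) CD8+ T-cell design in which AgS carries roughly ten times more
#' differential regions than CytP, a stated fraction of the CytP differential
#' regions is shared with AgS (one third of opening, two thirds of closing
#' regions), fragment lengths follow a nucleosome-periodic three-component
#' mixture, and a distinct transcription-factor motif is planted into each
#' stimulated condition's opening regions.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param n_chroms,chrom_length Number of chromosomes and their length (bp).
#' @param n_genes Number of genes; every TSS is placed within 200 bp of the
#'   center of a distinct accessible region so TSS enrichment is testable.
#' @param n_regions Number of accessible regions.
#' @param region_width_mean,region_width_sd Region width distribution (bp).
#' @param conditions Ordered condition labels; the first is the reference.
#' @param frac_diff Named fraction of regions truly differential (vs the
#'   reference) per non-reference condition.
#' @param frac_opening Named fraction of each condition's differential
#'   regions that open (the rest close).
#' @param shared_frac Named length-2 vector (`opening`, `closing`): fraction
#'   of the first stimulated condition's differential regions that are also
#'   differential (same direction) in the second.
#' @param effect_log2fc Magnitude of the planted log2 fold change.
#' @param depth Expected fragments per condition attributable to regions.
#' @param nb_dispersion Negative-binomial dispersion alpha of per-region
#'   counts (variance = mu + alpha * mu^2); 0 gives Poisson counts.
#' @param length_mixture List with `weights`, `means`, `sds` of the
#'   nucleosome-free / mono- / di-nucleosome fragment-length components,
#'   truncated to 20-800 bp.
#' @param background_rate Background fragments per bp per condition.
#' @param motif_plant Named character vector mapping condition to the name of
#'   the motif (in `motifs`) planted at the center of its opening regions.
#' @param motifs Named list of [pwm()] objects available for planting.
#' @param peak_jitter_sd Gaussian sd (bp) of the noise added to emitted
#'   peak-call boundaries.
#' @param peak_call_floor Accessibility below which a region is left out of a
#'   condition's peak-call file.
#' @param baseline_sdlog Log-normal sdlog of baseline region accessibility.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e6,
                       n_genes = 150L,
                       n_regions = 500L,
                       region_width_mean = 400,
                       region_width_sd = 60,
                       conditions = c("N", "CytP", "AgS"),
                       frac_diff = c(CytP = 0.04, AgS = 0.4),
                       frac_opening = c(CytP = 0.30, AgS = 0.63),
                       shared_frac = c(opening = 0.33, closing = 0.63),
                       effect_log2fc = 2,
                       depth = 200 * n_regions,
                       nb_dispersion = 0.2,
                       length_mixture = list(weights = c(0.50, 0.35, 0.15),
                                             means = c(75, 200, 400),
                                             sds = c(15, 30, 40)),
                       background_rate = 0.005,
                       motif_plant = c(CytP = "STAT5_like", AgS = "BZIP_like"),
                       motifs = default_motifs(),
                       peak_jitter_sd = 10,
                       peak_call_floor = 0.25,
                       baseline_sdlog = 0.25) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
              region_width_mean = region_width_mean,
              region_width_sd = region_width_sd,
              conditions = conditions, frac_diff = frac_diff,
              frac_opening = frac_opening, shared_frac = shared_frac,
              effect_log2fc = effect_log2fc, depth = depth,
              nb_dispersion = nb_dispersion, length_mixture = length_mixture,
              background_rate = background_rate, motif_plant = motif_plant,
              motifs = motifs, peak_jitter_sd = peak_jitter_sd,
              peak_call_floor = peak_call_floor, baseline_sdlog = baseline_sdlog)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$conditions) >= 2)
  extra <- setdiff(cfg$conditions[-1], names(cfg$frac_diff))
  if (length(extra) > 0) {
    abort(sprintf("frac_diff missing condition(s): %s", paste(extra, collapse = ", ")))
  }
  fr <- c(cfg$frac_diff, cfg$shared_frac, cfg$frac_opening)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (cfg$depth <= 0) abort("depth must be > 0")
  if (cfg$effect_log2fc < 0) abort("effect_log2fc must be >= 0")
  if (cfg$nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  w <- cfg$length_mixture$weights
  if (abs(sum(w) - 1) > 1e-9) abort("length_mixture weights must sum to 1")
  planted <- setdiff(unname(cfg$motif_plant), names(cfg$motifs))
  if (length(planted) > 0) {
    abort(sprintf("motif_plant names not in motifs: %s", paste(planted, collapse = ", ")))
  }
  invisible(cfg)
}

#' Built-in motif set used by the simulator
#'
#' Two strong planted motifs -- a STAT5-like palindromic GAS element
#' (TTCYNRGAA core) planted in cytokine-primed opening regions and a
#' bZIP/AP-1-like TRE element (TGACTCA core) planted in antigen-stimulated
#' opening regions -- plus a handful of unplanted decoys so enrichment ranks
#' are meaningful.
#'
#' @param consensus_prob Probability of the consensus base at each position.
#' @return Named list of [pwm()] objects.
#' @export
default_motifs <- function(consensus_prob = 0.85) {
  make <- function(name, consensus) {
    bases <- strsplit(consensus, "")[[1]]
    off <- (1 - consensus_prob) / 3
    probs <- vapply(bases, function(b) {
      p <- rep(off, 4); names(p) <- c("A", "C", "G", "T"); p[b] <- consensus_prob; p
    }, numeric(4))
    pwm(name = name, probs = probs)
  }
  list(
    STAT5_like = make("STAT5_like", "TTCCTAGGAA"),
    BZIP_like  = make("BZIP_like",  "ATGACTCATC"),
    CTCF_like  = make("CTCF_like",  "CCACCAGGGGGC"),
    RUNX_like  = make("RUNX_like",  "TGTGGTTT"),
    KLF_like   = make("KLF_like",   "GGGGCGGGG"),
    EBOX_like  = make("EBOX_like",  "CACCTGTC")
  )
}

#' Generate a toy genome, gene model and accessible regions
#'
#' Chromosome sequences are i.i.d. uniform A/C/G/T. Regions are
#' non-overlapping with at least 500 bp between neighbours; each gene's TSS
#' sits within 200 bp of the center of a distinct region. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector), `genes` (tibble:
#'   gene_id, chrom, tss, strand) and `regions` (tibble: region_id, chrom,
#'   start, end).
#' @export
generate_genome <- function(config) {
  withr::with_seed(config$seed, {
    genome <- setNames(
      vapply(seq_len(config$n_chroms), function(i) {
        paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
              collapse = "")
      }, character(1)),
      paste0("chr", seq_len(config$n_chroms))
    )
    regions <- place_regions(config)
    genes <- place_genes(config, regions)
  })
  list(genome = genome, genes = genes, regions = regions)
}

place_regions <- function(config) {
  n <- config$n_regions
  if (n == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  min_gap <- 500L
  out <- purrr::map2(seq_len(config$n_chroms), per_chrom, function(ci, k) {
    if (k == 0) return(NULL)
    for (attempt in 1:20) {
      widths <- pmax(100L, as.integer(round(rnorm(k, config$region_width_mean,
                                                  config$region_width_sd))))
      needed <- sum(widths) + (k + 1L) * min_gap
      if (needed > config$chrom_length) {
        if (attempt == 20) {
          abort("cannot place regions: increase chrom_length or reduce n_regions")
        }
        next
      }
      slack <- config$chrom_length - needed
      # random extra gap before each region; floor() keeps every gap >= min_gap
      extra <- floor(diff(c(0, sort(runif(k, 0, slack)))))
      starts <- min_gap + cumsum(c(0L, widths[-k] + min_gap)) +
        as.integer(cumsum(extra))
      return(tibble(chrom = paste0("chr", ci),
                    start = starts, end = starts + widths))
    }
  })
  out <- bind_rows(out)
  out <- mutate(out, region_id = sprintf("region_%04d", row_number())) |>
    select("region_id", "chrom", "start", "end")
  out
}

place_genes <- function(config, regions) {
  if (config$n_genes == 0 || nrow(regions) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  tss = integer(), strand = character()))
  }
  k <- min(config$n_genes, nrow(regions))
  host <- sort(sample(nrow(regions), k))
  center <- (regions$start[host] + regions$end[host]) %/% 2L
  tss <- pmax(0L, center + as.integer(round(runif(k, -200, 200))))
  tibble(gene_id = sprintf("gene_%04d", seq_len(k)),
         chrom = regions$chrom[host],
         tss = pmin(tss, config$chrom_length - 1L),
         strand = sample(c("+", "-"), k, replace = TRUE),
         host_region = regions$region_id[host])
}

# Plant true differential structure: which regions open/close in each
# non-reference condition, with the configured shared fractions between the
# first and second stimulated conditions (same direction when shared).
build_truth <- function(config, regions) {
  n <- nrow(regions)
  conds <- config$conditions
  ref <- conds[1]
  truth <- regions
  truth[[paste0("acc_", ref)]] <- if (n > 0) rlnorm(n, 0, config$baseline_sdlog) else numeric()
  stim <- conds[-1]
  sets <- list()
  for (cond in stim) {
    n_diff <- round(config$frac_diff[[cond]] * n)
    n_open <- round(config$frac_opening[[cond]] * n_diff)
    n_close <- n_diff - n_open
    sets[[cond]] <- list(n_open = n_open, n_close = n_close)
  }
  open_idx <- list(); close_idx <- list()
  if (length(stim) >= 1) {
    c1 <- stim[1]
    avail <- seq_len(n)
    open_idx[[c1]] <- sort(sample_from(avail, sets[[c1]]$n_open))
    avail <- setdiff(avail, open_idx[[c1]])
    close_idx[[c1]] <- sort(sample_from(avail, sets[[c1]]$n_close))
  }
  if (length(stim) >= 2) {
    c1 <- stim[1]; c2 <- stim[2]
    sh_open <- round(config$shared_frac[["opening"]] * length(open_idx[[c1]]))
    sh_close <- round(config$shared_frac[["closing"]] * length(close_idx[[c1]]))
    shared_open <- if (sh_open > 0) sort(sample_from(open_idx[[c1]], sh_open)) else integer()
    shared_close <- if (sh_close > 0) sort(sample_from(close_idx[[c1]], sh_close)) else integer()
    pool <- setdiff(seq_len(n), c(open_idx[[c1]], close_idx[[c1]]))
    extra_open <- max(0, sets[[c2]]$n_open - length(shared_open))
    extra_close <- max(0, sets[[c2]]$n_close - length(shared_close))
    if (extra_open + extra_close > length(pool)) {
      abort("frac_diff too large for n_regions: not enough non-differential regions to draw from")
    }
    eo <- if (extra_open > 0) sort(sample_from(pool, extra_open)) else integer()
    pool <- setdiff(pool, eo)
    ec <- if (extra_close > 0) sort(sample_from(pool, extra_close)) else integer()
    open_idx[[c2]] <- sort(c(shared_open, eo))
    close_idx[[c2]] <- sort(c(shared_close, ec))
    # any further conditions: independent draws (rarely used)
    for (cond in stim[-(1:2)]) {
      open_idx[[cond]] <- sort(sample(seq_len(n), sets[[cond]]$n_open))
      close_idx[[cond]] <- sort(sample(setdiff(seq_len(n), open_idx[[cond]]),
                                       sets[[cond]]$n_close))
    }
  }
  motif_col <- vector("list", n)
  for (cond in stim) {
    lfc <- numeric(n)
    lfc[open_idx[[cond]]] <- config$effect_log2fc
    lfc[close_idx[[cond]]] <- -config$effect_log2fc
    cls <- rep("unchanged", n)
    cls[open_idx[[cond]]] <- "opening"
    cls[close_idx[[cond]]] <- "closing"
    truth[[paste0("lfc_", cond)]] <- lfc
    truth[[paste0("class_", cond)]] <- cls
    truth[[paste0("acc_", cond)]] <- truth[[paste0("acc_", ref)]] * 2^lfc
    planted <- config$motif_plant[cond]
    if (!is.na(planted) && cond %in% names(config$motif_plant)) {
      for (i in open_idx[[cond]]) {
        motif_col[[i]] <- c(motif_col[[i]], unname(planted))
      }
    }
  }
  truth$motif <- vapply(motif_col, function(m) {
    if (is.null(m)) NA_character_ else paste(m, collapse = ",")
  }, character(1))
  truth
}

# Overwrite the genome with one consensus instance of the planted motif at
# the center of each motif-planted region, on a random strand.
plant_motifs <- function(genome, truth, motifs) {
  planted <- truth[!is.na(truth$motif), , drop = FALSE]
  if (nrow(planted) == 0) return(genome)
  for (i in seq_len(nrow(planted))) {
    for (mname in strsplit(planted$motif[i], ",", fixed = TRUE)[[1]]) {
      cons <- motifs[[mname]]$consensus
      if (runif(1) < 0.5) cons <- revcomp_string(cons)
      len <- nchar(cons)
      center <- (planted$start[i] + planted$end[i]) %/% 2L
      at <- center - len %/% 2L  # 0-based insertion offset
      chrom <- planted$chrom[i]
      substr(genome[[chrom]], at + 1L, at + len) <- cons
    }
  }
  genome
}

revcomp_string <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Draw fragment lengths from the nucleosome-periodic mixture
#'
#' Three-component Gaussian mixture (nucleosome-free, mono-, di-nucleosome)
#' truncated to 20-800 bp by rejection.
#'
#' @param n Number of lengths to draw.
#' @param mixture List with `weights`, `means`, `sds`.
#' @return Integer vector of lengths.
#' @export
sample_fragment_lengths <- function(n, mixture) {
  if (n == 0) return(integer())
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  len <- round(rnorm(n, mixture$means[comp], mixture$sds[comp]))
  bad <- which(len < 20 | len > 800)
  while (length(bad) > 0) {
    comp2 <- sample.int(length(mixture$weights), length(bad), replace = TRUE,
                        prob = mixture$weights)
    len[bad] <- round(rnorm(length(bad), mixture$means[comp2], mixture$sds[comp2]))
    bad <- bad[len[bad] < 20 | len[bad] > 800]
  }
  as.integer(len)
}

#' Generate per-condition fragment files from the truth table
#'
#' Per region and condition, the fragment count is negative binomial with
#' mean `depth * acc / sum(acc)` and dispersion `nb_dispersion`; fragment
#' midpoints are uniform within the region and lengths follow the
#' nucleosome-periodic mixture. Background fragments are placed uniformly
#' over the genome at `background_rate` per bp.
#'
#' @param config A [sim_config()].
#' @param genome Named character vector of chromosome sequences (used for
#'   chromosome lengths).
#' @param regions Region tibble from [generate_genome()].
#' @param truth Truth table consistent with `regions`.
#' @return Named list (one per condition) of fragment tibbles
#'   (`chrom`, `start`, `end`), sorted by coordinate.
#' @export
generate_fragments <- function(config, genome, regions, truth) {
  if (!identical(regions$region_id, truth$region_id)) {
    abort("truth table is not consistent with regions (region_id mismatch)")
  }
  chrom_len <- nchar(genome)
  out <- withr::with_seed(config$seed + 1L, {
    lapply(setNames(config$conditions, config$conditions), function(cond) {
      acc <- truth[[paste0("acc_", cond)]]
      frags <- NULL
      if (nrow(regions) > 0) {
        mu <- config$depth * acc / sum(acc)
        cnt <- if (config$nb_dispersion > 0) {
          rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
        } else {
          rpois(length(mu), mu)
        }
        ridx <- rep(seq_len(nrow(regions)), cnt)
        mid <- as.integer(floor(runif(length(ridx), regions$start[ridx],
                                      regions$end[ridx])))
        len <- sample_fragment_lengths(length(ridx), config$length_mixture)
        frags <- tibble(chrom = regions$chrom[ridx],
                        start = mid - len %/% 2L, len = len)
      }
      n_bg <- rpois(1, config$background_rate * sum(chrom_len))
      if (n_bg > 0) {
        bchrom <- sample(names(chrom_len), n_bg, replace = TRUE,
                         prob = chrom_len / sum(chrom_len))
        blen <- sample_fragment_lengths(n_bg, config$length_mixture)
        bmid <- as.integer(floor(runif(n_bg, 0, chrom_len[bchrom])))
        frags <- bind_rows(frags, tibble(chrom = bchrom,
                                         start = bmid - blen %/% 2L, len = blen))
      }
      if (is.null(frags) || nrow(frags) == 0) {
        return(tibble(chrom = character(), start = integer(), end = integer()))
      }
      # keep length fixed; shift fragments that stick out past an end
      maxlen <- unname(chrom_len[frags$chrom])
      frags$start <- pmax(0L, pmin(frags$start, maxlen - frags$len))
      tibble(chrom = frags$chrom, start = as.integer(frags$start),
             end = as.integer(frags$start + frags$len)) |>
        arrange(.data$chrom, .data$start, .data$end)
    })
  })
  out
}

#' Emit per-condition peak calls from the truth table
#'
#' Every region whose true accessibility in a condition exceeds
#' `peak_call_floor` is emitted with boundaries jittered by
#' N(0, `peak_jitter_sd`), resampling any jitter that would produce an empty
#' interval. Generation asserts that at least 99% of same-region call pairs
#' across conditions still satisfy the >= 75% reciprocal-overlap merge rule.
#'
#' @param regions Region tibble from [generate_genome()].
#' @param truth Truth table consistent with `regions`.
#' @param config A [sim_config()].
#' @return Named list (one per condition) of peak-call tibbles
#'   (`chrom`, `start`, `end`, `name` = source region id, `score` = true
#'   accessibility, `strand` = ".").
#' @export
emit_peak_calls <- function(regions, truth, config) {
  if (!identical(regions$region_id, truth$region_id)) {
    abort("truth table is not consistent with regions (region_id mismatch)")
  }
  calls <- withr::with_seed(config$seed + 2L, {
    lapply(setNames(config$conditions, config$conditions), function(cond) {
      acc <- truth[[paste0("acc_", cond)]]
      keep <- which(acc >= config$peak_call_floor)
      if (length(keep) == 0) {
        return(tibble(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
      }
      s <- regions$start[keep]; e <- regions$end[keep]
      js <- as.integer(s + round(rnorm(length(keep), 0, config$peak_jitter_sd)))
      je <- as.integer(e + round(rnorm(length(keep), 0, config$peak_jitter_sd)))
      bad <- which(je <= js | js < 0)
      while (length(bad) > 0) {
        js[bad] <- as.integer(s[bad] + round(rnorm(length(bad), 0, config$peak_jitter_sd)))
        je[bad] <- as.integer(e[bad] + round(rnorm(length(bad), 0, config$peak_jitter_sd)))
        bad <- bad[je[bad] <= js[bad] | js[bad] < 0]
      }
      tibble(chrom = regions$chrom[keep], start = js, end = je,
             name = regions$region_id[keep], score = acc[keep], strand = ".")
    })
  })
  assert_call_coherence(calls, config)
  calls
}

# Check that same-region calls across conditions retain >75% reciprocal
# overlap with empirical probability >= 0.99.
assert_call_coherence <- function(calls, config, min_frac = 0.75) {
  all_calls <- bind_rows(calls)
  if (nrow(all_calls) == 0) return(invisible(TRUE))
  ok <- all_calls |>
    group_by(.data$name) |>
    summarise(ok = {
      if (n() < 2) TRUE else {
        pairs <- utils::combn(n(), 2)
        ov <- pmin(.data$end[pairs[1, ]], .data$end[pairs[2, ]]) -
          pmax(.data$start[pairs[1, ]], .data$start[pairs[2, ]])
        la <- .data$end[pairs[1, ]] - .data$start[pairs[1, ]]
        lb <- .data$end[pairs[2, ]] - .data$start[pairs[2, ]]
        all(ov >= min_frac * la & ov >= min_frac * lb)
      }
    }, .groups = "drop")
  frac_ok <- mean(ok$ok)
  if (frac_ok < 0.99) {
    abort(sprintf(
      "peak_jitter_sd too large: only %.1f%% of same-region call groups retain >=75%% reciprocal overlap",
      100 * frac_ok))
  }
  invisible(TRUE)
}

#' Simulate a complete three-condition ATAC experiment
#'
#' Orchestrates [generate_genome()], truth-table construction, motif
#' planting, [generate_fragments()] and [emit_peak_calls()]. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An `atac_sim` object: list with `config`, `genome`, `genes`,
#'   `regions`, `truth`, `fragments` (named list of tibbles) and
#'   `peak_calls` (named list of tibbles).
#' @export
simulate_atac <- function(config = sim_config()) {
  g <- generate_genome(config)
  truth <- withr::with_seed(config$seed + 3L, build_truth(config, g$regions))
  genome <- withr::with_seed(config$seed + 4L,
                             plant_motifs(g$genome, truth, config$motifs))
  fragments <- generate_fragments(config, genome, g$regions, truth)
  peak_calls <- emit_peak_calls(g$regions, truth, config)
  structure(list(config = config, genome = genome, genes = g$genes,
                 regions = g$regions, truth = truth,
                 fragments = fragments, peak_calls = peak_calls),
            class = "atac_sim")
}

#' @export
print.atac_sim <- function(x, ...) {
  cat(sprintf("<atac_sim> %d chrom(s) x %s bp, %d regions, %d genes, conditions: %s\n",
              x$config$n_chroms, fmt_int(x$config$chrom_length),
              nrow(x$regions), nrow(x$genes),
              paste(x$config$conditions, collapse = ", ")))
  frs <- vapply(x$fragments, nrow, integer(1))
  cat("  fragments:", paste(sprintf("%s=%d", names(frs), frs), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `genes.bed` (BED6, 1-bp gene records anchored at the
#' TSS), per-condition `<cond>.fragments.bed` (BED3) and `<cond>.peaks.bed`
#' (BED6), `truth.tsv` and `config.json`.
#'
#' @param sim An `atac_sim` object.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             genes = file.path(outdir, "genes.bed"),
             truth = file.path(outdir, "truth.tsv"),
             config = file.path(outdir, "config.json"))
  write_fasta(sim$genome, paths[["genome"]])
  genes_bed <- tibble(chrom = sim$genes$chrom, start = sim$genes$tss,
                      end = sim$genes$tss + 1L, name = sim$genes$gene_id,
                      score = 0, strand = sim$genes$strand)
  write_bed(genes_bed, paths[["genes"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  cfg <- sim$config
  cfg$motifs <- lapply(cfg$motifs, function(p) p$consensus)
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (cond in sim$config$conditions) {
    fp <- file.path(outdir, paste0(cond, ".fragments.bed"))
    pp <- file.path(outdir, paste0(cond, ".peaks.bed"))
    write_bed(sim$fragments[[cond]], fp)
    write_bed(sim$peak_calls[[cond]], pp)
    paths[paste0("fragments_", cond)] <- fp
    paths[paste0("peaks_", cond)] <- pp
  }
  invisible(paths)
}

#' Build synthetic gene sets from a simulation's truth table
#'
#' One term per stimulated condition and direction (genes whose host region
#' opens/closes in that condition) plus random decoy terms, for exercising
#' gene-set overrepresentation on data with known structure.
#'
#' @param sim An `atac_sim` object.
#' @param n_random_terms Number of random decoy terms.
#' @param random_term_size Genes per decoy term.
#' @return A tibble as returned by [read_gmt()].
#' @export
make_gene_sets <- function(sim, n_random_terms = 20, random_term_size = 25) {
  genes <- sim$genes
  truth <- sim$truth
  sets <- list()
  for (cond in sim$config$conditions[-1]) {
    cls <- truth[[paste0("class_", cond)]]
    for (direction in c("opening", "closing")) {
      rid <- truth$region_id[cls == direction]
      gs <- genes$gene_id[genes$host_region %in% rid]
      if (length(gs) >= 1) {
        sets[[length(sets) + 1]] <- tibble(
          term_id = sprintf("SET_%s_%s", toupper(cond), toupper(direction)),
          description = sprintf("genes at regions %s in %s", direction, cond),
          genes = list(gs))
      }
    }
  }
  decoys <- withr::with_seed(sim$config$seed + 5L, {
    purrr::map(seq_len(n_random_terms), function(i) {
      tibble(term_id = sprintf("SET_RANDOM_%02d", i),
             description = "random decoy term",
             genes = list(sample(genes$gene_id,
                                 min(random_term_size, nrow(genes)))))
    })
  })
  bind_rows(c(sets, decoys))
}
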