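#' Read a BED file of genomic intervals
#'
#' Reads BED3 or BED6 into a tibble of 0-based half-open intervals. Records
#' are validated strictly: a malformed line (too few columns, non-numeric
#' coordinates, `end <= start`, negative `start`, empty chromosome) is an
#' error naming the offending line, never silently repaired.
#'
#' @param path Path to a tab-separated BED file.
#' @param expected_columns Either 3 or 6. Lines may carry more columns than
#'   requested; extras are ignored.
#' @return A tibble with columns `chrom`, `start`, `end` and, for BED6,
#'   `name`, `score`, `strand` (strand is one of `"+"`, `"-"`, `"."`).
#'   File order is preserved.
#' @export
read_bed <- function(path, expected_columns = 3) {
  expected_columns <- as.integer(expected_columns)
  if (!expected_columns %in% c(3L, 6L)) {
    abort("`expected_columns` must be 3 or 6")
  }
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    if (expected_columns == 6L) {
      out$name <- character(); out$score <- numeric(); out$strand <- character()
    }
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < expected_columns)) {
    bad <- which(nf < expected_columns)[1]
    abort(sprintf("malformed BED line %d in %s: %d column(s), expected >= %d",
                  lineno[bad], path, nf[bad], expected_columns))
  }
  col <- function(k) vapply(fields, `[[`, character(1), k)
  start <- suppressWarnings(as.numeric(col(2)))
  end <- suppressWarnings(as.numeric(col(3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinate",
                  lineno[bad], path))
  }
  out <- tibble(chrom = col(1), start = as.integer(start), end = as.integer(end))
  validate_intervals(out, what = "BED record", lines = lineno)
  if (expected_columns == 6L) {
    strand <- col(6)
    bad <- which(!strand %in% c("+", "-", "."))
    if (length(bad) > 0) {
      abort(sprintf("malformed BED line %d in %s: strand must be +, - or .",
                    lineno[bad[1]], path))
    }
    out$name <- col(4)
    out$score <- suppressWarnings(as.numeric(col(5)))
    out$strand <- strand
  }
  out
}

#' Write intervals to a BED file
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(x, path))` reproduces `x`.
#' Writes BED3 or BED6 depending on the presence of `name`/`score`/`strand`
#' columns.
#'
#' @param x A tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, fmt_int(x$start), fmt_int(x$end))
  if (all(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, list(x$name, format(x$score, scientific = FALSE, trim = TRUE),
                         x$strand))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (nrow(x) == 0) lines <- character()
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTA file into a named vector of sequences
#'
#' Sequences are upper-cased and validated to contain only A, C, G, T, N.
#' The chromosome name is the header token before the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @param mask_invalid If `FALSE` (default) any letter outside A/C/G/T/N is
#'   an error; if `TRUE` such letters are replaced by `N`.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path, mask_invalid = FALSE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  seqs <- tryCatch(
    as.character(Biostrings::readBStringSet(path, format = "fasta")),
    error = function(e) abort(sprintf("failed to parse FASTA %s: %s",
                                      path, conditionMessage(e)))
  )
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA record name(s): %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  names(seqs) <- nm
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (mask_invalid) {
      seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
    } else {
      abort(sprintf("record %s contains letters outside A/C/G/T/N (set mask_invalid = TRUE to N-mask)",
                    nm[which(bad)[1]]))
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

#' Read position frequency matrices (JASPAR or HOMER dialect)
#'
#' JASPAR files carry count matrices as four base rows (A, C, G, T) per
#' record; HOMER `.motif` files carry a header `>consensus name threshold`
#' followed by one probability row per motif position. Counts (or
#' probabilities) are converted to per-column probabilities after adding
#' `pseudocount` to every cell, so all probabilities are strictly positive.
#'
#' @param path Path to the motif file.
#' @param dialect `"jaspar"` or `"homer"`.
#' @param pseudocount Mass added per cell before column renormalization
#'   (default 0.001).
#' @return A named list of `pwm` objects (see [pwm()]).
#' @export
read_pfm <- function(path, dialect = c("jaspar", "homer"), pseudocount = 0.001) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort(sprintf("no motif records (no '>' header) in %s", path))
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    body <- lines[(s + 1L):e]
    if (dialect == "jaspar") parse_jaspar_record(header, body, pseudocount, path)
    else parse_homer_record(header, body, pseudocount, path)
  })
  names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  pwms
}

parse_numeric_row <- function(line, path) {
  # strip base labels and JASPAR-style brackets: "A [ 8 0 1 ]"
  cleaned <- gsub("^[ \t]*[ACGTacgt][ \t:|]*", "", line)
  cleaned <- gsub("[][]", " ", cleaned)
  toks <- strsplit(trimws(cleaned), "[ \t]+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0 || anyNA(vals)) {
    abort(sprintf("non-numeric motif matrix cell in %s: '%s'", path, line))
  }
  vals
}

parse_jaspar_record <- function(header, body, pseudocount, path) {
  if (length(body) < 4) abort(sprintf("JASPAR record '%s' has fewer than 4 matrix rows", header))
  rows <- lapply(body[1:4], parse_numeric_row, path = path)
  if (length(unique(lengths(rows))) != 1) {
    abort(sprintf("ragged matrix rows in JASPAR record '%s'", header))
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  # honor explicit base labels if present
  labels <- toupper(sub("^[ \t]*([ACGTacgt]).*$", "\\1", body[1:4]))
  if (all(labels %in% c("A", "C", "G", "T")) && !anyDuplicated(labels)) {
    rownames(counts) <- labels
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  }
  pwm(name = trimws(header), probs = normalize_pfm(counts, pseudocount, header),
      pseudocount = pseudocount)
}

parse_homer_record <- function(header, body, pseudocount, path) {
  toks <- strsplit(trimws(header), "[ \t]+")[[1]]
  consensus <- toks[1]
  name <- if (length(toks) >= 2) toks[2] else toks[1]
  threshold <- if (length(toks) >= 3) suppressWarnings(as.numeric(toks[3])) else NA_real_
  rows <- lapply(body, parse_numeric_row, path = path)
  if (any(lengths(rows) != 4)) {
    abort(sprintf("HOMER record '%s' has a position row without 4 values", name))
  }
  probs <- t(do.call(rbind, rows))   # 4 x L, rows A,C,G,T
  rownames(probs) <- c("A", "C", "G", "T")
  pwm(name = name, probs = normalize_pfm(probs, pseudocount, name),
      pseudocount = pseudocount, consensus = consensus, threshold = threshold)
}

normalize_pfm <- function(mat, pseudocount, name) {
  sums <- colSums(mat)
  if (any(sums <= 0)) {
    abort(sprintf("motif '%s' has a column summing to 0", name))
  }
  mat <- mat + pseudocount
  sweep(mat, 2, colSums(mat), "/")
}

#' Construct a position weight matrix object
#'
#' @param name Motif name.
#' @param probs 4 x L numeric matrix of base probabilities, rows in A, C, G,
#'   T order; every column must sum to 1 (within 1e-9) and all entries must
#'   be positive.
#' @param pseudocount Pseudocount used when the matrix was built (metadata).
#' @param consensus Optional consensus string (HOMER dialect).
#' @param threshold Optional file-supplied log-odds threshold (HOMER dialect).
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, pseudocount = 0.001, consensus = NULL,
                threshold = NA_real_) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == 4, ncol(probs) >= 1)
  rownames(probs) <- c("A", "C", "G", "T")
  if (any(probs <= 0)) abort(sprintf("motif '%s': all probabilities must be > 0", name))
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    abort(sprintf("motif '%s': columns must sum to 1", name))
  }
  structure(list(name = name, probs = probs, pseudocount = pseudocount,
                 consensus = consensus %||% consensus_sequence(probs),
                 threshold = threshold),
            class = "pwm")
}

consensus_sequence <- function(probs) {
  paste(rownames(probs)[apply(probs, 2, which.max)], collapse = "")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  (%d bp, consensus %s)\n", x$name, ncol(x$probs), x$consensus))
  print(round(x$probs, 3))
  invisible(x)
}

#' Write position weight matrices (JASPAR-style probability matrices)
#'
#' Writes probabilities (not counts); reading the file back with
#' `read_pfm(..., pseudocount = 0)` reproduces the matrices.
#'
#' @param pwms A list of `pwm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$name),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste(b, "[", paste(sprintf("%.12g", p$probs[b, ]), collapse = " "), "]")
      }, character(1)))
  }), use.names = FALSE)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a gene model with strand-aware TSS positions
#'
#' Accepts BED6 (where `start` is the TSS of a `+` strand gene and `end - 1`
#' the TSS of a `-` strand gene) or a minimal GTF restricted to `gene`
#' features (1-based closed coordinates, converted to the internal 0-based
#' frame on read).
#'
#' @param path Path to the gene model.
#' @param format `"auto"` (by file extension), `"bed6"` or `"gtf"`.
#' @return A tibble with `gene_id`, `chrom`, `tss` (0-based position) and
#'   `strand` (`"+"` or `"-"`).
#' @export
read_gene_model <- function(path, format = c("auto", "bed6", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff)$", path, ignore.case = TRUE)) "gtf" else "bed6"
  }
  if (format == "bed6") {
    bed <- read_bed(path, expected_columns = 6)
    if (any(bed$strand == ".")) {
      abort("gene model requires an explicit strand (+ or -) for every gene")
    }
    tibble(gene_id = bed$name, chrom = bed$chrom,
           tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
           strand = bed$strand)
  } else {
    lines <- readr::read_lines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 9)) {
      abort(sprintf("malformed GTF line %d: fewer than 9 columns",
                    which(lengths(fields) < 9)[1]))
    }
    feat <- vapply(fields, `[[`, character(1), 3)
    genes <- fields[feat == "gene"]
    if (length(genes) == 0) abort("no 'gene' features in GTF")
    chrom <- vapply(genes, `[[`, character(1), 1)
    start1 <- as.integer(vapply(genes, `[[`, character(1), 4))
    end1 <- as.integer(vapply(genes, `[[`, character(1), 5))
    strand <- vapply(genes, `[[`, character(1), 7)
    if (any(!strand %in% c("+", "-"))) {
      abort("gene model requires an explicit strand (+ or -) for every gene")
    }
    attrs <- vapply(genes, `[[`, character(1), 9)
    m <- regmatches(attrs, regexec('gene_id[ ="]+([^";]+)', attrs))
    gene_id <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                      character(1))
    if (anyNA(gene_id)) abort("GTF gene feature without gene_id attribute")
    # GTF is 1-based closed; internal frame is 0-based half-open.
    tibble(gene_id = gene_id, chrom = chrom,
           tss = ifelse(strand == "+", start1 - 1L, end1 - 1L),
           strand = strand)
  }
}

#' Read a GMT-like gene-set file
#'
#' Each line is `term_id TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param path Path to the file.
#' @return A tibble with `term_id`, `description` and a list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort(sprintf("malformed gene-set line %d: need term, description and >= 1 gene",
                  which(lengths(fields) < 3)[1]))
  }
  tibble(
    term_id = vapply(fields, `[[`, character(1), 1),
    description = vapply(fields, `[[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write a GMT-like gene-set file
#'
#' @param sets A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(sets, function(term_id, description, genes, ...) {
    paste(c(term_id, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}
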