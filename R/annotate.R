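#' Annotate atlas peaks with their nearest gene
#'
#' The peak position is its integer center `floor((start + end) / 2)`; the
#' nearest gene minimizes the absolute center-to-TSS distance on the same
#' chromosome, with ties broken by the lexicographically smaller gene id.
#' The signed distance is negative when the peak center lies 5' (upstream)
#' of the TSS in the gene's orientation: for `+` strand genes it is
#' `center - tss`, for `-` strand genes `tss - center`. Peaks on
#' chromosomes without genes get gene id `"none"` and distance `NA`.
#'
#' @param atlas Atlas tibble (needs `peak_id`, `chrom`, `start`, `end`).
#' @param genes Gene model tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @return Tibble with `peak_id`, `gene_id`, `distance`.
#' @export
annotate_nearest <- function(atlas, genes) {
  if (nrow(genes) == 0) abort("empty gene model")
  center <- (atlas$start + atlas$end) %/% 2L
  by_chrom <- split(seq_len(nrow(genes)), genes$chrom)
  res <- purrr::map(seq_len(nrow(atlas)), function(i) {
    gi <- by_chrom[[atlas$chrom[i]]]
    if (is.null(gi)) {
      return(list(gene_id = "none", distance = NA_real_))
    }
    d_abs <- abs(center[i] - genes$tss[gi])
    cand <- gi[d_abs == min(d_abs)]
    g <- cand[order(genes$gene_id[cand])][1]
    signed <- if (genes$strand[g] == "+") center[i] - genes$tss[g]
              else genes$tss[g] - center[i]
    list(gene_id = genes$gene_id[g], distance = as.numeric(signed))
  })
  tibble(peak_id = atlas$peak_id,
         gene_id = vapply(res, `[[`, character(1), "gene_id"),
         distance = vapply(res, `[[`, numeric(1), "distance"))
}

#' Gene-set overrepresentation by the hypergeometric upper tail
#'
#' For each term with at least one observed gene, the p-value is
#' `P(X >= observed)` for a hypergeometric draw of `|query|` genes from a
#' universe in which `background` genes carry the term; p-values are adjusted
#' across all tested terms by Benjamini-Hochberg and rows are sorted by FDR
#' then p.
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe Character vector: the background gene universe.
#' @param sets Gene sets: a tibble as from [read_gmt()] (`term_id`,
#'   `description`, list-column `genes`) or a named list of gene vectors.
#' @return Tibble with `term_id`, `description`, `observed`, `background`,
#'   `p_value`, `fdr`.
#' @export
geneset_enrichment <- function(query, universe, sets) {
  universe <- unique(universe)
  query <- unique(query)
  missing <- setdiff(query, universe)
  if (length(missing) > 0) {
    abort(sprintf("query gene(s) absent from universe: %s",
                  paste(head(missing, 10), collapse = ", ")))
  }
  if (!is.data.frame(sets)) {
    sets <- tibble(term_id = names(sets), description = "",
                   genes = unname(sets))
  }
  rows <- purrr::pmap(sets, function(term_id, description, genes, ...) {
    gs <- intersect(unique(genes), universe)
    obs <- length(intersect(query, gs))
    if (obs < 1) return(NULL)
    p <- phyper(obs - 1, length(gs), length(universe) - length(gs),
                length(query), lower.tail = FALSE)
    tibble(term_id = term_id, description = description,
           observed = obs, background = length(gs), p_value = p)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(term_id = character(), description = character(),
                  observed = integer(), background = integer(),
                  p_value = numeric(), fdr = numeric()))
  }
  out$fdr <- p.adjust(out$p_value, method = "BH")
  arrange(out, .data$fdr, .data$p_value)
}
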