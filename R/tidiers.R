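# broom-style tidiers for the package's result objects.

#' @export
tidy.length_histogram <- function(x, ...) x$hist

#' @export
glance.length_histogram <- function(x, ...) {
  tibble(n_fragments = x$n_fragments, overflow = x$overflow,
         n_modes = nrow(x$modes),
         mono_mode = if ("mono-nucleosome" %in% x$modes$band)
           x$modes$length[x$modes$band == "mono-nucleosome"] else NA_integer_)
}

#' @export
tidy.tss_profile <- function(x, ...) x$profile

#' @export
glance.tss_profile <- function(x, ...) {
  tibble(n_genes = x$n_genes, enrichment_score = x$enrichment_score)
}

#' @export
tidy.dispersion_fit <- function(x, ...) x$table

#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble(a0 = x$a0, a1 = x$a1, n_peaks = nrow(x$table),
         median_alpha = median(x$table$alpha_mom))
}

#' Long-format rlog values
#'
#' @param x An `atac_rlog` object.
#' @param ... Unused.
#' @return Tibble with `peak_id`, `sample`, `rlog`.
#' @export
tidy.atac_rlog <- function(x, ...) {
  tidyr::pivot_longer(x$values, -"peak_id", names_to = "sample",
                      values_to = "rlog")
}

#' @export
glance.atac_rlog <- function(x, ...) {
  tibble(n_peaks = nrow(x$values), n_samples = length(x$samples),
         sigma_sq_prior = x$sigma_sq,
         dispersion_a0 = x$dispersion$a0, dispersion_a1 = x$dispersion$a1)
}

#' @export
tidy.atac_pca <- function(x, ...) x$coords

#' @export
glance.atac_pca <- function(x, ...) {
  tibble(n_peaks = x$n_peaks,
         pc1_var = x$variance_explained[1],
         pc2_var = if (length(x$variance_explained) >= 2)
           x$variance_explained[2] else NA_real_)
}
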