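counts_to_matrix <- function(counts) {
  stopifnot("peak_id" %in% names(counts))
  m <- as.matrix(as.data.frame(counts[setdiff(names(counts), "peak_id")]))
  rownames(m) <- counts$peak_id
  storage.mode(m) <- "double"
  m
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over peaks with positive
#' counts in every sample of the ratio between the sample's count and the
#' peak's geometric mean across samples; factors are then rescaled to have
#' geometric mean 1. This equalizes depth and composition between libraries
#' before any log transform.
#'
#' @param counts Count tibble from [count_matrix()] (`peak_id` + one numeric
#'   column per sample).
#' @param fallback If `"error"` (default), fail when no peak has positive
#'   counts in all samples; `"poscounts"` instead takes geometric means over
#'   the positive entries of every peak (pseudo-reference fallback for very
#'   sparse data).
#' @return Tibble with `sample`, `size_factor`; the factors' geometric mean
#'   is 1.
#' @export
size_factors <- function(counts, fallback = c("error", "poscounts")) {
  fallback <- match.arg(fallback)
  m <- counts_to_matrix(counts)
  if (ncol(m) < 1) abort("no sample columns")
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos) && fallback == "error") {
    abort(paste("no peak has positive counts in every sample;",
                "simulate/sequence deeper or use fallback = 'poscounts'"))
  }
  if (any(allpos)) {
    sub <- m[allpos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    s <- apply(sub / geo, 2, median)
  } else {
    lg <- log(m); lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    use <- is.finite(geo) & geo > 0
    s <- apply(m[use, , drop = FALSE] / geo[use], 2, function(r) median(r[r > 0]))
  }
  if (any(!is.finite(s) | s <= 0)) abort("degenerate size factors; counts too sparse")
  s <- s / exp(mean(log(s)))
  tibble(sample = colnames(m), size_factor = unname(s))
}

#' Method-of-moments dispersion with a 1/mean trend
#'
#' Per peak, counts are normalized by the size factors, and the
#' method-of-moments negative-binomial dispersion is
#' `alpha = max(0, (var - mean) / mean^2)` across samples. A trend
#' `alpha(mu) = a0 + a1 / mu` is fitted by least squares to the peaks with
#' positive `alpha`, with `a0` floored at 0.01; the trended dispersion is
#' what the regularized log transform consumes. With no replication the
#' estimate is blind to condition structure: true signal inflates it, which
#' only makes the transform shrink more (a documented, conservative bias).
#'
#' @param counts Count tibble.
#' @param sf Size-factor tibble from [size_factors()]; computed if `NULL`.
#' @return A `dispersion_fit` object: list with `table` (tibble: `peak_id`,
#'   `base_mean`, `alpha_mom`, `alpha_trend`) and coefficients `a0`, `a1`.
#' @export
fit_dispersion <- function(counts, sf = NULL) {
  m <- counts_to_matrix(counts)
  if (ncol(m) < 2) abort("dispersion needs at least 2 samples")
  if (nrow(m) < 10) warn("fewer than 10 peaks: dispersion trend will be unstable")
  sf <- sf %||% size_factors(counts)
  nmat <- sweep(m, 2, sf$size_factor[match(colnames(m), sf$sample)], "/")
  mu <- unname(rowMeans(nmat))
  v <- unname(apply(nmat, 1, var))
  alpha <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  use <- alpha > 0 & mu > 0
  if (sum(use) >= 2) {
    fit <- lm(alpha[use] ~ I(1 / mu[use]))
    a0 <- max(unname(coef(fit)[1]), 0.01)
    a1 <- unname(coef(fit)[2])
  } else {
    a0 <- max(median(alpha), 0.01)
    a1 <- 0
  }
  trend <- pmax(a0 + ifelse(mu > 0, a1 / mu, 0), 1e-8)
  structure(list(table = tibble(peak_id = rownames(m), base_mean = mu,
                                alpha_mom = alpha, alpha_trend = trend),
                 a0 = a0, a1 = a1),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("<dispersion_fit> %d peaks; trend alpha(mu) = %.4g + %.4g/mu\n",
              nrow(x$table), x$a0, x$a1))
  invisible(x)
}

#' Regularized log transform of accessibility counts
#'
#' A variance-stabilizing, empirical-Bayes shrunken log2 transform.
#' Normalized counts `n = K / s` receive a 0.5 pseudocount; per peak the row
#' mean of `log2(n + 0.5)` is `mu` and the per-entry deviation is `beta`.
#' Each deviation carries a delta-method sampling variance
#' `w = (1/ln 2)^2 (1/(n + 0.5) + alpha)` (Poisson plus overdispersion on the
#' log2 scale) and is shrunk toward zero by `c = sigma2 / (sigma2 + w)`,
#' where the prior variance `sigma2` is quantile-matched to the observed
#' deviations as `(q95(|beta|) / 1.645)^2` (floored at 1e-6):
#' `rlog = mu + c * beta`. Low counts (large `w`) are therefore pulled toward
#' the row mean, so fold changes between samples cannot be driven by a
#' handful of fragments.
#'
#' @param counts Count tibble from [count_matrix()].
#' @param sf Size factors ([size_factors()]); computed if `NULL`.
#' @param dispersion A [fit_dispersion()] result; computed if `NULL`.
#' @param sigma_sq Optional prior-variance override. `Inf` disables
#'   shrinkage, recovering plain `log2(n + 0.5)`.
#' @return An `atac_rlog` object: list with `values` (tibble: `peak_id` + one
#'   rlog column per sample), `mu`, `shrinkage` (same shape as `values`),
#'   `sigma_sq`, `samples`, plus the inputs used.
#' @export
rlog_transform <- function(counts, sf = NULL, dispersion = NULL,
                           sigma_sq = NULL) {
  m <- counts_to_matrix(counts)
  sf <- sf %||% size_factors(counts)
  dispersion <- dispersion %||% fit_dispersion(counts, sf)
  nmat <- sweep(m, 2, sf$size_factor[match(colnames(m), sf$sample)], "/")
  lmat <- log2(nmat + 0.5)
  mu <- unname(rowMeans(lmat))
  beta <- lmat - mu
  alpha <- dispersion$table$alpha_trend[match(rownames(m), dispersion$table$peak_id)]
  w <- (1 / log(2))^2 * (1 / (nmat + 0.5) + alpha)
  if (is.null(sigma_sq)) {
    sigma_sq <- max((quantile(abs(beta[is.finite(beta)]), 0.95) / 1.645)^2, 1e-6)
  }
  cmat <- if (is.infinite(sigma_sq)) {
    matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    sigma_sq / (sigma_sq + w)
  }
  rl <- mu + cmat * beta
  structure(list(
    values = bind_cols(tibble(peak_id = rownames(m)), as_tibble(rl)),
    shrinkage = bind_cols(tibble(peak_id = rownames(m)), as_tibble(cmat)),
    mu = tibble(peak_id = rownames(m), mu = mu),
    sigma_sq = unname(sigma_sq),
    samples = colnames(m),
    size_factors = sf,
    dispersion = dispersion
  ), class = "atac_rlog")
}

#' @export
print.atac_rlog <- function(x, ...) {
  cat(sprintf("<atac_rlog> %d peaks x %d samples, prior variance %.4g\n",
              nrow(x$values), length(x$samples), x$sigma_sq))
  invisible(x)
}

#' Classify peaks as opening, closing or unchanged
#'
#' For an ordered condition pair (A, B) the rlog fold change is
#' `rlog[, B] - rlog[, A]`; a peak is `opening` when the fold change is at
#' least the threshold, `closing` when at most minus the threshold
#' (boundaries inclusive) and `unchanged` otherwise. The default threshold
#' log2(1.5) ~ 0.585 flags peaks whose regularized accessibility changes by
#' at least 1.5-fold.
#'
#' @param rlog An [rlog_transform()] result.
#' @param pair Character vector `c(A, B)` of sample labels; fold changes are
#'   B relative to A (the reference first).
#' @param threshold Fold-change threshold on the rlog scale (default
#'   `log2(1.5)`).
#' @return An `atac_classes` tibble: `peak_id`, `base_mean` (mean rlog of the
#'   pair), `rlog_fc`, `class` (factor: opening/closing/unchanged), with
#'   attributes `pair` and `threshold`.
#' @export
classify_peaks <- function(rlog, pair, threshold = log2(1.5)) {
  if (length(pair) != 2) abort("pair must be c(reference, condition)")
  missing <- setdiff(pair, rlog$samples)
  if (length(missing) > 0) {
    abort(sprintf("unknown condition label(s): %s", paste(missing, collapse = ", ")))
  }
  a <- rlog$values[[pair[1]]]
  b <- rlog$values[[pair[2]]]
  fc <- b - a
  cls <- factor(ifelse(fc >= threshold, "opening",
                       ifelse(fc <= -threshold, "closing", "unchanged")),
                levels = c("opening", "closing", "unchanged"))
  out <- tibble(peak_id = rlog$values$peak_id, base_mean = (a + b) / 2,
                rlog_fc = fc, class = cls)
  structure(out, class = c("atac_classes", class(out)),
            pair = pair, threshold = threshold)
}

#' Principal component analysis of samples
#'
#' Selects the `top_n` peaks with the largest rlog row variance, centers each
#' peak across samples and decomposes the samples x peaks matrix by SVD.
#'
#' @param rlog An [rlog_transform()] result.
#' @param top_n Number of most-variable peaks to use (all peaks if fewer).
#' @return An `atac_pca` object: list with `coords` (tibble: `sample`, `PC1`,
#'   `PC2`, ...) and `variance_explained` (fraction per component).
#' @export
pca_samples <- function(rlog, top_n = 500) {
  m <- counts_to_matrix(rlog$values)
  if (ncol(m) < 2) abort("PCA needs at least 2 samples")
  rv <- apply(m, 1, var)
  if (sum(rv) == 0) abort("zero total variance across peaks")
  keep <- head(order(rv, decreasing = TRUE), min(top_n, nrow(m)))
  pc <- prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- bind_cols(tibble(sample = colnames(m)), as_tibble(pc$x))
  structure(list(coords = coords, variance_explained = ve, n_peaks = length(keep)),
            class = "atac_pca")
}

#' @export
print.atac_pca <- function(x, ...) {
  cat(sprintf("<atac_pca> %d peaks; variance explained: %s\n", x$n_peaks,
              paste(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                            100 * x$variance_explained), collapse = ", ")))
  print(as.data.frame(x$coords))
  invisible(x)
}

#' Randomly split peaks into two subgroups
#'
#' Each peak is assigned independently to subgroup 1 or 2 with probability
#' 1/2 (so the halves are exchangeable), reproducibly for a given seed; used
#' to check that a large peak set is not skewed.
#'
#' @param peak_ids Character vector of peak ids.
#' @param seed Integer seed.
#' @return Tibble with `peak_id`, `subgroup` (integer 1 or 2); the subgroup
#'   sizes are attached as attribute `sizes`.
#' @export
random_split <- function(peak_ids, seed) {
  if (length(peak_ids) < 2) abort("need at least 2 peaks to split")
  grp <- withr::with_seed(as.integer(seed),
                          rbinom(length(peak_ids), 1L, 0.5) + 1L)
  out <- tibble(peak_id = peak_ids, subgroup = grp)
  structure(out, sizes = c(`1` = sum(grp == 1L), `2` = sum(grp == 2L)))
}

#' Cross-condition overlap of opening and closing peak sets
#'
#' Given two classifications over the same peak universe (for condition
#' pairs (N, X) and (N, Y)), reports per class how many of X's differential
#' peaks are also differential in the same direction in Y, with the shared
#' percentage rounded half away from zero to the nearest integer.
#'
#' @param class_a,class_b `atac_classes` tibbles from [classify_peaks()]
#'   over the same atlas.
#' @return Tibble with `class`, `n_a`, `n_shared`, `pct_shared`.
#' @export
overlap_summary <- function(class_a, class_b) {
  if (!setequal(class_a$peak_id, class_b$peak_id) ||
      nrow(class_a) != nrow(class_b)) {
    abort("classifications are over different peak universes")
  }
  purrr::map_dfr(c("opening", "closing"), function(cl) {
    ids_a <- class_a$peak_id[class_a$class == cl]
    ids_b <- class_b$peak_id[class_b$class == cl]
    shared <- intersect(ids_a, ids_b)
    tibble(class = cl, n_a = length(ids_a), n_shared = length(shared),
           pct_shared = if (length(ids_a) == 0) 0 else
             round_half_away(100 * length(shared) / length(ids_a)))
  })
}
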