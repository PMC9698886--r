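test_that("size factors recover depth scalings exactly", {
  m <- matrix(c(10, 20, 35, 10, 20, 35), ncol = 2)
  expect_equal(size_factors(make_counts(m))$size_factor, c(1, 1))

  # sample B = 2x sample A: geometric mean is K*sqrt(2)
  m2 <- cbind(c(10, 20, 35), 2 * c(10, 20, 35))
  expect_equal(size_factors(make_counts(m2))$size_factor,
               c(1 / sqrt(2), sqrt(2)))

  # doubling ladder (K, 2K, 4K) -> (1/2, 1, 2)
  m3 <- cbind(c(8, 40), 2 * c(8, 40), 4 * c(8, 40))
  expect_equal(size_factors(make_counts(m3))$size_factor, c(0.5, 1, 2))

  # random scaled copies of one sample: recovery up to geomean normalization
  withr::with_seed(91, {
    base <- rpois(300, 80) + 1
    sc <- c(0.5, 1.3, 2.1)
    m4 <- sapply(sc, function(s) round(base * s))
  })
  got <- size_factors(make_counts(m4))$size_factor
  expect_equal(got, sc / exp(mean(log(sc))), tolerance = 0.02)
})

test_that("all-zero-overlap count matrices error unless poscounts is allowed", {
  m <- matrix(c(5, 0, 0, 7), ncol = 2)   # no all-positive peak
  expect_error(size_factors(make_counts(m)), "poscounts")
  sf <- size_factors(make_counts(m), fallback = "poscounts")
  expect_equal(exp(mean(log(sf$size_factor))), 1, tolerance = 1e-12)
})

test_that("dispersion: constant rows are 0, Poisson data sits near the floor", {
  m <- matrix(rep(c(50, 200, 1000), 3), ncol = 3)
  expect_warning(
    fit <- fit_dispersion(make_counts(m), sf = tibble::tibble(
      sample = paste0("s", 1:3), size_factor = rep(1, 3))),
    "fewer than 10 peaks")
  expect_equal(fit$table$alpha_mom, rep(0, 3))

  withr::with_seed(101, {
    mp <- matrix(rpois(2000 * 4, 200), ncol = 4)
  })
  suppressWarnings(fitp <- fit_dispersion(make_counts(mp)))
  expect_lt(median(fitp$table$alpha_mom), 0.02)
  expect_lt(fitp$a0, 0.05)

  expect_error(fit_dispersion(make_counts(matrix(1:5, ncol = 1))), "2 samples")
})

test_that("NB dispersion 0.2 is recovered by the trend intercept", {
  withr::with_seed(107, {
    mu <- exp(runif(2000, log(50), log(2000)))
    mnb <- sapply(1:4, function(j) rnbinom(2000, mu = mu, size = 1 / 0.2))
  })
  fit <- fit_dispersion(make_counts(mnb))
  expect_gt(fit$a0, 0.1)
  expect_lt(fit$a0, 0.4)
})

test_that("rlog: equal-count rows have fold change exactly 0", {
  m <- rbind(c(100, 100), c(3, 3), c(0, 0), c(250, 70))
  cnt <- make_counts(m, samples = c("N", "CytP"))
  sf <- tibble::tibble(sample = c("N", "CytP"), size_factor = c(1, 1))
  rl <- suppressWarnings(rlog_transform(cnt, sf))
  cls <- classify_peaks(rl, c("N", "CytP"))
  expect_equal(cls$rlog_fc[1:3], rep(0, 3))
  expect_equal(as.character(cls$class[1:3]), rep("unchanged", 3))
})

test_that("rlog fold changes are antisymmetric under condition swap", {
  sim <- small_sim(seed = 113)
  atlas <- build_atlas(sim$peak_calls)
  cnt <- count_matrix(atlas, sim$fragments)
  rl <- rlog_transform(cnt)
  f1 <- classify_peaks(rl, c("N", "AgS"))
  f2 <- classify_peaks(rl, c("AgS", "N"))
  expect_equal(f1$rlog_fc, -f2$rlog_fc)
  expect_equal(f1$class == "opening", f2$class == "closing")
})

test_that("shrinkage is stronger for low counts at the same raw ratio", {
  m <- rbind(c(400, 100), c(4, 1))
  cnt <- make_counts(m, samples = c("A", "B"))
  sf <- tibble::tibble(sample = c("A", "B"), size_factor = c(1, 1))
  disp <- structure(list(table = tibble::tibble(
    peak_id = cnt$peak_id, base_mean = rowMeans(m), alpha_mom = 0.05,
    alpha_trend = 0.05), a0 = 0.05, a1 = 0), class = "dispersion_fit")
  rl <- rlog_transform(cnt, sf, disp)
  fc <- classify_peaks(rl, c("A", "B"))$rlog_fc
  expect_lt(abs(fc[2]), abs(fc[1]))
  cmat <- as.matrix(rl$shrinkage[, c("A", "B")])
  expect_true(all(cmat > 0 & cmat <= 1))
  expect_true(all(cmat[1, ] > cmat[2, ]))
})

test_that("the no-shrinkage limit recovers plain log2(n + 0.5)", {
  m <- rbind(c(100, 25), c(7, 13))
  cnt <- make_counts(m, samples = c("A", "B"))
  sf <- tibble::tibble(sample = c("A", "B"), size_factor = c(1, 1))
  rl <- suppressWarnings(rlog_transform(cnt, sf, sigma_sq = Inf))
  expect_equal(as.matrix(rl$values[, c("A", "B")]),
               log2(m + 0.5), ignore_attr = TRUE)
})

test_that("classification applies the inclusive log2(1.5) threshold", {
  expect_equal(formals(classify_peaks)$threshold, quote(log2(1.5)))
  m <- rbind(c(100, 100), c(100, 100), c(100, 100))
  cnt <- make_counts(m, samples = c("N", "X"))
  sf <- tibble::tibble(sample = c("N", "X"), size_factor = c(1, 1))
  rl <- suppressWarnings(rlog_transform(cnt, sf))
  # inject exact fold changes to probe the decision boundary
  rl$values$N <- rep(0, 3)
  rl$values$X <- c(0.60, -0.30, log2(1.5))
  cls <- classify_peaks(rl, c("N", "X"))
  expect_equal(as.character(cls$class), c("opening", "unchanged", "opening"))
  expect_error(classify_peaks(rl, c("N", "nope")), "unknown")
})

test_that("PCA: duplicated samples coincide; variance fractions behave", {
  withr::with_seed(127, {
    m <- matrix(rpois(300 * 2, 100), ncol = 2)
  })
  m <- cbind(m, m[, 2])
  cnt <- make_counts(m, samples = c("a", "b", "b2"))
  sf <- tibble::tibble(sample = c("a", "b", "b2"), size_factor = rep(1, 3))
  rl <- suppressWarnings(rlog_transform(cnt, sf))
  pca <- pca_samples(rl, top_n = 100)
  cb <- as.numeric(pca$coords[pca$coords$sample == "b", -1])
  cb2 <- as.numeric(pca$coords[pca$coords$sample == "b2", -1])
  expect_equal(cb, cb2, tolerance = 1e-8)
  ve <- pca$variance_explained
  expect_lte(sum(ve), 1 + 1e-9)
  expect_true(all(diff(ve) <= 1e-12))
})

test_that("PCA places cytokine-primed samples nearer the reference than antigen-stimulated", {
  sim <- small_sim(seed = 131)
  rl <- rlog_transform(count_matrix(build_atlas(sim$peak_calls), sim$fragments))
  pca <- pca_samples(rl)
  xy <- as.matrix(pca$coords[, c("PC1", "PC2")])
  rownames(xy) <- pca$coords$sample
  d <- function(a, b) sqrt(sum((xy[a, ] - xy[b, ])^2))
  expect_lt(d("CytP", "N"), d("AgS", "N"))
})

test_that("random_split is a reproducible, unbiased partition", {
  ids <- sprintf("pk%03d", 1:400)
  s1 <- random_split(ids, seed = 99)
  s2 <- random_split(ids, seed = 99)
  expect_equal(s1, s2)
  expect_equal(sum(attr(s1, "sizes")), 400)
  expect_false(identical(s1$subgroup, random_split(ids, seed = 100)$subgroup))

  # no skew: opening-peak share differs between halves by < 4 binomial sigma
  sim <- small_sim(seed = 137)
  rl <- rlog_transform(count_matrix(build_atlas(sim$peak_calls), sim$fragments))
  cls <- classify_peaks(rl, c("N", "AgS"))
  sp <- random_split(cls$peak_id, seed = 7)
  joined <- dplyr::left_join(sp, cls, by = "peak_id")
  p1 <- mean(joined$class[joined$subgroup == 1] == "opening")
  p2 <- mean(joined$class[joined$subgroup == 2] == "opening")
  p <- mean(joined$class == "opening")
  sigma <- sqrt(p * (1 - p) * (1 / sum(joined$subgroup == 1) +
                                 1 / sum(joined$subgroup == 2)))
  expect_lt(abs(p1 - p2), 4 * sigma)
})

test_that("overlap_summary reproduces the printed worked example and set logic", {
  universe <- sprintf("pk%05d", 1:2000)
  mk <- function(open_ids, close_ids) {
    cls <- factor(ifelse(universe %in% open_ids, "opening",
                         ifelse(universe %in% close_ids, "closing", "unchanged")),
                  levels = c("opening", "closing", "unchanged"))
    tibble::tibble(peak_id = universe, base_mean = 0, rlog_fc = 0, class = cls)
  }
  # 212 opening peaks with 70 shared; 484 closing with 305 shared
  a <- mk(universe[1:212], universe[301:784])
  b <- mk(c(universe[1:70], universe[1001:1100]),
          c(universe[301:605], universe[1201:1300]))
  ov <- overlap_summary(a, b)
  expect_equal(ov$n_shared, c(70, 305))
  expect_equal(ov$pct_shared, c(33, 63))
  # brute-force equivalence
  expect_equal(ov$n_shared[1],
               length(intersect(a$peak_id[a$class == "opening"],
                                b$peak_id[b$class == "opening"])))

  disjoint <- mk(universe[1500:1600], character())
  ov2 <- overlap_summary(a, disjoint)
  expect_equal(ov2$n_shared, c(0, 0))
  expect_equal(ov2$pct_shared, c(0, 0))

  expect_error(overlap_summary(a, mk(universe[1:10], character())[1:100, ]),
               "universe")
})
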