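test_that("precision distances use floored midpoints, strand-independent", {
  peaks <- tibble::tibble(peak_id = c("a", "b"), start = c(0, 0),
                          end = c(100, 100), strand = c("+", "-"))
  sites <- tibble::tibble(peak_id = c("a", "a", "b"),
                          site_start = c(45, 10, 10),
                          site_end = c(55, 30, 30))
  d <- precision_distances(sites, peaks)
  expect_equal(d$center_distance, c(0, 30, 30))
  orphan <- tibble::tibble(peak_id = "zz", site_start = 0, site_end = 10)
  expect_error(precision_distances(orphan, peaks), "unknown peak_id")
})

test_that("signed-rank p-values match hand enumeration of concordant pairs", {
  ref <- tibble::tibble(dataset_id = paste0("d", 1:6),
                        n_sites = c(50, 60, 70, 80, 90, 100))
  shuf <- tidyr::crossing(dataset_id = paste0("d", 1:6), shuffle = 1:2) |>
    dplyr::mutate(n_sites = c(10, 12, 11, 13, 12, 14, 15, 16, 13, 17,
                              14, 18))
  sp <- specificity_test(ref, shuf)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$p, rep(1 / 64, 2))  # all 6 pairs concordant, one-sided
  expect_equal(sp$method, rep("exact", 2))
  # reference below every shuffle: no evidence in the tested direction
  worse <- dplyr::mutate(ref, n_sites = c(1, 2, 3, 4, 5, 6))
  big <- tidyr::crossing(dataset_id = paste0("d", 1:6), shuffle = 1) |>
    dplyr::mutate(n_sites = 100 + dplyr::row_number())
  expect_equal(specificity_test(worse, big)$p, 1)
  # all differences zero: p = 1 with warning
  same <- dplyr::mutate(ref, shuffle = 1)
  expect_warning(z <- specificity_test(ref, same), "zero")
  expect_equal(z$p, 1)
  expect_error(specificity_test(ref[1:3, ], shuf), "at least 5")
})

test_that("exact signed-rank agrees with full 2^n sign enumeration", {
  withr::local_seed(55)
  enum_p <- function(d) {
    d <- d[d != 0]
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    mean(signs %*% r >= W - 1e-9)
  }
  for (i in 1:25) {
    n <- sample(5:10, 1)
    ref <- tibble::tibble(dataset_id = paste0("d", 1:n),
                          n_sites = sample(0:40, n, replace = TRUE))
    shuf <- tibble::tibble(dataset_id = paste0("d", 1:n), shuffle = 1,
                           n_sites = sample(0:40, n, replace = TRUE))
    diffs <- ref$n_sites - shuf$n_sites
    if (all(diffs == 0)) next
    got <- suppressWarnings(specificity_test(ref, shuf))
    expect_equal(got$p, enum_p(diffs), tolerance = 1e-12,
                 info = paste("iter", i))
  }
})

test_that("promiscuity summary counts sites and correlates ranks", {
  sites <- tibble::tibble(
    peak_id = c("p1", "p1", "p2"),
    site_id = c("s1", "s2", "s3"),
    n_mirnas = c(2, 1, 1))
  mp <- multiplicity_promiscuity(sites)
  expect_equal(mp$per_peak$m, c(2L, 1L))
  expect_equal(mp$per_peak$n_promiscuous, c(1L, 0L))
  expect_equal(mp$promiscuous_fraction, 0.5)
  expect_equal(mp$sites_per_peak, 4 / 2)              # interactions / peaks
  expect_equal(mp$sites_per_peak_promiscuous_as_one, 3 / 2)
  expect_equal(sum(mp$m_fractions$fraction), 1)
})

test_that("Spearman rho equals rank-then-Pearson, including ties", {
  x <- c(1, 2, 3, 4); y <- c(0, 1, 2, 3)
  expect_equal(stats::cor(x, y, method = "spearman"), 1)
  xt <- c(1, 2, 2, 3); yt <- c(3, 2, 2, 1)
  expect_equal(stats::cor(xt, yt, method = "spearman"), -1)
  withr::local_seed(60)
  for (i in 1:30) {
    a <- sample(1:5, 12, replace = TRUE)
    b <- sample(1:5, 12, replace = TRUE)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    expect_equal(stats::cor(a, b, method = "spearman"),
                 stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  }
})

test_that("quantile normalization matches the worked order statistics", {
  counts <- tibble::tibble(
    replicate = rep(c("r1", "r2"), each = 3),
    mirna = rep(c("a", "b", "c"), 2),
    count = c(2, 4, 6, 1, 5, 9))
  top <- top_expressed_mirnas(counts, k = 3)
  # both replicates normalize to (1.5, 4.5, 7.5) in their own rank order
  expect_equal(top$mean_normalized, c(7.5, 4.5, 1.5))
  expect_equal(top$mirna, c("c", "b", "a"))
  # k beyond the catalogue warns and returns everything
  expect_warning(all_ <- top_expressed_mirnas(counts, k = 10), "exceeds")
  expect_equal(nrow(all_), 3)
  # deterministic alphabetical tie-break
  tied <- tibble::tibble(replicate = "r1", mirna = c("z", "m", "a"),
                         count = c(10, 5, 5))
  expect_equal(top_expressed_mirnas(tied, k = 2)$mirna, c("z", "a"))
  # length filter drops reads outside the small-RNA window
  lng <- tibble::tibble(replicate = "r1", mirna = c("a", "a", "b"),
                        count = c(5, 7, 3), length = c(20, 50, 22))
  t2 <- top_expressed_mirnas(lng, k = 2)
  expect_equal(t2$mean_normalized[t2$mirna == "a"], 5)
})

test_that("sensitivity summary reports counts and region composition", {
  peaks <- tibble::tibble(peak_id = paste0("p", 1:10),
                          region = rep(c("3UTR", "CDS"), 5))
  sites <- tibble::tibble(peak_id = c("p1", "p1", "p3", "p5", "p2"),
                          site_id = paste0("s", 1:5))
  ss <- sensitivity_summary(peaks, sites)
  expect_equal(ss$summary$n_peaks, 10L)
  expect_equal(ss$summary$n_sites, 5L)
  expect_equal(ss$summary$pct_peaks_with_sites, 40)
  expect_equal(ss$summary$sites_per_peak, 0.5)
  expect_equal(sum(ss$peak_regions$fraction), 1)
  expect_equal(sum(ss$site_regions$fraction), 1)
  only3 <- sensitivity_summary(peaks,
                               dplyr::filter(sites, peak_id != "p2"))
  expect_equal(only3$site_regions$fraction[
    only3$site_regions$region == "3UTR"], 1)
})

test_that("site spacing takes per-peak medians of non-overlapping pairs", {
  sites <- tibble::tibble(
    peak_id = "p1", site_id = paste0("s", 1:3),
    site_start = c(5, 45, 85), site_end = c(15, 55, 95))
  sp <- site_spacing(sites)
  # centers 10, 50, 90: pair distances {40, 80, 40} -> median 40
  expect_equal(sp$per_peak$median_distance, 40)
  expect_equal(sp$median, 40)
  single <- tibble::tibble(peak_id = "p2", site_id = "s1",
                           site_start = 0, site_end = 10)
  expect_warning(none <- site_spacing(single), "no peak")
  expect_true(is.na(none$median))
  # overlapping pairs are excluded
  ovl <- tibble::tibble(peak_id = "p3", site_id = c("a", "b", "c"),
                        site_start = c(0, 5, 60), site_end = c(20, 25, 80))
  sp3 <- site_spacing(ovl)
  expect_equal(sp3$per_peak$n_pairs, 2L)
})
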