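dupx <- function(mfe = -10, paired = 14, len = 22, seed_p = 6, bulges = 1,
                 motif_p = 6, motif_l = 7, seed_l = 7, mirna = "x",
                 peak = "pk1", s = 0, e = 20) {
  tibble::tibble(peak_id = peak, mirna = mirna, len_mirna = len,
                 site_start = s, site_end = e, mfe = mfe,
                 n_paired_nt = paired, n_paired_nt_seed = seed_p,
                 n_bulges_seed = bulges, motif_len = motif_l,
                 n_paired_nt_motif = motif_p, seed_len = seed_l)
}

test_that("beta score reproduces the worked values exactly", {
  best <- dupx(mfe = -20, paired = 22, seed_p = 7, bulges = 0, motif_p = 7)
  expect_equal(beta_score(best, -20), 5, tolerance = 1e-12)
  worked <- dupx(mfe = -10, paired = 14, seed_p = 6, bulges = 1, motif_p = 6)
  expect_equal(beta_score(worked, -20),
               0.5 + 14 / 22 + 6 / 7 + 6 / 7 + 6 / 7, tolerance = 1e-12)
  expect_equal(round(beta_score(worked, -20), 6), 3.707792)
  expect_error(beta_score(dupx(mfe = 1), -20), "negative")
  expect_error(beta_score(dupx(), 1), "negative")
  expect_error(beta_score(dupx(mfe = -30), -20), "min_mfe")
})

test_that("beta is bounded by 5 and maximal only for the best duplex", {
  withr::local_seed(14)
  for (i in 1:50) {
    d <- dupx(mfe = -runif(1, 1, 30), paired = sample(7:22, 1),
              seed_p = sample(4:7, 1), bulges = sample(0:2, 1),
              motif_p = 7)
    b <- beta_score(d, -30)
    expect_gt(b, 0)
    expect_lte(b, 5)
    if (abs(b - 5) < 1e-12) {
      expect_equal(d$mfe, -30)
      expect_equal(d$n_paired_nt, 22L)
      expect_equal(d$n_bulges_seed, 0L)
    }
  }
})

test_that("binding sites merge transitively with coalition semantics", {
  # identical footprints, two miRNAs -> one site with coalition of 2
  d <- dplyr::bind_rows(dupx(mirna = "x", s = 10, e = 30),
                        dupx(mirna = "y", s = 10, e = 30))
  s1 <- group_sites(d)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$n_mirnas, 2L)
  # disjoint footprints -> two sites
  d2 <- dplyr::bind_rows(dupx(s = 0, e = 10), dupx(s = 20, e = 30))
  expect_equal(nrow(group_sites(d2)), 2)
  # 1 bp overlap merges with union bounds; adjacency does not merge
  d3 <- dplyr::bind_rows(dupx(mirna = "x", s = 10, e = 30),
                         dupx(mirna = "y", s = 29, e = 45))
  s3 <- group_sites(d3)
  expect_equal(nrow(s3), 1)
  expect_equal(c(s3$site_start, s3$site_end), c(10L, 45L))
  d4 <- dplyr::bind_rows(dupx(mirna = "x", s = 10, e = 30),
                         dupx(mirna = "y", s = 30, e = 45))
  expect_equal(nrow(group_sites(d4)), 2)
  # same miRNA twice at one site keeps the lowest-energy duplex
  d5 <- dplyr::bind_rows(dupx(mfe = -5, s = 0, e = 20),
                         dupx(mfe = -12, s = 5, e = 25))
  s5 <- group_sites(d5)
  expect_equal(s5$n_mirnas, 1L)
  expect_equal(s5$coalition[[1]]$mfe, -12)
})

test_that("mu is the log of summed coalition contributions", {
  # one coalition with beta = 5: full-score duplex
  d <- dupx(mfe = -20, paired = 22, seed_p = 7, bulges = 0, motif_p = 7)
  s <- group_sites(d)
  expect_equal(mu_score(s, min_mfe = -20)$mu, log(5), tolerance = 1e-9)
  # unit contributions make the log identities exact: ln 2 and ln 1 = 0
  imp <- tibble::tibble(
    peak_id = "pk", site_id = "s1", site_start = 0, site_end = 10,
    n_mirnas = 2,
    coalition = list(tibble::tibble(mirna = c("x", "y"),
                                    site_score = c(1, 1))))
  expect_equal(mu_score(imp, score_source = "imported")$mu, log(2))
  one <- imp
  one$coalition <- list(tibble::tibble(mirna = "x", site_score = 1))
  expect_equal(mu_score(one, score_source = "imported")$mu, 0)
  # negative imported scores (context scores) are mapped to |score|
  neg <- imp
  neg$coalition <- list(tibble::tibble(mirna = "x", site_score = -0.5))
  expect_message(mneg <- mu_score(neg, score_source = "imported"),
                 "absolute")
  expect_equal(mneg$mu, log(0.5))
})

test_that("delta sums site contributions and counts sites", {
  sites <- tibble::tibble(
    peak_id = c("pk", "pk"), site_id = c("s1", "s2"),
    mu = c(log(5), log(2)))
  occ <- degree_of_occupancy(sites)
  expect_equal(occ$delta, log(5) + log(2), tolerance = 1e-9)
  expect_equal(round(occ$delta, 6), 2.302585)
  expect_equal(occ$m, 2L)
  expect_error(degree_of_occupancy(sites[0, ]), "no binding sites")
})

test_that("mu grows sub-linearly in coalition size (log of k equal scores)", {
  base <- tibble::tibble(peak_id = "pk", site_id = "s", site_start = 0,
                         site_end = 10, n_mirnas = 1)
  mus <- vapply(1:8, function(k) {
    s <- base
    s$coalition <- list(tibble::tibble(mirna = paste0("m", 1:k),
                                       site_score = rep(2.5, k)))
    mu_score(s, score_source = "imported")$mu
  }, 0)
  expect_equal(mus, log(1:8) + log(2.5))
  gains <- diff(mus)
  expect_true(all(diff(gains) < 0))  # diminishing per-miRNA gain
})

test_that("quartile stratification assigns boundary ties downward", {
  occ <- tibble::tibble(peak_id = letters[1:8], m = 1, delta = 1:8)
  s <- stratify_quartiles(occ)
  expect_equal(s$level, rep(1:4, each = 2))
  expect_equal(attr(s, "boundaries"), c(2.75, 4.5, 6.25))
  occ4 <- tibble::tibble(peak_id = letters[1:4], m = 1, delta = 1:4)
  expect_equal(stratify_quartiles(occ4)$level, 1:4)
  # all equal -> everything level 1, with a warning
  occeq <- tibble::tibble(peak_id = letters[1:6], m = 1, delta = rep(2, 6))
  expect_warning(seq_ <- stratify_quartiles(occeq), "identical")
  expect_equal(seq_$level, rep(1L, 6))
  expect_error(stratify_quartiles(occ4, n_levels = 5), "at least")
  # region filter
  occr <- dplyr::mutate(occ, region = rep(c("3UTR", "CDS"), 4))
  sr <- stratify_quartiles(occr, region = "3UTR")
  expect_equal(nrow(sr), 4)
  expect_error(stratify_quartiles(occ, region = "3UTR"), "region")
})

test_that("stratification levels are invariant to the log base of mu", {
  withr::local_seed(8)
  occ <- tibble::tibble(peak_id = paste0("p", 1:40), m = 1,
                        delta = rexp(40))
  a <- stratify_quartiles(occ)
  b <- stratify_quartiles(dplyr::mutate(occ, delta = delta / log(10)))
  expect_equal(a$level, b$level)
  # permutation invariance
  perm <- sample(40)
  c_ <- stratify_quartiles(occ[perm, ])
  expect_equal(c_$level[order(perm)], a$level)
  # near-balanced level sizes without ties
  expect_true(all(abs(table(a$level) - 10) <= 1))
})

test_that("simple-count stratification works on m and composes with subsets", {
  occ <- tibble::tibble(peak_id = paste0("p", 1:8),
                        m = c(1, 1, 2, 2, 3, 3, 4, 4), delta = 8:1)
  s <- stratify_simple_count(occ)
  expect_equal(s$level, rep(1:4, each = 2))
  all1 <- tibble::tibble(peak_id = paste0("p", 1:6), m = 1, delta = 1:6)
  expect_warning(s1 <- stratify_simple_count(all1), "identical")
  expect_equal(s1$level, rep(1L, 6))
  # the single-site analysis path: subset to m == 1 then stratify by delta
  # (quantiles of 1..6: 2.25 / 3.5 / 4.75)
  sub <- stratify_quartiles(dplyr::filter(all1, m == 1))
  expect_equal(sub$level, c(1, 1, 2, 3, 4, 4))
})

test_that("appending a site changes delta according to its contribution", {
  withr::local_seed(12)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    base <- tibble::tibble(peak_id = "pk", site_id = paste0("s", 1:k),
                           mu = log(runif(k, 0.5, 5)))
    d0 <- degree_of_occupancy(base)$delta
    gain <- tibble::tibble(peak_id = "pk", site_id = "extra",
                           mu = log(runif(1, 1 + 1e-6, 4)))
    expect_gt(degree_of_occupancy(dplyr::bind_rows(base, gain))$delta, d0)
    neutral <- tibble::tibble(peak_id = "pk", site_id = "extra", mu = log(1))
    expect_equal(degree_of_occupancy(dplyr::bind_rows(base, neutral))$delta,
                 d0, tolerance = 1e-12)
  }
})
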