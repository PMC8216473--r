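test_that("the generator is fully deterministic under a fixed seed", {
  a <- simulate_clip_dataset(small_config())
  b <- simulate_clip_dataset(small_config())
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$genome, b$genome)
  expect_identical(a$mirnas, b$mirnas)
  expect_identical(a$truth_sites, b$truth_sites)
  expect_identical(a$expression, b$expression)
  c_ <- simulate_clip_dataset(small_config(seed = 18))
  expect_false(identical(a$peaks$start, c_$peaks$start))
})

test_that("realized pairwise Jaccard stays within 0.02 of the intention", {
  sim <- simulate_replicate_peaks(small_config())
  expect_true(all(abs(sim$truth_pairs$realized_j -
                        sim$truth_pairs$intended_j) <= 0.02))
  # adjacent pairs carry the configured target value
  adj <- sim$truth_pairs |>
    dplyr::filter(rep_1 == "rep1", rep_2 == "rep2") |>
    dplyr::left_join(dplyr::select(sim$truth_peaks, true_peak_id, target_j),
                     by = "true_peak_id")
  expect_true(all(abs(adj$realized_j - adj$target_j) <= 0.02))
  # a peak planted at J = 1 is identical across replicates
  ones <- sim$truth_pairs |>
    dplyr::left_join(dplyr::select(sim$truth_peaks, true_peak_id, target_j),
                     by = "true_peak_id") |>
    dplyr::filter(target_j == 1)
  expect_true(all(ones$realized_j == 1))
})

test_that("consensus recovers planted peaks according to their overlap", {
  cfg <- small_config()
  sim <- simulate_replicate_peaks(cfg)
  truth_at <- function(thr) {
    # a planted peak is recoverable at thr iff some intended pair >= thr
    sim$truth_pairs |>
      dplyr::group_by(true_peak_id) |>
      dplyr::summarise(ok = any(intended_j >= thr)) |>
      dplyr::filter(ok) |> nrow()
  }
  for (thr in c(0.2, 0.4, 0.8)) {
    cons <- consensus_peaks(dplyr::select(sim$peaks, -true_peak_id), thr)
    expect_equal(nrow(cons), truth_at(thr), info = paste("thr", thr))
  }
  # decoys (single-replicate) never become consensus peaks
  cons20 <- consensus_peaks(dplyr::select(sim$peaks, -true_peak_id), 0.2)
  member_ids <- unlist(lapply(cons20$members, function(m) m$peak_id))
  decoy_ids <- sim$peaks$peak_id[is.na(sim$peaks$true_peak_id)]
  expect_length(intersect(member_ids, decoy_ids), 0)
})

test_that("every planted site is recoverable by seed scanning", {
  cfg <- small_config(sites_per_peak_prob = 1)  # exactly one site per peak
  layout <- synthetic_layout(cfg)
  rp <- simulate_replicate_peaks(cfg, layout)
  ts <- simulate_targets_and_sites(cfg, layout, rp$truth_peaks)
  expect_true(all(ts$truth_m$m_true == 1))
  genome <- ts$genome
  for (i in seq_len(nrow(rp$truth_peaks))) {
    pkseq <- extract_sequence(genome, rp$truth_peaks[i, ])
    tr <- ts$truth_sites[ts$truth_sites$true_peak_id ==
                           rp$truth_peaks$true_peak_id[i], ]
    mir <- ts$mirnas$sequence[ts$mirnas$id ==
                                strsplit(tr$mirnas, ",")[[1]][1]]
    expect_gte(nrow(find_seed_matches(mir, pkseq)), 1)
  }
})

test_that("promiscuity probability one makes every site promiscuous", {
  cfg <- small_config(promiscuity_prob = 1)
  layout <- synthetic_layout(cfg)
  rp <- simulate_replicate_peaks(cfg, layout)
  ts <- simulate_targets_and_sites(cfg, layout, rp$truth_peaks)
  expect_true(all(ts$truth_sites$n_mirnas_true >= 2))
  # scanning then grouping finds multi-miRNA coalitions at those loci
  pk1 <- rp$truth_peaks[1, ]
  seqs <- tibble::tibble(
    peak_id = pk1$true_peak_id,
    sequence = extract_sequence(ts$genome, pk1))
  dup <- predict_binding_sites(seqs, ts$mirnas)
  grp <- group_sites(dup)
  expect_gte(max(grp$n_mirnas), 2)
})

test_that("background anchor counts match the binomial expectation", {
  # no embedding: 7mer matches on random sequence are Bernoulli(4^-7) per
  # position
  withr::local_seed(123)
  L <- 200000
  target <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                  collapse = "")
  mir <- "ACGUACGUACGUACGUACGU"
  n_hits <- nrow(find_seed_matches(mir, target))
  expected <- (L - 6) * 0.25^7
  expect_lt(abs(n_hits - expected), 4 * sqrt(expected) + 1)
})

test_that("noiseless expression is exactly linear in the true site count", {
  cfg <- small_config(noise_sd = 0, repression_slope = 0.2)
  layout <- synthetic_layout(cfg)
  rp <- simulate_replicate_peaks(cfg, layout)
  ts <- simulate_targets_and_sites(cfg, layout, rp$truth_peaks)
  expr <- simulate_expression(cfg, layout, ts$truth_m)
  j <- dplyr::inner_join(expr, ts$truth_m, by = "gene_id")
  expect_equal(j$log2fc, -0.2 * j$m_true)
  bg <- dplyr::anti_join(expr, ts$truth_m, by = "gene_id")
  expect_true(all(bg$log2fc == 0))
})

test_that("peaks too short for the requested sites raise an error", {
  cfg <- small_config(peak_width = 40,
                      sites_per_peak_prob = c(0, 0, 0, 1))
  layout <- synthetic_layout(cfg)
  rp <- simulate_replicate_peaks(cfg, layout)
  expect_error(simulate_targets_and_sites(cfg, layout, rp$truth_peaks),
               "too short")
})

test_that("occupancy ranking recovers the planted site-count ordering", {
  sim <- simulate_clip_dataset(small_config(n_true_peaks = 120))
  cons <- consensus_peaks(dplyr::select(sim$peaks, -true_peak_id), 0.2)
  cons <- annotate_regions(dplyr::rename(cons, peak_id = consensus_id),
                           sim$layout$regions)
  seqs <- cons |>
    dplyr::mutate(sequence = purrr::pmap_chr(
      list(chrom, start, end, strand),
      function(ch, s, e, st) extract_sequence(
        sim$genome, list(chrom = ch, start = s, end = e, strand = st))))
  dup <- predict_binding_sites(seqs, sim$mirnas)
  occ <- occupancy(dup, peaks = cons)
  pg <- map_peaks_to_genes(cons, dplyr::select(sim$layout$genes, chrom,
                                               start, end, strand, gene_id))
  j <- occ |>
    dplyr::inner_join(pg, by = "peak_id") |>
    dplyr::inner_join(sim$truth_m, by = "gene_id")
  expect_gte(stats::cor(j$delta, j$m_true, method = "spearman"), 0.75)
})
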