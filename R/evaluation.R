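#' Distance of binding sites to peak centers
#'
#' Peak-center precision: the absolute distance (nt) between each site's
#' midpoint and its peak's midpoint, strand-independent. Midpoints of
#' 0-based half-open intervals use `floor((start + end) / 2)`.
#'
#' @param sites Site tibble with `peak_id`, `site_start`, `site_end`
#'   (coordinates in the same frame as the peaks; peak-local coordinates
#'   with peak-local peaks, or genomic with genomic peaks).
#' @param peaks Peak tibble with `peak_id`, `start`, `end`.
#' @return `sites` with a `center_distance` column added.
#' @export
precision_distances <- function(sites, peaks) {
  if (!all(sites$peak_id %in% peaks$peak_id))
    abort("site refers to an unknown peak_id")
  pk <- peaks |>
    mutate(.peak_mid = floor((.data$start + .data$end) / 2)) |>
    select("peak_id", ".peak_mid")
  sites |>
    left_join(pk, by = "peak_id") |>
    mutate(center_distance = abs(
      floor((.data$site_start + .data$site_end) / 2) - .data$.peak_mid)) |>
    select(-".peak_mid")
}

# Exact one-sided signed-rank p-value P(W+ >= w) for n tie-free |differences|
# via the exact null distribution; with ties, full 2^n sign enumeration for
# n <= max_enum.
signed_rank_p <- function(d, max_enum = 12) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p = 1, n = 0, W = NA_real_, method = "degenerate"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  tied <- anyDuplicated(abs(d)) > 0
  if (!tied && n <= 25) {
    p <- 1 - stats::psignrank(W - 1, n)
    method <- "exact"
  } else if (tied && n <= max_enum) {
    signs <- expand.grid(rep(list(c(0, 1)), n))
    Wnull <- as.matrix(signs) %*% r
    p <- mean(Wnull >= W - 1e-9)
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties_tab^3 - ties_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal_approx"
  }
  list(p = p, n = n, W = W, method = method)
}

#' Specificity of site identification against shuffled-miRNA controls
#'
#' Compares per-dataset reference site counts with the counts obtained from
#' each mononucleotide-shuffled miRNA control, using a paired one-sided
#' Wilcoxon signed-rank test (alternative: reference > shuffle). Zero
#' differences are dropped; the p-value is exact when the differences are
#' tie-free and `n <= 25` (full sign enumeration when tied and small), and a
#' continuity-corrected normal approximation otherwise.
#'
#' @param reference_counts Tibble `dataset_id`, `n_sites` (one row per
#'   dataset).
#' @param shuffle_counts Tibble `dataset_id`, `shuffle`, `n_sites` (one row
#'   per dataset x shuffle).
#' @return Tibble with one row per shuffle: `shuffle`, `n_pairs`,
#'   `statistic`, `p`, `method`.
#' @export
specificity_test <- function(reference_counts, shuffle_counts) {
  stopifnot(all(c("dataset_id", "n_sites") %in% names(reference_counts)),
            all(c("dataset_id", "shuffle", "n_sites") %in%
                  names(shuffle_counts)))
  if (nrow(reference_counts) < 5)
    abort("specificity test needs at least 5 paired datasets")
  shuffle_counts |>
    group_by(.data$shuffle) |>
    dplyr::group_modify(function(s, key) {
      m <- left_join(reference_counts, s, by = "dataset_id",
                     suffix = c("_ref", "_shuf"))
      d <- m$n_sites_ref - m$n_sites_shuf
      if (all(d == 0)) {
        warn("all reference/shuffle differences are zero")
        return(tibble(n_pairs = 0L, statistic = NA_real_, p = 1,
                      method = "degenerate"))
      }
      r <- signed_rank_p(d)
      tibble(n_pairs = r$n, statistic = r$W, p = r$p, method = r$method)
    }) |>
    ungroup()
}

#' Multiplicity and promiscuity of binding sites per peak
#'
#' A promiscuous binding site is one targeted by more than one miRNA. This
#' summarizes, per peak, the number of binding sites (`m`) and the number of
#' promiscuous sites, tabulates their dataset-level fractions, reports the
#' Spearman rank correlation (average ranks on ties) between the two
#' per-peak vectors, and gives the per-peak normalized site count, both
#' counting every miRNA::site interaction and counting each promiscuous site
#' once.
#'
#' @param sites Site tibble from [group_sites()] (`peak_id`, `site_id`,
#'   `n_mirnas`).
#' @return A list: `per_peak` (tibble `peak_id`, `m`, `n_promiscuous`),
#'   `m_fractions` (fraction of peaks per site count), `promiscuous_fraction`
#'   (fraction of peaks with at least one promiscuous site),
#'   `spearman_rho`, `sites_per_peak` (total miRNA::site interactions /
#'   peaks), `sites_per_peak_promiscuous_as_one` (each site counted once).
#' @export
multiplicity_promiscuity <- function(sites) {
  per_peak <- sites |>
    group_by(.data$peak_id) |>
    summarise(m = n(), n_promiscuous = sum(.data$n_mirnas >= 2),
              .groups = "drop")
  rho <- if (nrow(per_peak) >= 2 && sd(per_peak$m) > 0 &&
               sd(per_peak$n_promiscuous) > 0) {
    stats::cor(per_peak$m, per_peak$n_promiscuous, method = "spearman")
  } else NA_real_
  total_peaks <- nrow(per_peak)
  list(
    per_peak = per_peak,
    m_fractions = per_peak |> dplyr::count(.data$m, name = "n_peaks") |>
      mutate(fraction = .data$n_peaks / total_peaks),
    promiscuous_fraction = mean(per_peak$n_promiscuous >= 1),
    spearman_rho = rho,
    sites_per_peak = sum(sites$n_mirnas) / total_peaks,
    sites_per_peak_promiscuous_as_one = nrow(sites) / total_peaks)
}

#' Rank the most expressed miRNAs across replicates
#'
#' Quantile-normalizes per-replicate miRNA read counts (mean-of-order-
#' statistics reference, average ties), averages across replicates, and
#' returns the top `k` miRNAs (descending mean, ties broken alphabetically).
#' When a `length` column is present, reads outside `len_range` are dropped
#' first (small-RNA length gate).
#'
#' @param mirna_counts Long tibble `replicate`, `mirna`, `count` (optional
#'   `length` column for the length filter).
#' @param k Number of top miRNAs (default 25).
#' @param len_range Inclusive read-length range applied when a `length`
#'   column is present.
#' @return Tibble `mirna`, `mean_normalized`, `rank`, at most `k` rows.
#' @export
top_expressed_mirnas <- function(mirna_counts, k = 25,
                                 len_range = c(18, 35)) {
  if ("length" %in% names(mirna_counts)) {
    mirna_counts <- filter(mirna_counts, .data$length >= len_range[1],
                           .data$length <= len_range[2]) |>
      group_by(.data$replicate, .data$mirna) |>
      summarise(count = sum(.data$count), .groups = "drop")
  }
  wide <- mirna_counts |>
    tidyr::pivot_wider(id_cols = "mirna", names_from = "replicate",
                       values_from = "count", values_fill = 0)
  mat <- as.matrix(wide[-1])
  norm <- limma::normalizeQuantiles(mat, ties = TRUE)
  res <- tibble(mirna = wide$mirna, mean_normalized = rowMeans(norm)) |>
    arrange(dplyr::desc(.data$mean_normalized), .data$mirna) |>
    mutate(rank = row_number())
  if (k > nrow(res)) {
    warn(sprintf("k = %d exceeds the %d available miRNAs; returning all",
                 k, nrow(res)))
    k <- nrow(res)
  }
  dplyr::slice_head(res, n = k)
}

#' Dataset sensitivity summary
#'
#' Counts peaks and binding sites, the percentage of peaks containing at
#' least one site, and the transcript-region composition of both peaks and
#' sites (a site inherits its peak's region).
#'
#' @param peaks Peak tibble with `peak_id` and a `region` column.
#' @param sites Site tibble with `peak_id`.
#' @param dataset_id Optional label.
#' @return A list: `summary` (one-row tibble: `dataset_id`, `n_peaks`,
#'   `n_sites`, `sites_per_peak`, `pct_peaks_with_sites`), `peak_regions`
#'   and `site_regions` (fraction tibbles).
#' @export
sensitivity_summary <- function(peaks, sites, dataset_id = "dataset") {
  with_sites <- unique(sites$peak_id)
  site_regions <- sites |>
    left_join(select(peaks, "peak_id", "region"), by = "peak_id") |>
    region_fractions()
  list(
    summary = tibble(
      dataset_id = dataset_id, n_peaks = nrow(peaks), n_sites = nrow(sites),
      sites_per_peak = nrow(sites) / nrow(peaks),
      pct_peaks_with_sites = 100 * mean(peaks$peak_id %in% with_sites)),
    peak_regions = region_fractions(peaks),
    site_regions = site_regions)
}

#' Spacing of non-overlapping binding sites within peaks
#'
#' For every peak with at least two binding sites, the median over all pairs
#' of non-overlapping sites of the absolute distance between their centers;
#' then the dataset median of the per-peak medians. This is the distance
#' scale over which co-bound sites could cooperate.
#'
#' @param sites Site tibble (`peak_id`, `site_start`, `site_end`).
#' @return A list: `per_peak` (tibble `peak_id`, `n_pairs`,
#'   `median_distance`), `median` (dataset median, NA with a warning when no
#'   peak has two non-overlapping sites).
#' @export
site_spacing <- function(sites) {
  per_peak <- sites |>
    group_by(.data$peak_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(tibble())
      ctr <- floor((d$site_start + d$site_end) / 2)
      pairs <- t(utils::combn(nrow(d), 2))
      disjoint <- d$site_end[pairs[, 1]] <= d$site_start[pairs[, 2]] |
        d$site_end[pairs[, 2]] <= d$site_start[pairs[, 1]]
      if (!any(disjoint)) return(tibble())
      dist <- abs(ctr[pairs[, 1]] - ctr[pairs[, 2]])[disjoint]
      tibble(n_pairs = sum(disjoint), median_distance = median(dist))
    }) |>
    ungroup()
  if (nrow(per_peak) == 0) {
    warn("no peak with two or more non-overlapping sites")
    return(list(per_peak = per_peak, median = NA_real_))
  }
  list(per_peak = per_peak, median = median(per_peak$median_distance))
}
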