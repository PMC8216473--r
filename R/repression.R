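#' Map peaks to genes by maximal overlap
#'
#' Assigns each peak to the gene span it maximally overlaps (ties broken
#' lexicographically by `gene_id`). Peaks overlapping no gene are dropped and
#' their count reported as a message.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `strand`, `peak_id`).
#' @param genes Gene-span tibble: `chrom`, `start`, `end`, `gene_id`
#'   (optional `strand`, matched when present in both).
#' @return Tibble `peak_id`, `gene_id` for the mapped peaks.
#' @export
map_peaks_to_genes <- function(peaks, genes) {
  lab <- assign_max_overlap(peaks, genes, label_col = "gene_id",
                            tie_order = NULL, no_hit = NA_character_)
  dropped <- sum(is.na(lab))
  if (dropped > 0)
    inform(sprintf("%d peak(s) overlapped no gene and were dropped", dropped))
  tibble(peak_id = peaks$peak_id, gene_id = lab) |>
    filter(!is.na(.data$gene_id))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; `p` is the
#' asymptotic two-sided p-value.
#'
#' @param x,y Numeric samples (non-empty).
#' @return Tibble `D`, `p` (one row).
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("empty sample in KS test")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble(D = unname(kt$statistic), p = kt$p.value)
}

#' Target repression by occupancy level
#'
#' Joins stratified peaks to genes and to a log2 fold-change table, and tests
#' each level's gene set against the all-gene background with the two-sample
#' KS test. The signed median shift (level median minus background median;
#' negative = repression, i.e. a left-shifted CDF) is reported alongside the
#' two-sided KS p-value. A level with no mapped genes is reported with NA
#' statistics and a warning.
#'
#' @param stratified Stratified occupancy tibble (see
#'   [stratify_quartiles()]): `peak_id`, `level`.
#' @param peak_genes Peak-to-gene map (see [map_peaks_to_genes()]).
#' @param expression Expression tibble `gene_id`, `log2fc` (see
#'   [read_expression_table()]); defines the background (all genes,
#'   targets included).
#' @param dedupe_genes `"per_level"` (default): a gene reached by peaks in
#'   several levels is counted in each (deduplicated within level).
#'   `"max_level"`: each gene is assigned only to its highest level.
#' @return An object of class `repression_test` with components `levels`
#'   (per-level tibble: `level`, `n_genes`, `median_log2fc`,
#'   `median_shift`, `ks_D`, `ks_p`), `cdf` (long tibble `level`, `log2fc`,
#'   `ecdf`, including a `"background"` level) and `background_n`. Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @export
repression_by_level <- function(stratified, peak_genes, expression,
                                dedupe_genes = c("per_level", "max_level")) {
  dedupe_genes <- match.arg(dedupe_genes)
  joined <- stratified |>
    select("peak_id", "level") |>
    inner_join(peak_genes, by = "peak_id") |>
    distinct(.data$level, .data$gene_id)
  if (dedupe_genes == "max_level") {
    joined <- joined |> group_by(.data$gene_id) |>
      dplyr::slice_max(.data$level, n = 1, with_ties = FALSE) |> ungroup()
  }
  joined <- inner_join(joined, expression, by = "gene_id")
  bg <- expression$log2fc
  bg_med <- median(bg)
  levels_all <- sort(unique(stratified$level))
  per_level <- purrr::map(levels_all, function(lv) {
    v <- joined$log2fc[joined$level == lv]
    if (length(v) == 0) {
      warn(sprintf("level %d has no mapped genes", lv))
      return(tibble(level = lv, n_genes = 0L, median_log2fc = NA_real_,
                    median_shift = NA_real_, ks_D = NA_real_,
                    ks_p = NA_real_))
    }
    kt <- ks_two_sample(v, bg)
    tibble(level = lv, n_genes = length(v), median_log2fc = median(v),
           median_shift = median(v) - bg_med, ks_D = kt$D, ks_p = kt$p)
  }) |> bind_rows()
  cdf <- bind_rows(
    joined |>
      group_by(.data$level) |>
      arrange(.data$log2fc, .by_group = TRUE) |>
      mutate(ecdf = row_number() / n(), level = as.character(.data$level)) |>
      ungroup() |>
      select("level", "log2fc", "ecdf"),
    tibble(level = "background", log2fc = sort(bg),
           ecdf = seq_along(bg) / length(bg)))
  structure(list(levels = per_level, cdf = cdf, background_n = length(bg)),
            class = "repression_test")
}

#' @export
print.repression_test <- function(x, ...) {
  cat("Target repression by occupancy level (KS vs", x$background_n,
      "background genes)\n")
  print(x$levels)
  invisible(x)
}

#' @rdname repression_by_level
#' @param x A `repression_test` object.
#' @param ... Unused.
#' @method tidy repression_test
#' @export
tidy.repression_test <- function(x, ...) x$levels

#' @rdname repression_by_level
#' @method glance repression_test
#' @export
glance.repression_test <- function(x, ...) {
  ok <- !is.na(x$levels$ks_p)
  tibble(n_levels = nrow(x$levels),
         n_genes_total = sum(x$levels$n_genes),
         min_ks_p = if (any(ok)) min(x$levels$ks_p[ok]) else NA_real_,
         monotone_median = !is.unsorted(rev(x$levels$median_log2fc[ok])))
}

#' @rdname repression_by_level
#' @param object A `repression_test` object.
#' @method autoplot repression_test
#' @export
autoplot.repression_test <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(x = .data$log2fc, y = .data$ecdf,
                               colour = .data$level)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log2 fold change", y = "cumulative fraction",
                  colour = "occupancy level") +
    ggplot2::theme_minimal()
}
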