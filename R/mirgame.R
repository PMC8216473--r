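#' Per-heteroduplex binding score (beta)
#'
#' The per-duplex contribution to the occupancy model: five additive terms,
#' each in `(0, 1]` for duplexes produced by the internal engine —
#'
#' `beta = mfe/min_mfe + n_paired_nt/len_mirna + n_paired_nt_seed/seed_len +
#'  n_paired_nt_motif/motif_len + (seed_len - n_bulges_seed)/seed_len`
#'
#' The energy term normalizes each duplex's minimum free energy by the most
#' negative energy in scope (`min_mfe`), so the most stable duplex scores 1
#' on that term and the score is bounded by 5.
#'
#' @param duplexes Heteroduplex tibble (see [hybridize()] /
#'   [predict_binding_sites()]); needs `mfe`, `n_paired_nt`, `len_mirna`,
#'   `n_paired_nt_seed`, `n_bulges_seed`, `n_paired_nt_motif`, `motif_len`,
#'   `seed_len`.
#' @param min_mfe The reference minimum free energy (negative,
#'   `<= min(duplexes$mfe)`); typically the dataset minimum.
#' @return A numeric vector of scores, one per duplex.
#' @export
beta_score <- function(duplexes, min_mfe) {
  if (any(duplexes$mfe >= 0)) abort("duplex mfe must be negative")
  if (min_mfe >= 0) abort("min_mfe must be negative")
  if (any(min_mfe > duplexes$mfe + 1e-12))
    abort("min_mfe must be <= every duplex mfe")
  duplexes$mfe / min_mfe +
    duplexes$n_paired_nt / duplexes$len_mirna +
    duplexes$n_paired_nt_seed / duplexes$seed_len +
    duplexes$n_paired_nt_motif / duplexes$motif_len +
    (duplexes$seed_len - duplexes$n_bulges_seed) / duplexes$seed_len
}

#' Group heteroduplexes into binding sites
#'
#' A binding site is the "player" of the occupancy game: duplexes on the same
#' peak whose target footprints overlap by at least 1 bp are merged
#' transitively into one site (union bounds), and the miRNAs hitting that
#' site form its coalition. Within a site, multiple duplexes of the same
#' miRNA are collapsed to the lowest-energy one.
#'
#' @param duplexes Heteroduplex tibble with `peak_id`, `site_start`,
#'   `site_end`, `mirna`, `mfe` (plus any feature columns, carried along).
#' @return A site tibble: `peak_id`, `site_id`, `site_start`, `site_end`
#'   (union bounds), `n_mirnas`, and a `coalition` list-column holding the
#'   per-miRNA member duplex rows.
#' @export
group_sites <- function(duplexes) {
  if (nrow(duplexes) == 0) {
    return(tibble(peak_id = character(), site_id = character(),
                  site_start = integer(), site_end = integer(),
                  n_mirnas = integer(), coalition = list()))
  }
  duplexes |>
    group_by(.data$peak_id) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(d$site_start + 1L, d$site_end)
      merged <- IRanges::reduce(ir, min.gapwidth = 0L)
      grp <- S4Vectors::subjectHits(
        IRanges::findOverlaps(ir, merged, minoverlap = 1L))
      d$`.grp` <- grp
      d |>
        group_by(.data$.grp) |>
        dplyr::group_modify(function(s, k2) {
          best <- s |>
            group_by(.data$mirna) |>
            dplyr::slice_min(.data$mfe, n = 1, with_ties = FALSE) |>
            ungroup()
          tibble(site_start = min(s$site_start), site_end = max(s$site_end),
                 n_mirnas = nrow(best), coalition = list(best))
        }) |>
        ungroup() |>
        select(-".grp")
    }) |>
    ungroup() |>
    arrange(.data$peak_id, .data$site_start) |>
    group_by(.data$peak_id) |>
    mutate(site_id = sprintf("%s_s%d", .data$peak_id[1], row_number())) |>
    ungroup() |>
    select("peak_id", "site_id", "site_start", "site_end", "n_mirnas",
           "coalition")
}

#' Per-site coalition score (mu)
#'
#' The marginal contribution of a binding site: the natural log of the sum of
#' its coalition's per-duplex scores. Summing inside the log makes the score
#' of a site shared by many miRNAs grow only logarithmically with the
#' coalition size, reflecting that such sites respond to the pool of
#' targeting miRNAs rather than to any single one.
#'
#' @param sites Site tibble from [group_sites()] (or from
#'   [import_external_sites()] routed through `score_source = "imported"`).
#' @param min_mfe Reference minimum free energy for [beta_score()]; required
#'   when `score_source = "beta"`.
#' @param score_source `"beta"` (default): coalition contributions are beta
#'   scores of the member duplexes. `"imported"`: contributions are the
#'   sites' `site_score` values (TargetScan context scores, which are
#'   negative, are mapped to their absolute value first; a message records
#'   this).
#' @return `sites` with a `mu` column added.
#' @export
mu_score <- function(sites, min_mfe = NULL,
                     score_source = c("beta", "imported")) {
  score_source <- match.arg(score_source)
  if (score_source == "beta") {
    if (is.null(min_mfe)) abort("min_mfe is required for score_source='beta'")
    contrib <- purrr::map_dbl(sites$coalition,
                              function(d) sum(beta_score(d, min_mfe)))
  } else {
    contrib <- purrr::map_dbl(sites$coalition, function(d) {
      s <- d$site_score
      if (any(s < 0)) {
        inform("negative imported site scores mapped to absolute values")
        s <- abs(s)
      }
      sum(s)
    })
  }
  if (any(contrib <= 0))
    abort("non-positive coalition contribution sum; cannot take log")
  sites$mu <- log(contrib)
  sites
}

#' Degree of occupancy per peak (delta)
#'
#' Sums the per-site coalition scores within each peak into the peak's degree
#' of occupancy and counts its binding sites.
#'
#' @param sites Site tibble with a `mu` column (see [mu_score()]).
#' @return A peak-occupancy tibble: `peak_id`, `m` (number of binding
#'   sites), `delta`.
#' @export
degree_of_occupancy <- function(sites) {
  if (nrow(sites) == 0) abort("no binding sites; occupancy is undefined")
  sites |>
    group_by(.data$peak_id) |>
    summarise(m = n(), delta = sum(.data$mu), .groups = "drop")
}

#' Occupancy pipeline: duplexes to per-peak degree of occupancy
#'
#' Convenience wrapper chaining [group_sites()], [mu_score()] and
#' [degree_of_occupancy()], with the energy reference (`min_mfe`) resolved by
#' scope: the most negative duplex energy across the whole run (`"dataset"`,
#' default, making scores comparable across peaks) or per miRNA
#' (`"per_mirna"`).
#'
#' @param duplexes Heteroduplex tibble from [predict_binding_sites()].
#' @param peaks Optional peak tibble with `peak_id` and `region`; when given,
#'   the peaks' region labels are joined onto the result.
#' @param min_mfe_scope `"dataset"` or `"per_mirna"`.
#' @param score_source Passed to [mu_score()].
#' @return Peak-occupancy tibble: `peak_id`, `m`, `delta` (+ `region`).
#' @export
occupancy <- function(duplexes, peaks = NULL,
                      min_mfe_scope = c("dataset", "per_mirna"),
                      score_source = c("beta", "imported")) {
  min_mfe_scope <- match.arg(min_mfe_scope)
  score_source <- match.arg(score_source)
  sites <- group_sites(duplexes)
  if (score_source == "beta" && min_mfe_scope == "per_mirna") {
    # per-miRNA scope: score each member against its own miRNA's minimum
    ref <- duplexes |> group_by(.data$mirna) |>
      summarise(.min_mfe = min(.data$mfe), .groups = "drop")
    contrib <- purrr::map_dbl(sites$coalition, function(d) {
      d <- left_join(d, ref, by = "mirna")
      sum(purrr::map_dbl(seq_len(nrow(d)), function(i)
        beta_score(d[i, ], d$.min_mfe[i])))
    })
    if (any(contrib <= 0)) abort("non-positive coalition contribution sum")
    sites$mu <- log(contrib)
  } else {
    mm <- if (score_source == "beta") min(duplexes$mfe) else NULL
    sites <- mu_score(sites, min_mfe = mm, score_source = score_source)
  }
  occ <- degree_of_occupancy(sites)
  if (!is.null(peaks) && "region" %in% names(peaks))
    occ <- left_join(occ, select(peaks, "peak_id", "region"), by = "peak_id")
  occ
}

#' Stratify peaks into occupancy levels by quantiles
#'
#' Splits peaks into `n_levels` levels by quantile boundaries
#' (linear-interpolation quantiles at probabilities `1/n, ..., (n-1)/n`) of
#' the degree of occupancy, computed over the region-filtered peaks
#' (conventionally the 3'UTR peaks). Level 1 is lowest occupancy, level
#' `n_levels` highest; a value equal to a boundary goes to the lower level.
#'
#' @param occupancies Peak-occupancy tibble (see [occupancy()]).
#' @param by `"delta"` (default) stratifies by degree of occupancy;
#'   `"count"` stratifies by the per-peak binding-site count `m` (the
#'   simple-count baseline).
#' @param region Region label to filter on before stratifying (requires a
#'   `region` column), or `NULL` for no filter.
#' @param n_levels Number of levels (default 4: quartiles).
#' @return The filtered occupancy tibble with a `level` column; the numeric
#'   boundaries are attached as `attr(, "boundaries")`.
#' @export
stratify_quartiles <- function(occupancies, by = c("delta", "count"),
                               region = NULL, n_levels = 4) {
  by <- match.arg(by)
  stopifnot(n_levels >= 2)
  occ <- occupancies
  if (!is.null(region)) {
    if (!"region" %in% names(occ))
      abort("region filter requested but no region column present")
    occ <- filter(occ, .data$region == !!region)
  }
  if (nrow(occ) < n_levels)
    abort(sprintf("only %d peaks after filtering; need at least %d",
                  nrow(occ), n_levels))
  x <- if (by == "delta") occ$delta else occ$m
  bounds <- quantile(x, probs = seq_len(n_levels - 1) / n_levels,
                     type = 7, names = FALSE)
  occ$level <- 1L + rowSums(outer(x, bounds, `>`))
  if (length(unique(x)) == 1)
    warn("all occupancy values identical; every peak assigned level 1")
  attr(occ, "boundaries") <- bounds
  occ
}

#' Simple-count stratification baseline
#'
#' Quantile stratification applied to the raw binding-site count `m` instead
#' of the degree of occupancy. Equivalent to
#' `stratify_quartiles(occupancies, by = "count", ...)`.
#'
#' @inheritParams stratify_quartiles
#' @return As [stratify_quartiles()].
#' @export
stratify_simple_count <- function(occupancies, region = NULL, n_levels = 4) {
  stratify_quartiles(occupancies, by = "count", region = region,
                     n_levels = n_levels)
}
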