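#' Jaccard index of two genomic intervals
#'
#' The Jaccard index of two intervals is the number of base positions they
#' share divided by the number of base positions in their union. Intervals on
#' different chromosomes or strands have index 0. This is the
#' replicate-reproducibility statistic thresholded by [consensus_peaks()].
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` and optionally
#'   `strand` (0-based half-open). Rows are paired (shorter input recycled if
#'   it has one row).
#' @return A numeric vector in `[0, 1]`.
#' @examples
#' jaccard_index(data.frame(chrom = "c", start = 0, end = 100),
#'               data.frame(chrom = "c", start = 50, end = 150))
#' @export
jaccard_index <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1) b <- b[rep(1, n), ]
  stopifnot(nrow(a) == nrow(b))
  same <- a$chrom == b$chrom
  if ("strand" %in% names(a) && "strand" %in% names(b))
    same <- same & a$strand == b$strand
  inter <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  uni <- (a$end - a$start) + (b$end - b$start) - inter
  ifelse(same, inter / uni, 0)
}

#' Call peaks from aligned-read intervals by coverage runs
#'
#' A plumbing peak caller: maximal runs of base positions (per chromosome and
#' strand) with read coverage at least `min_coverage` and run length at least
#' `min_length` become peaks, with `support` equal to the maximum coverage
#' within the run.
#'
#' @param reads Tibble of read intervals: `chrom`, `start`, `end`, `strand`.
#' @param min_coverage Minimum read depth for a position to be inside a peak.
#' @param min_length Minimum peak length in nt.
#' @param id_prefix Prefix for generated `peak_id`s.
#' @return A peak tibble: `chrom`, `start`, `end`, `strand`, `peak_id`,
#'   `support`.
#' @export
call_peaks <- function(reads, min_coverage = 2, min_length = 10,
                       id_prefix = "pk") {
  stopifnot(min_coverage >= 1, min_length >= 1)
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), peak_id = character(),
                  support = integer())
  if (nrow(reads) == 0) return(empty)
  if (!"strand" %in% names(reads)) reads$strand <- "+"
  out <- reads |>
    group_by(.data$chrom, .data$strand) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
      cov <- IRanges::coverage(ir)
      runs <- IRanges::slice(cov, lower = min_coverage, rangesOnly = FALSE)
      w <- IRanges::width(runs)
      keep <- w >= min_length
      tibble(start = IRanges::start(runs)[keep] - 1L,
             end = IRanges::end(runs)[keep],
             support = as.integer(IRanges::viewMaxs(runs)[keep]))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$strand, .data$start)
  if (nrow(out) == 0) return(empty)
  out |>
    mutate(peak_id = sprintf("%s%04d", id_prefix, row_number())) |>
    select("chrom", "start", "end", "strand", "peak_id", "support")
}

#' Merge-method baseline: pool replicates before peak calling
#'
#' The baseline the consensus method is compared against: all replicates'
#' reads are concatenated and [call_peaks()] is run once on the pool, so a
#' position can clear `min_coverage` from the sum of sub-threshold replicate
#' coverages. Invariant to replicate labelling.
#'
#' @param replicate_reads Named list of read tibbles, or one tibble with a
#'   `replicate_id` column.
#' @inheritParams call_peaks
#' @return A peak tibble as from [call_peaks()].
#' @export
merge_method <- function(replicate_reads, min_coverage = 2, min_length = 10) {
  reads <- if (is.data.frame(replicate_reads)) replicate_reads
           else bind_rows(replicate_reads)
  call_peaks(reads, min_coverage = min_coverage, min_length = min_length,
             id_prefix = "merged_pk")
}

# normalize replicate peak input to one tibble with replicate_id
as_replicate_peaks <- function(replicate_peaks) {
  pk <- if (is.data.frame(replicate_peaks)) {
    replicate_peaks
  } else {
    bind_rows(replicate_peaks, .id = "replicate_id")
  }
  if (!"replicate_id" %in% names(pk))
    abort("replicate peaks need a replicate_id column or a named list")
  if (!"strand" %in% names(pk)) pk$strand <- "+"
  if (!"peak_id" %in% names(pk)) {
    pk <- pk |> group_by(.data$replicate_id) |>
      mutate(peak_id = sprintf("%s_pk%04d", .data$replicate_id[1],
                               row_number())) |>
      ungroup()
  }
  pk
}

#' Consensus peaks across replicates by Jaccard-index thresholding
#'
#' Peak calling is run per replicate; reproducible peaks are then identified
#' from the overlap structure. Peaks from *different* replicates overlapping
#' by at least 1 bp are connected in an overlap graph; each connected
#' component spanning at least `min_replicates` replicates is a candidate
#' consensus peak, and the Jaccard index is computed for every cross-replicate
#' peak pair in the component. The component is retained when
#'
#' * `aggregation = "any_pair"` (default): at least one pair's Jaccard index
#'   reaches `threshold`;
#' * `"all_pairs"`: every cross-replicate pair reaches it;
#' * `"group"`: the intersection across replicates of each replicate's merged
#'   footprint, divided by the union of all footprints, reaches it.
#'
#' Retained components are reported with union bounds over their members.
#' Lowering `threshold` can only grow the consensus set: the set at 0.8 is a
#' subset of the set at 0.4, which is a subset of the set at 0.2.
#'
#' @param replicate_peaks Named list of peak tibbles, or one tibble with a
#'   `replicate_id` column. Peaks need `chrom`, `start`, `end`, `strand`,
#'   and get `peak_id`s if missing.
#' @param threshold Jaccard-index threshold in `(0, 1]` (0.2, 0.4 and 0.8 are
#'   the conventional operating points).
#' @param min_replicates Minimum number of distinct replicates a component
#'   must span (default 2).
#' @param aggregation How pairwise Jaccard values are aggregated across more
#'   than two replicates; see above.
#' @return A tibble of consensus peaks: `chrom`, `start`, `end`, `strand`,
#'   `consensus_id`, `n_replicates`, `n_members`, `max_jaccard`, `threshold`,
#'   plus list-columns `members` (member peak tibble) and `pair_jaccard`
#'   (per cross-replicate pair).
#' @export
consensus_peaks <- function(replicate_peaks, threshold = 0.2,
                            min_replicates = 2,
                            aggregation = c("any_pair", "all_pairs", "group")) {
  aggregation <- match.arg(aggregation)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    abort("threshold must be in (0, 1]")
  pk <- as_replicate_peaks(replicate_peaks)
  if (dplyr::n_distinct(pk$replicate_id) < 2)
    abort("consensus requires peaks from at least 2 replicates")
  n <- nrow(pk)

  # overlap graph (cross-replicate edges, >= 1 bp) via union-find
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (idx in split(seq_len(n), paste(pk$chrom, pk$strand))) {
    if (length(idx) < 2) next
    if (length(idx) <= 256) {
      cmb <- utils::combn(length(idx), 2)
      q <- cmb[1, ]; s <- cmb[2, ]
      ov <- pmin(pk$end[idx[q]], pk$end[idx[s]]) -
        pmax(pk$start[idx[q]], pk$start[idx[s]])
      keep <- ov > 0 & pk$replicate_id[idx[q]] != pk$replicate_id[idx[s]]
    } else {
      ir <- IRanges::IRanges(start = pk$start[idx] + 1L, end = pk$end[idx])
      h <- IRanges::findOverlaps(ir, ir, minoverlap = 1L)
      q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
      keep <- q < s & pk$replicate_id[idx[q]] != pk$replicate_id[idx[s]]
    }
    for (e in which(keep)) {
      ra <- find_root(idx[q[e]]); rb <- find_root(idx[s[e]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(n), find_root, integer(1))

  rows <- list()
  for (cidx in split(seq_len(n), comp)) {
    reps <- pk$replicate_id[cidx]
    if (length(unique(reps)) < min_replicates) next
    cmb <- utils::combn(length(cidx), 2)
    i1 <- cidx[cmb[1, ]]; i2 <- cidx[cmb[2, ]]
    cross <- pk$replicate_id[i1] != pk$replicate_id[i2]
    i1 <- i1[cross]; i2 <- i2[cross]
    # components are single-chrom/strand, so interval arithmetic suffices
    inter <- pmax(0, pmin(pk$end[i1], pk$end[i2]) -
                    pmax(pk$start[i1], pk$start[i2]))
    jac <- inter / ((pk$end[i1] - pk$start[i1]) +
                      (pk$end[i2] - pk$start[i2]) - inter)
    ok <- switch(aggregation,
      any_pair = any(jac >= threshold),
      all_pairs = all(jac >= threshold),
      group = group_jaccard(pk[cidx, ]) >= threshold)
    if (!ok) next
    rows[[length(rows) + 1]] <- list(
      chrom = pk$chrom[cidx[1]], start = min(pk$start[cidx]),
      end = max(pk$end[cidx]), strand = pk$strand[cidx[1]],
      n_replicates = length(unique(reps)), n_members = length(cidx),
      max_jaccard = max(jac),
      members = pk[cidx, ],
      pair_jaccard = tibble::new_tibble(list(
        replicate_1 = pk$replicate_id[i1], peak_1 = pk$peak_id[i1],
        replicate_2 = pk$replicate_id[i2], peak_2 = pk$peak_id[i2],
        jaccard = jac), nrow = length(i1)))
  }
  res <- tibble::new_tibble(list(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    n_replicates = vapply(rows, `[[`, numeric(1), "n_replicates"),
    n_members = vapply(rows, `[[`, numeric(1), "n_members"),
    max_jaccard = vapply(rows, `[[`, numeric(1), "max_jaccard"),
    members = lapply(rows, `[[`, "members"),
    pair_jaccard = lapply(rows, `[[`, "pair_jaccard")), nrow = length(rows))
  if (nrow(res) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), consensus_id = character(),
                  n_replicates = integer(), n_members = integer(),
                  max_jaccard = numeric(), threshold = numeric(),
                  members = list(), pair_jaccard = list()))
  }
  res |>
    arrange(.data$chrom, .data$strand, .data$start) |>
    mutate(consensus_id = sprintf("cons%04d", row_number()),
           threshold = threshold) |>
    select("chrom", "start", "end", "strand", "consensus_id",
           "n_replicates", "n_members", "max_jaccard", "threshold",
           "members", "pair_jaccard")
}

# group-mode Jaccard: |intersection across replicates of per-replicate
# footprints| / |union of all footprints|
group_jaccard <- function(d) {
  foot <- lapply(split(d, d$replicate_id), function(x)
    IRanges::reduce(IRanges::IRanges(start = x$start + 1L, end = x$end)))
  inter <- Reduce(IRanges::intersect, foot)
  uni <- IRanges::reduce(do.call(c, unname(foot)))
  sum(IRanges::width(inter)) / sum(IRanges::width(uni))
}

#' Annotate peaks with transcript regions
#'
#' Labels each peak with the transcript region it maximally overlaps
#' (3UTR > 5UTR > CDS > intron > ncRNA precedence on ties); peaks overlapping
#' no region are `intergenic`.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, `strand`).
#' @param regions Tibble of region spans with columns `chrom`, `start`,
#'   `end`, `region` (labels among 5UTR, CDS, 3UTR, intron, ncRNA) and
#'   optionally `strand` (matched when present).
#' @return `peaks` with a `region` column added.
#' @seealso [region_fractions()] for the per-label summary.
#' @export
annotate_regions <- function(peaks, regions) {
  precedence <- c("3UTR", "5UTR", "CDS", "intron", "ncRNA")
  bad <- setdiff(unique(regions$region), precedence)
  if (length(bad)) abort(paste0("unknown region label(s): ",
                                paste(bad, collapse = ", ")))
  peaks$region <- assign_max_overlap(
    peaks, regions, label_col = "region",
    tie_order = precedence, no_hit = "intergenic")
  peaks
}

#' Fraction of peaks per region label
#'
#' @param peaks Peak tibble with a `region` column (see [annotate_regions()]).
#' @return Tibble `region`, `n`, `fraction` (fractions sum to 1).
#' @export
region_fractions <- function(peaks) {
  peaks |>
    dplyr::count(.data$region, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(dplyr::desc(.data$fraction))
}

# max-overlap assignment of query intervals to labelled subject spans.
# tie_order: preferred label order on equal overlap; NULL = lexicographic.
assign_max_overlap <- function(query, subject, label_col,
                               tie_order = NULL, no_hit = NA_character_) {
  out <- rep(no_hit, nrow(query))
  use_strand <- "strand" %in% names(query) && "strand" %in% names(subject)
  qkey <- if (use_strand) paste(query$chrom, query$strand)
          else query$chrom
  skey <- if (use_strand) paste(subject$chrom, subject$strand)
          else subject$chrom
  for (k in unique(qkey)) {
    qi <- which(qkey == k); si <- which(skey == k)
    if (!length(si)) next
    qr <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    sr <- IRanges::IRanges(subject$start[si] + 1L, subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      qr[S4Vectors::queryHits(hits)], sr[S4Vectors::subjectHits(hits)]))
    lab <- subject[[label_col]][si[S4Vectors::subjectHits(hits)]]
    rank <- if (is.null(tie_order)) xtfrm(lab) else match(lab, tie_order)
    h <- tibble(q = S4Vectors::queryHits(hits), ov = ov, lab = lab,
                rank = rank) |>
      arrange(.data$q, dplyr::desc(.data$ov), .data$rank) |>
      distinct(.data$q, .keep_all = TRUE)
    out[qi[h$q]] <- h$lab
  }
  out
}
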