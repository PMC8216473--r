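#' Additive duplex energy model
#'
#' Parameters of the seed-anchored hybridization engine: per-pair stacking-free
#' base-pair energies (kcal/mol, negative), per-nucleotide bulge and
#' internal-loop penalties (positive), a duplex initiation penalty, and the
#' maximum gap allowed between consecutive base pairs on either strand.
#' The model is deliberately simple and additive so that its optimum is
#' exactly checkable by enumeration; the per-duplex binding score normalizes
#' energies by the dataset minimum, so only the ranking matters downstream.
#'
#' @param gc,au,gu Pair energies for G:C, A:U and G:U (wobble) pairs.
#' @param bulge_per_nt,loop_per_nt Penalty per bulged / internal-loop nt.
#' @param init_penalty Duplex initiation penalty.
#' @param max_gap Maximum unpaired stretch between consecutive pairs, per
#'   strand.
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(gc = -3, au = -2, gu = -1, bulge_per_nt = 3,
                         loop_per_nt = 2, init_penalty = 4, max_gap = 10) {
  stopifnot(gc < 0, au < 0, gu < 0, bulge_per_nt > 0, loop_per_nt > 0,
            init_penalty > 0, max_gap >= 0)
  structure(list(gc = gc, au = au, gu = gu, bulge_per_nt = bulge_per_nt,
                 loop_per_nt = loop_per_nt, init_penalty = init_penalty,
                 max_gap = as.integer(max_gap)),
            class = "energy_model")
}

# seed window (positions 2 .. 1+seed_len, 1-based on the miRNA)
seed_sequence <- function(mirna_seq, seed_len = 7, seed_start = 2) {
  substr(mirna_seq, seed_start, seed_start + seed_len - 1)
}

#' Find seed matches of a miRNA on a target sequence
#'
#' Reports every target position (1-based start, overlapping matches
#' included) carrying the exact Watson-Crick reverse complement of the miRNA
#' seed, i.e. miRNA positions 2..7 (6mer), 2..8 (7mer) or 2..9 (8mer).
#'
#' @param mirna_seq miRNA sequence, RNA alphabet, 5' to 3'.
#' @param target Target sequence (RNA or DNA alphabet).
#' @param match_types Subset of `c("6mer", "7mer", "8mer")`.
#' @return Tibble `anchor` (1-based target start of the match), `match_type`,
#'   `match_len`.
#' @export
find_seed_matches <- function(mirna_seq, target,
                              match_types = "7mer") {
  stopifnot(length(match_types) > 0,
            all(match_types %in% c("6mer", "7mer", "8mer")))
  target_dna <- gsub("U", "T", toupper(target), fixed = TRUE)
  out <- purrr::map(match_types, function(mt) {
    k <- c(`6mer` = 6L, `7mer` = 7L, `8mer` = 8L)[[mt]]
    if (nchar(mirna_seq) < 1 + k) return(tibble())
    pat <- gsub("U", "T", rna_revcomp(seed_sequence(mirna_seq, k)),
                fixed = TRUE)
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(target_dna))
    tibble(anchor = Biostrings::start(m), match_type = mt, match_len = k)
  })
  bind_rows(out) |> arrange(.data$anchor, .data$match_len)
}

#' Hybridize a miRNA onto a target window at a seed anchor
#'
#' Computes the minimum-energy antiparallel co-fold of the miRNA and the
#' target window under the additive [energy_model()], with the seed block
#' (miRNA positions `seed_start .. seed_start+seed_len-1`, Watson-Crick only)
#' forced onto the anchor. G:U wobble pairs are allowed in the extensions
#' but not in the seed. Returns `NULL` when the anchor is not a Watson-Crick
#' seed match or the optimal energy is non-negative.
#'
#' @param mirna_seq miRNA sequence (RNA, 5' to 3').
#' @param target_window Target window sequence (RNA or DNA alphabet, 5' to
#'   3').
#' @param anchor 1-based start, within the window, of the seed match (from
#'   [find_seed_matches()] on the window).
#' @param model An [energy_model()].
#' @param mirna_name Name recorded in the output.
#' @param seed_len,seed_start Seed window definition (defaults: positions
#'   2-8).
#' @return A one-row heteroduplex tibble: `mirna`, `len_mirna`, `site_start`,
#'   `site_end` (0-based half-open, window coordinates), `mfe`,
#'   `n_paired_nt`, `n_paired_nt_seed`, `n_bulges_seed`, `motif_len`,
#'   `n_paired_nt_motif`, `seed_len`, and a `pairing_mask` list-column
#'   (logical over miRNA positions). Or `NULL`.
#' @export
hybridize <- function(mirna_seq, target_window, anchor,
                      model = energy_model(), mirna_name = "mir",
                      seed_len = 7, seed_start = 2) {
  mir <- toupper(mirna_seq)
  win <- gsub("T", "U", toupper(target_window), fixed = TRUE)
  if (anchor < 1 || anchor + seed_len - 1 > nchar(win))
    abort("anchor outside the target window")
  r <- duplex_dp_cpp(mir, win, as.integer(anchor), as.integer(seed_start),
                     as.integer(seed_len), model$gc, model$au, model$gu,
                     model$bulge_per_nt, model$loop_per_nt,
                     model$init_penalty, model$max_gap)
  if (!r$ok || r$mfe >= 0) return(NULL)
  M <- nchar(mir)
  mask <- rep(FALSE, M)
  mask[r$mir_pos] <- TRUE
  seed_idx <- seq(seed_start, seed_start + seed_len - 1)
  # forced contiguous seed block: bulge count inside the seed is structural
  ord <- order(r$mir_pos)
  mp <- r$mir_pos[ord]; wp <- r$win_pos[ord]
  in_seed <- mp %in% seed_idx
  seed_bulges <- sum(abs(diff(mp[in_seed])) - 1) +
    sum(abs(diff(wp[in_seed])) - 1)
  # motif: longest contiguous paired stretch on the target
  wps <- sort(r$win_pos)
  runs <- split(wps, cumsum(c(1, diff(wps) != 1)))
  motif_len <- max(lengths(runs))
  tibble(mirna = mirna_name, len_mirna = M,
         site_start = min(r$win_pos) - 1L, site_end = max(r$win_pos),
         mfe = r$mfe, n_paired_nt = length(r$mir_pos),
         n_paired_nt_seed = sum(in_seed), n_bulges_seed = seed_bulges,
         motif_len = motif_len, n_paired_nt_motif = motif_len,
         seed_len = seed_len, pairing_mask = list(mask))
}

#' Predict miRNA binding sites on peak sequences
#'
#' For each miRNA and each peak sequence, scans for seed matches and
#' hybridizes every anchor (window: anchor +/- miRNA length + 15 nt, clipped
#' to the peak). Site coordinates are reported peak-locally (0-based
#' half-open) and, when the peaks carry `start`, genomically.
#'
#' @param peak_seqs Tibble with `peak_id` and `sequence` (peak-level target
#'   sequences, DNA or RNA alphabet); optional `chrom`, `start`, `strand`
#'   columns are propagated and used to compute genomic site coordinates.
#' @param mirnas Tibble with `id` and `sequence` (RNA) as from
#'   [read_fasta()].
#' @param model An [energy_model()].
#' @param match_types Seed match types to scan, see [find_seed_matches()].
#' @param seed_len Seed length used for the duplex feature counts.
#' @return A heteroduplex tibble, one row per (peak, miRNA, anchor) duplex,
#'   with `peak_id`, the [hybridize()] columns, and `anchor`.
#' @export
predict_binding_sites <- function(peak_seqs, mirnas, model = energy_model(),
                                  match_types = "7mer", seed_len = 7) {
  stopifnot(all(c("peak_id", "sequence") %in% names(peak_seqs)),
            all(c("id", "sequence") %in% names(mirnas)))
  seqs_dna <- gsub("U", "T", toupper(peak_seqs$sequence), fixed = TRUE)
  subject <- Biostrings::DNAStringSet(seqs_dna)
  names(subject) <- peak_seqs$peak_id
  res <- vector("list", nrow(mirnas) * length(match_types))
  ri <- 0
  for (mi in seq_len(nrow(mirnas))) {
    mir <- mirnas$sequence[mi]
    for (mt in match_types) {
      k <- c(`6mer` = 6L, `7mer` = 7L, `8mer` = 8L)[[mt]]
      if (nchar(mir) < 1 + k) next
      pat <- gsub("U", "T", rna_revcomp(seed_sequence(mir, k)), fixed = TRUE)
      hits <- Biostrings::vmatchPattern(pat, subject)
      nh <- S4Vectors::elementNROWS(hits)
      if (sum(nh) == 0) next
      idx <- rep(seq_along(nh), nh)
      anchors <- unlist(lapply(hits, Biostrings::start), use.names = FALSE)
      rows <- purrr::map2(idx, anchors, function(pi, a) {
        L <- nchar(seqs_dna[pi])
        w0 <- max(1L, a - (nchar(mir) + 15L))
        w1 <- min(L, a + k - 1L + nchar(mir) + 15L)
        d <- hybridize(mir, substr(seqs_dna[pi], w0, w1), a - w0 + 1L,
                       model = model, mirna_name = mirnas$id[mi],
                       seed_len = seed_len)
        if (is.null(d)) return(NULL)
        d$site_start <- d$site_start + w0 - 1L
        d$site_end <- d$site_end + w0 - 1L
        d$anchor <- a
        d$peak_id <- peak_seqs$peak_id[pi]
        d
      })
      ri <- ri + 1
      res[[ri]] <- bind_rows(rows)
    }
  }
  out <- bind_rows(res[seq_len(ri)])
  if (nrow(out) == 0) {
    return(tibble(peak_id = character(), mirna = character(),
                  len_mirna = integer(), site_start = integer(),
                  site_end = integer(), mfe = numeric(),
                  n_paired_nt = integer(), n_paired_nt_seed = integer(),
                  n_bulges_seed = integer(), motif_len = integer(),
                  n_paired_nt_motif = integer(), seed_len = integer(),
                  anchor = integer(), pairing_mask = list()))
  }
  out <- select(out, "peak_id", dplyr::everything())
  # one duplex per (peak, miRNA, anchor): keep best energy across match types
  out |>
    group_by(.data$peak_id, .data$mirna, .data$anchor) |>
    dplyr::slice_min(.data$mfe, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$peak_id, .data$site_start, .data$mirna)
}

#' Mononucleotide shuffles of a miRNA sequence
#'
#' Uniform random permutations of the sequence letters; composition and
#' length are preserved. Used to build the negative-control miRNA sets of
#' the specificity protocol.
#'
#' @param mirna_seq miRNA sequence.
#' @param n_shuffles Number of shuffles.
#' @param seed RNG seed; output is deterministic given the seed.
#' @param name Base name; shuffles are suffixed `_shuf1`, `_shuf2`, ...
#' @return Tibble `id`, `sequence` with `n_shuffles` rows.
#' @export
shuffle_mirna <- function(mirna_seq, n_shuffles = 5, seed = 1, name = "mir") {
  stopifnot(n_shuffles >= 1)
  letters_ <- strsplit(mirna_seq, "")[[1]]
  seqs <- withr::with_seed(seed, replicate(
    n_shuffles, paste(sample(letters_), collapse = "")))
  tibble(id = sprintf("%s_shuf%d", name, seq_len(n_shuffles)),
         sequence = seqs)
}

#' Site-prediction parameter tiers by dataset size
#'
#' Returns the heuristic motif-discovery parameter tier for a dataset with
#' `n_peaks` peaks: the Homer motif `-log10(p)` cutoff, the Homer
#' motif-to-miRNA match score, and the FIMO score threshold. Tier boundaries
#' are half-open: `[0,100)`, `[100,1000)`, `[1000,2000)`, `[2000,Inf)`.
#'
#' @param n_peaks Number of peaks (non-negative).
#' @return Tibble `motif_log10p`, `match_score`, `fimo_score` (one row).
#' @export
select_mirbshunter_params <- function(n_peaks) {
  if (!is.numeric(n_peaks) || n_peaks < 0) abort("n_peaks must be >= 0")
  tiers <- tibble(
    motif_log10p = c(3L, 5L, 7L, 12L),
    match_score = c(0.25, 0.35, 0.35, 0.35),
    fimo_score = c(0.0008, 0.0008, 0.0002, 0.0002))
  tiers[findInterval(n_peaks, c(0, 100, 1000, 2000)), ]
}

#' Import externally computed binding-site predictions
#'
#' Reads a TSV of predicted sites in one of three dialects. The
#' `mirbshunter` dialect carries the full heteroduplex feature set; the
#' `miranda` (`relative_score` column) and `targetscan` (`context_score`
#' column) dialects carry a single score used directly as the coalition
#' contribution in [mu_score()].
#'
#' @param path Path to the TSV (header required).
#' @param dialect One of `"mirbshunter"`, `"miranda"`, `"targetscan"`.
#' @return A site tibble with `peak_id`, `site_start`, `site_end`, `mirna`
#'   and either the heteroduplex feature columns or `site_score`.
#' @export
import_external_sites <- function(path,
                                  dialect = c("mirbshunter", "miranda",
                                              "targetscan")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  required <- switch(dialect,
    mirbshunter = c("peak_id", "site_start", "site_end", "mirna", "mfe",
                    "len_mirna", "n_paired_nt", "n_paired_nt_seed",
                    "n_bulges_seed", "motif_len", "n_paired_nt_motif",
                    "seed_len"),
    miranda = c("peak_id", "site_start", "site_end", "mirna",
                "relative_score"),
    targetscan = c("peak_id", "site_start", "site_end", "mirna",
                   "context_score"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(paste0("missing required column(s) for dialect '", dialect, "': ",
                 paste(missing, collapse = ", ")))
  df <- as_tibble(df[required])
  if (dialect == "miranda") df <- rename(df, site_score = "relative_score")
  if (dialect == "targetscan") df <- rename(df, site_score = "context_score")
  df
}
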