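#' Configuration for the synthetic CLIP-seq dataset generator
#'
#' Defines the study conditions the simulator emulates: replicate peak sets
#' with controlled pairwise overlap, peaks carrying 0-k embedded
#' miRNA-binding sites of known structure, and gene expression fold changes
#' whose repression grows linearly with the true site count plus Gaussian
#' noise. All randomness is driven by `seed`; the same configuration always
#' yields byte-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_replicates Number of CLIP replicates.
#' @param n_true_peaks Number of reproducible (planted) peaks, one per
#'   target-gene 3'UTR.
#' @param peak_width Width (nt) of every replicate peak interval.
#' @param overlap_j Target Jaccard index for adjacent replicate pairs of
#'   each planted peak; recycled across peaks. Replicate intervals are laid
#'   out on a shift chain, so the full intended pairwise Jaccard matrix
#'   (recorded in the ground truth) follows from the chain geometry.
#' @param n_decoys_per_replicate Unreproducible peaks private to each
#'   replicate, planted in distinct background-gene 3'UTRs.
#' @param n_mirnas,mirna_len miRNA set size and length; miRNAs are built in
#'   pairs whose seeds are 1-nt shifts of a common 8-nt target word, so one
#'   embedded word can be bound by both (a promiscuous site).
#' @param sites_per_peak_prob Probabilities of 1, 2, ... binding sites per
#'   planted peak (must sum to 1).
#' @param promiscuity_prob Probability that an embedded site is promiscuous
#'   (bound by a miRNA pair).
#' @param ext_prob Probability that a site also carries 6 nt of
#'   complementarity to miRNA positions 10-15 (3'-extended pairing),
#'   lowering its duplex energy.
#' @param site_spacing_nt Center-to-center spacing of multiple sites within
#'   a peak.
#' @param site_jitter Maximum absolute shift (nt, uniform integer) of each
#'   peak's site block relative to the peak center.
#' @param repression_slope Log2 fold-change units of repression per true
#'   binding site.
#' @param noise_sd Gaussian noise SD added to every gene's log2 fold
#'   change.
#' @param n_background_genes Genes without planted peaks (pure noise).
#' @param utr5_len,cds_len,utr3_len,intergenic_len Gene-cassette geometry
#'   (nt).
#' @param n_chroms Number of chromosomes genes are tiled over.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 17, n_replicates = 3,
                             n_true_peaks = 2000, peak_width = 100,
                             overlap_j = c(0.25, 0.5, 0.9),
                             n_decoys_per_replicate = 50, n_mirnas = 25,
                             mirna_len = 22,
                             sites_per_peak_prob = c(0.4, 0.3, 0.2, 0.1),
                             promiscuity_prob = 0.15, ext_prob = 0.5,
                             site_spacing_nt = 18, site_jitter = 5,
                             repression_slope = 0.15, noise_sd = 0.4,
                             n_background_genes = 2000, utr5_len = 100,
                             cds_len = 200, utr3_len = 250,
                             intergenic_len = 60, n_chroms = 4) {
  stopifnot(abs(sum(sites_per_peak_prob) - 1) < 1e-9,
            all(overlap_j > 0), all(overlap_j <= 1), noise_sd >= 0,
            n_mirnas >= 2, utr3_len >= peak_width,
            n_background_genes >= n_replicates * n_decoys_per_replicate)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Gene and region layout of the synthetic genome
#'
#' Tiles `n_true_peaks + n_background_genes` plus-strand gene cassettes
#' (5'UTR, CDS, 3'UTR, intergenic gap) over the configured chromosomes and
#' assigns which genes carry a planted peak.
#'
#' @param config A [synthetic_config()].
#' @return A list: `genes` (tibble `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `utr3_start`, `utr3_end`, `is_true`), `regions` (region-span
#'   tibble usable by [annotate_regions()]), `chrom_lengths`.
#' @export
synthetic_layout <- function(config) {
  n_genes <- config$n_true_peaks + config$n_background_genes
  cassette <- config$utr5_len + config$cds_len + config$utr3_len +
    config$intergenic_len
  per_chrom <- ceiling(n_genes / config$n_chroms)
  gi <- seq_len(n_genes) - 1L
  chrom_idx <- gi %/% per_chrom + 1L
  within <- gi %% per_chrom
  start <- within * cassette
  genes <- tibble(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    chrom = paste0("chr", chrom_idx),
    start = start, end = start + cassette - config$intergenic_len,
    strand = "+",
    utr3_start = start + config$utr5_len + config$cds_len,
    utr3_end = start + config$utr5_len + config$cds_len + config$utr3_len)
  genes$is_true <- FALSE
  genes$is_true[withr::with_seed(config$seed + 1L,
    sample(n_genes, config$n_true_peaks))] <- TRUE
  regions <- bind_rows(
    genes |> mutate(start = .data$start,
                    end = .data$start + config$utr5_len, region = "5UTR"),
    genes |> mutate(start = .data$start + config$utr5_len,
                    end = .data$start + config$utr5_len + config$cds_len,
                    region = "CDS"),
    genes |> mutate(start = .data$utr3_start, end = .data$utr3_end,
                    region = "3UTR")) |>
    select("chrom", "start", "end", "strand", "region")
  chrom_lengths <- genes |> group_by(.data$chrom) |>
    summarise(length = max(.data$end) + config$intergenic_len,
              .groups = "drop")
  list(genes = genes, regions = regions,
       chrom_lengths = setNames(chrom_lengths$length, chrom_lengths$chrom))
}

# chain geometry for one planted peak: integer replicate offsets whose
# adjacent-pair Jaccard matches j (after integer rounding of the overlap)
chain_offsets <- function(j, width, n_replicates) {
  o <- round(2 * width * j / (1 + j))
  s <- width - o
  off <- (seq_len(n_replicates) - 1L) * s
  off - floor(max(off) / 2)
}

#' Simulate replicate peak sets with controlled overlap
#'
#' Plants one reproducible peak per true gene's 3'UTR: every replicate gets
#' an interval of `peak_width` nt, shifted along a chain so the realized
#' Jaccard index of adjacent replicate pairs equals the configured target
#' (within integer rounding, < 0.02). Farther pairs have the smaller Jaccard
#' the chain geometry implies; the full intended matrix is recorded in the
#' ground truth. Decoy peaks private to single replicates are planted in
#' background-gene 3'UTRs.
#'
#' @param config A [synthetic_config()].
#' @param layout A [synthetic_layout()] (recomputed from `config` when
#'   omitted).
#' @return A list: `peaks` (tibble with `replicate_id`, ready for
#'   [consensus_peaks()]), `truth_peaks` (tibble `true_peak_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `target_j`), `truth_pairs`
#'   (`true_peak_id`, `rep_1`, `rep_2`, `intended_j`, `realized_j`).
#' @export
simulate_replicate_peaks <- function(config, layout = synthetic_layout(config)) {
  true_genes <- filter(layout$genes, .data$is_true)
  n <- nrow(true_genes)
  w <- config$peak_width
  jt <- rep_len(config$overlap_j, n)
  center <- floor((true_genes$utr3_start + true_genes$utr3_end) / 2)
  base_start <- center - floor(w / 2)
  truth_peaks <- tibble(
    true_peak_id = sprintf("tp%05d", seq_len(n)),
    gene_id = true_genes$gene_id, chrom = true_genes$chrom,
    start = base_start, end = base_start + w, strand = "+", target_j = jt)

  reps <- sprintf("rep%d", seq_len(config$n_replicates))
  pk <- purrr::map(seq_len(n), function(i) {
    off <- chain_offsets(jt[i], w, config$n_replicates)
    tibble(replicate_id = reps, chrom = truth_peaks$chrom[i],
           start = base_start[i] + off, end = base_start[i] + off + w,
           strand = "+", true_peak_id = truth_peaks$true_peak_id[i])
  }) |> bind_rows()

  pairs <- purrr::map(seq_len(n), function(i) {
    off <- chain_offsets(jt[i], w, config$n_replicates)
    cmb <- t(utils::combn(config$n_replicates, 2))
    ov <- pmax(0, w - abs(off[cmb[, 1]] - off[cmb[, 2]]))
    tibble(true_peak_id = truth_peaks$true_peak_id[i],
           rep_1 = reps[cmb[, 1]], rep_2 = reps[cmb[, 2]],
           intended_j = ov / (2 * w - ov))
  }) |> bind_rows()
  realized <- pk |>
    inner_join(pk, by = c("true_peak_id", "chrom", "strand"),
               relationship = "many-to-many") |>
    filter(.data$replicate_id.x < .data$replicate_id.y)
  pairs$realized_j <- jaccard_index(
    tibble(chrom = realized$chrom, start = realized$start.x,
           end = realized$end.x),
    tibble(chrom = realized$chrom, start = realized$start.y,
           end = realized$end.y))

  # decoys: single-replicate peaks in distinct background-gene 3'UTRs
  bg <- filter(layout$genes, !.data$is_true)
  n_dec <- config$n_decoys_per_replicate * config$n_replicates
  decoys <- if (n_dec > 0) {
    idx <- withr::with_seed(config$seed + 2L, sample(nrow(bg), n_dec))
    dg <- bg[idx, ]
    ds <- floor((dg$utr3_start + dg$utr3_end) / 2) - floor(w / 2)
    tibble(replicate_id = rep(reps, each = config$n_decoys_per_replicate),
           chrom = dg$chrom, start = ds, end = ds + w, strand = "+",
           true_peak_id = NA_character_)
  } else NULL
  peaks <- bind_rows(pk, decoys) |>
    arrange(.data$replicate_id, .data$chrom, .data$start) |>
    group_by(.data$replicate_id) |>
    mutate(peak_id = sprintf("%s_pk%05d", .data$replicate_id[1],
                             row_number()),
           support = 10L) |>
    ungroup()
  list(peaks = peaks, truth_peaks = truth_peaks, truth_pairs = pairs)
}

# random RNA/DNA string helpers
random_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# build the miRNA set: odd/even pairs share a planted 8-nt target word
# (pair member seeds are 1-nt shifts), enabling promiscuous sites
synthetic_mirnas <- function(config) {
  withr::with_seed(config$seed + 3L, {
    ab <- c("A", "C", "G", "U")
    seqs <- vapply(seq_len(config$n_mirnas), function(i)
      random_seq(config$mirna_len, ab), "")
    words <- character(floor(config$n_mirnas / 2))
    for (k in seq_along(words)) {
      a <- 2 * k - 1; b <- 2 * k
      w <- paste0(rna_revcomp(substr(seqs[a], 2, 8)), sample(ab, 1))
      seed_b <- rna_revcomp(substr(w, 2, 8))
      substr(seqs[b], 2, 8) <- seed_b
      words[k] <- w
    }
    list(mirnas = tibble(id = sprintf("mir%02d", seq_len(config$n_mirnas)),
                         sequence = seqs),
         pair_words = words)
  })
}

#' Simulate target sequences with embedded miRNA-binding sites
#'
#' Generates an i.i.d.-uniform random genome over the layout, then embeds
#' exact seed-match words inside the planted peak footprints: each planted
#' peak gets `m` sites (drawn from `sites_per_peak_prob`) spaced
#' `site_spacing_nt` apart around the peak center. A promiscuous site embeds
#' the 8-nt word matching both members of a miRNA pair; an extended site
#' also embeds 6 nt complementary to miRNA positions 10-15 just 5' of the
#' seed match.
#'
#' @param config A [synthetic_config()].
#' @param layout A [synthetic_layout()].
#' @param truth_peaks Planted-peak truth from [simulate_replicate_peaks()].
#' @param mirnas Optional miRNA tibble (`id`, `sequence`); generated from
#'   the config when omitted (required for promiscuous pairs).
#' @return A list: `genome` (named chromosome strings, DNA), `mirnas`,
#'   `truth_sites` (tibble `true_peak_id`, `gene_id`, `site_index`,
#'   `mirnas` comma-joined, `n_mirnas_true`, `promiscuous`, `extended`,
#'   `anchor_start` 0-based genomic), `truth_m` (`true_peak_id`, `gene_id`,
#'   `m_true`).
#' @export
simulate_targets_and_sites <- function(config, layout, truth_peaks,
                                       mirnas = NULL) {
  gen <- if (is.null(mirnas)) synthetic_mirnas(config)
         else list(mirnas = mirnas, pair_words = character())
  withr::with_seed(config$seed + 4L, {
    genome <- lapply(layout$chrom_lengths, function(L)
      sample(c("A", "C", "G", "T"), L, replace = TRUE))
    m_true <- sample(seq_along(config$sites_per_peak_prob),
                     nrow(truth_peaks), replace = TRUE,
                     prob = config$sites_per_peak_prob)
    sites <- vector("list", nrow(truth_peaks))
    for (i in seq_len(nrow(truth_peaks))) {
      m <- m_true[i]
      w <- config$peak_width
      center <- truth_peaks$start[i] + floor(w / 2)
      jit <- sample(-config$site_jitter:config$site_jitter, 1)
      offsets <- (seq_len(m) - (m + 1) / 2) * config$site_spacing_nt
      centers <- round(center + offsets + jit)
      half_span <- max(abs(offsets)) + config$site_jitter + 12
      if (half_span > w / 2)
        abort("peak too short for the requested number of sites")
      rows <- vector("list", m)
      for (si in seq_len(m)) {
        prom <- length(gen$pair_words) > 0 &&
          runif(1) < config$promiscuity_prob
        ext <- runif(1) < config$ext_prob
        if (prom) {
          pair <- sample(length(gen$pair_words), 1)
          word <- gsub("U", "T", gen$pair_words[pair], fixed = TRUE)
          mir_ids <- gen$mirnas$id[c(2 * pair - 1, 2 * pair)]
          mir_seq <- gen$mirnas$sequence[2 * pair - 1]
        } else {
          mi <- sample(nrow(gen$mirnas), 1)
          word <- gsub("U", "T",
                       rna_revcomp(substr(gen$mirnas$sequence[mi], 2, 8)),
                       fixed = TRUE)
          mir_ids <- gen$mirnas$id[mi]
          mir_seq <- gen$mirnas$sequence[mi]
        }
        a0 <- centers[si] - 3L  # 0-based genomic start of the word
        chrom <- truth_peaks$chrom[i]
        genome[[chrom]][(a0 + 1):(a0 + nchar(word))] <-
          strsplit(word, "")[[1]]
        if (ext) {
          wext <- gsub("U", "T", rna_revcomp(substr(mir_seq, 10, 15)),
                       fixed = TRUE)
          genome[[chrom]][(a0 - 7):(a0 - 2)] <- strsplit(wext, "")[[1]]
        }
        rows[[si]] <- tibble(
          true_peak_id = truth_peaks$true_peak_id[i],
          gene_id = truth_peaks$gene_id[i], site_index = si,
          mirnas = paste(mir_ids, collapse = ","),
          n_mirnas_true = length(mir_ids), promiscuous = prom,
          extended = ext, anchor_start = a0)
      }
      sites[[i]] <- bind_rows(rows)
    }
    truth_sites <- bind_rows(sites)
  })
  list(genome = vapply(genome, paste, "", collapse = ""),
       mirnas = gen$mirnas, truth_sites = truth_sites,
       truth_m = tibble(true_peak_id = truth_peaks$true_peak_id,
                        gene_id = truth_peaks$gene_id, m_true = m_true))
}

#' Simulate gene expression fold changes from the site ground truth
#'
#' Every gene's log2 fold change is `-repression_slope * m_true` plus
#' `Normal(0, noise_sd)` noise; background genes (no planted peak) get pure
#' noise. This is the weakest structure sufficient to test the monotone
#' level-repression claim: repression linear in the true site count.
#'
#' @param config A [synthetic_config()].
#' @param layout A [synthetic_layout()].
#' @param truth_m Per-peak true site counts from
#'   [simulate_targets_and_sites()].
#' @return Expression tibble `gene_id`, `log2fc`.
#' @export
simulate_expression <- function(config, layout, truth_m) {
  genes <- layout$genes
  m <- setNames(rep(0, nrow(genes)), genes$gene_id)
  m[truth_m$gene_id] <- truth_m$m_true
  withr::with_seed(config$seed + 5L, tibble(
    gene_id = genes$gene_id,
    log2fc = -config$repression_slope * unname(m) +
      rnorm(nrow(genes), 0, config$noise_sd)))
}

#' Simulate a complete synthetic CLIP-seq study
#'
#' Chains [synthetic_layout()], [simulate_replicate_peaks()],
#' [simulate_targets_and_sites()] and [simulate_expression()] into one
#' deterministic bundle with full ground truth.
#'
#' @param config A [synthetic_config()].
#' @return A list: `config`, `layout`, `peaks`, `truth_peaks`,
#'   `truth_pairs`, `genome`, `mirnas`, `truth_sites`, `truth_m`,
#'   `expression`.
#' @export
simulate_clip_dataset <- function(config = synthetic_config()) {
  layout <- synthetic_layout(config)
  rp <- simulate_replicate_peaks(config, layout)
  ts <- simulate_targets_and_sites(config, layout, rp$truth_peaks)
  expr <- simulate_expression(config, layout, ts$truth_m)
  c(list(config = config, layout = layout), rp, ts,
    list(expression = expr))
}
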