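#' Run the full analysis pipeline
#'
#' Wires the package's stages into the standard workflow — replicate peaks
#' -> Jaccard consensus -> binding-site prediction -> occupancy scoring ->
#' quartile stratification -> repression analysis -> evaluation summaries —
#' with every stage reading and writing plain on-disk artifacts (BED/TSV)
#' under `out_dir`, so runs are restartable and inspectable. Stages are
#' selected with `config$stages`; a stage whose upstream artifact is missing
#' raises a dependency error naming the stage. A `simulate` stage writes a
#' complete synthetic input set first.
#'
#' @param config A named list (or path to a YAML file) with keys among:
#'   `seed`, `stages`, `inputs` (paths: `replicate_beds`, `genome_fasta`,
#'   `mirna_fasta`, `regions_tsv`, `genes_tsv`, `expression_tsv`),
#'   `synthetic` (overrides for [synthetic_config()]), `consensus`
#'   (`threshold`, `aggregation`, `min_replicates`), `sites`
#'   (`match_types`, `seed_len`), `score` (`min_mfe_scope`),
#'   `stratify` (`n_levels`, `region`, `by`). Unknown keys are rejected.
#' @param out_dir Output directory (created).
#' @return `out_dir`, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config, out_dir = "agoclip_run") {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  known <- c("seed", "stages", "inputs", "synthetic", "consensus", "sites",
             "score", "stratify")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "agoclip_validation_error")
  seed <- config$seed %||% 17L
  stages <- config$stages %||% c("simulate", "consensus", "sites", "score",
                                 "stratify", "repression", "evaluate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inform(sprintf("run_pipeline: seed=%d stages=%s", seed,
                 paste(stages, collapse = ",")))
  yaml::write_yaml(c(config, list(resolved_seed = seed)),
                   file.path(out_dir, "config_resolved.yaml"))
  inputs <- config$inputs %||% list()
  need <- function(stage, path) {
    if (is.null(path) || !file.exists(path))
      abort(sprintf("stage '%s' is missing its upstream input (%s)",
                    stage, path %||% "unset"),
            class = "agoclip_dependency_error")
    path
  }

  if ("simulate" %in% stages) {
    sc <- do.call(synthetic_config,
                  c(list(seed = seed), config$synthetic %||% list()))
    sim <- simulate_clip_dataset(sc)
    idir <- file.path(out_dir, "inputs")
    dir.create(idir, showWarnings = FALSE)
    for (r in unique(sim$peaks$replicate_id)) {
      write_bed(sim$peaks |> filter(.data$replicate_id == r) |>
                  mutate(name = .data$peak_id, score = .data$support),
                file.path(idir, paste0(r, ".bed")))
    }
    write_fasta(tibble(id = names(sim$genome), sequence = sim$genome),
                file.path(idir, "genome.fa"))
    write_fasta(sim$mirnas, file.path(idir, "mirnas.fa"))
    readr::write_tsv(sim$layout$regions, file.path(idir, "regions.tsv"))
    readr::write_tsv(sim$layout$genes |>
                       select("chrom", "start", "end", "strand", "gene_id"),
                     file.path(idir, "genes.tsv"))
    readr::write_tsv(sim$expression, file.path(idir, "expression.tsv"))
    inputs <- list(
      replicate_beds = file.path(idir, paste0(
        unique(sim$peaks$replicate_id), ".bed")),
      genome_fasta = file.path(idir, "genome.fa"),
      mirna_fasta = file.path(idir, "mirnas.fa"),
      regions_tsv = file.path(idir, "regions.tsv"),
      genes_tsv = file.path(idir, "genes.tsv"),
      expression_tsv = file.path(idir, "expression.tsv"))
  }

  cons_path <- file.path(out_dir, "consensus.tsv")
  if ("consensus" %in% stages) {
    beds <- inputs$replicate_beds
    if (is.null(beds) || !all(file.exists(beds)))
      abort("stage 'consensus' is missing replicate peak BEDs",
            class = "agoclip_dependency_error")
    rp <- purrr::map(beds, function(b) {
      read_bed(b, min_fields = 6) |> rename(peak_id = "name")
    })
    names(rp) <- sub("\\.bed$", "", basename(beds))
    cc <- config$consensus %||% list()
    cons <- consensus_peaks(rp, threshold = cc$threshold %||% 0.2,
                            min_replicates = cc$min_replicates %||% 2,
                            aggregation = cc$aggregation %||% "any_pair")
    readr::write_tsv(cons |> select(-"members", -"pair_jaccard"), cons_path)
    readr::write_tsv(tidyr::unnest(select(cons, "consensus_id",
                                          "pair_jaccard"),
                                   "pair_jaccard"),
                     file.path(out_dir, "consensus_pairs.tsv"))
    write_bed(cons |> mutate(name = .data$consensus_id,
                             score = .data$n_members),
              file.path(out_dir, "consensus.bed"))
  }

  sites_path <- file.path(out_dir, "duplexes.tsv")
  if ("sites" %in% stages) {
    need("sites", cons_path)
    cons <- readr::read_tsv(cons_path, show_col_types = FALSE)
    genome <- read_fasta(need("sites", inputs$genome_fasta))
    mirnas <- read_fasta(need("sites", inputs$mirna_fasta), alphabet = "RNA")
    regions <- readr::read_tsv(need("sites", inputs$regions_tsv),
                               show_col_types = FALSE)
    cons <- annotate_regions(rename(cons, peak_id = "consensus_id"), regions)
    seqs <- cons |>
      mutate(sequence = purrr::pmap_chr(
        list(.data$chrom, .data$start, .data$end, .data$strand),
        function(ch, s, e, st) extract_sequence(
          genome, list(chrom = ch, start = s, end = e, strand = st))))
    sc <- config$sites %||% list()
    dup <- predict_binding_sites(seqs, mirnas,
                                 match_types = sc$match_types %||% "7mer",
                                 seed_len = sc$seed_len %||% 7)
    readr::write_tsv(
      dup |> mutate(pairing_mask = purrr::map_chr(
        .data$pairing_mask, function(m) paste(as.integer(m), collapse = ""))),
      sites_path)
    readr::write_tsv(select(cons, "peak_id", "region"),
                     file.path(out_dir, "peak_regions.tsv"))
  }

  occ_path <- file.path(out_dir, "occupancy.tsv")
  if ("score" %in% stages) {
    need("score", sites_path)
    dup <- read_duplex_tsv(sites_path)
    regions <- readr::read_tsv(
      need("score", file.path(out_dir, "peak_regions.tsv")),
      show_col_types = FALSE)
    occ <- occupancy(dup, peaks = regions,
                     min_mfe_scope = (config$score %||% list())$min_mfe_scope
                       %||% "dataset")
    readr::write_tsv(occ, occ_path)
  }

  strat_path <- file.path(out_dir, "stratified.tsv")
  if ("stratify" %in% stages) {
    need("stratify", occ_path)
    occ <- readr::read_tsv(occ_path, show_col_types = FALSE)
    st <- config$stratify %||% list()
    strat <- stratify_quartiles(occ, by = st$by %||% "delta",
                                region = st$region %||% "3UTR",
                                n_levels = st$n_levels %||% 4)
    readr::write_tsv(strat, strat_path)
  }

  if ("repression" %in% stages) {
    need("repression", strat_path)
    strat <- readr::read_tsv(strat_path, show_col_types = FALSE)
    genes <- readr::read_tsv(need("repression", inputs$genes_tsv),
                             show_col_types = FALSE)
    expr <- read_expression_table(need("repression", inputs$expression_tsv))
    cons <- readr::read_tsv(cons_path, show_col_types = FALSE) |>
      rename(peak_id = "consensus_id")
    pg <- map_peaks_to_genes(cons, genes)
    rep_ <- repression_by_level(strat, pg, expr)
    readr::write_tsv(tidy(rep_), file.path(out_dir, "repression_levels.tsv"))
    readr::write_tsv(rep_$cdf, file.path(out_dir, "repression_cdf.tsv"))
  }

  if ("evaluate" %in% stages) {
    need("evaluate", sites_path)
    dup <- read_duplex_tsv(sites_path)
    cons <- readr::read_tsv(cons_path, show_col_types = FALSE) |>
      rename(peak_id = "consensus_id")
    regions <- readr::read_tsv(
      file.path(out_dir, "peak_regions.tsv"), show_col_types = FALSE)
    cons <- left_join(cons, regions, by = "peak_id")
    sites <- group_sites(dup)
    # site coordinates are peak-local; compare against peak-local bounds
    local_peaks <- cons |> mutate(width = .data$end - .data$start,
                                  start = 0L, end = .data$width)
    prec <- precision_distances(select(sites, -"coalition"), local_peaks)
    mp <- multiplicity_promiscuity(sites)
    sens <- sensitivity_summary(cons, sites)
    readr::write_tsv(prec, file.path(out_dir, "precision.tsv"))
    readr::write_tsv(mp$per_peak, file.path(out_dir, "promiscuity.tsv"))
    readr::write_tsv(sens$summary, file.path(out_dir, "sensitivity.tsv"))
    spacing <- site_spacing(sites)
    readr::write_tsv(
      tibble(sites_per_peak = mp$sites_per_peak,
             promiscuous_fraction = mp$promiscuous_fraction,
             spearman_rho = mp$spearman_rho,
             median_site_spacing = spacing$median),
      file.path(out_dir, "evaluation_summary.tsv"))
  }
  invisible(out_dir)
}

# reload a duplex TSV written by run_pipeline (pairing_mask round-trip)
read_duplex_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pairing_mask = readr::col_character())) |>
    mutate(pairing_mask = purrr::map(
      .data$pairing_mask,
      function(s) as.logical(as.integer(strsplit(s, "")[[1]]))))
}
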