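# agoclip

Consensus peak identification and miRNA occupancy scoring for Ago2 CLIP-seq.

## The problem

CLIP-seq on Argonaute-2 captures where miRNA-loaded silencing complexes
contact the transcriptome, as "peaks" of read coverage. Two analysis
questions follow:

1. **Which peaks are reproducible?** Peak callers run per replicate disagree;
   pooling reads before calling (the *merge method*) is sensitive but admits
   irreproducible peaks. `agoclip` implements a Jaccard-index consensus:
   peaks are called per replicate, peaks from different replicates that
   overlap are grouped, and a group is kept as a consensus peak when the
   Jaccard index *J* = |intersection| / |union| of a cross-replicate peak
   pair reaches a threshold (conventionally *J* ≥ 0.2, 0.4 or 0.8, referred
   to as J20/J40/J80). The consensus footprint is the union of the member
   peaks. Lowering the threshold can only grow the consensus set, so
   J80 ⊆ J40 ⊆ J20.

2. **How occupied is each peak?** A peak may hold several miRNA-binding
   sites, and one site may be bound by several miRNAs (a *promiscuous*
   site). `agoclip` scores each peak's *degree of occupancy* with a
   cooperative (game-theoretic) model in which each binding site is a player
   and the miRNAs hitting it form its coalition:

   - per heteroduplex (one miRNA paired to one site):

     β = MFE/min(MFE) + N_paired/len_miRNA + N_paired_seed/len_seed
         + N_paired_motif/len_motif + (len_seed − N_bulges_seed)/len_seed

     where MFE is the duplex minimum free energy and min(MFE) the most
     negative energy in the dataset, so every term lies in (0, 1] and
     β ≤ 5;
   - per binding site: μ = ln Σ β over the site's coalition, so a site
     shared by *k* miRNAs gains only ln *k*;
   - per peak: Δ = Σ μ over the peak's sites.

   Peaks (conventionally 3'UTR peaks) are stratified into quartile levels of
   Δ, and each level's genes are tested for repression against the all-gene
   background of a log2 fold-change table with the two-sample
   Kolmogorov–Smirnov test. Higher occupancy levels are expected to show
   stronger repression (left-shifted CDFs).

Duplex energies come from a seed-anchored dynamic program over an explicit
additive energy model (G:C −3, A:U −2, G:U −1 kcal/mol per pair; bulge
+3/nt, internal loop +2/nt, initiation +4), chosen so its optimum is exactly
verifiable by enumeration; β normalizes energies by min(MFE), so only the
ranking matters. Externally predicted sites (miRanda relative scores,
TargetScan context scores) can be imported and used in place of β.

A seeded synthetic-data generator (`simulate_clip_dataset()`) produces
replicate peak sets with controlled pairwise overlap, target sequences with
embedded seed matches (including promiscuous and 3'-extended sites), and
expression tables whose repression grows with the true site count — so every
stage is testable with ground truth and no external data.

## Worked example

```r
library(agoclip)
library(dplyr)

cfg <- synthetic_config(seed = 17, n_true_peaks = 300, n_background_genes = 300)
sim <- simulate_clip_dataset(cfg)

cons <- consensus_peaks(select(sim$peaks, -true_peak_id), threshold = 0.2)
nrow(cons)
#> [1] 300

cons <- annotate_regions(rename(cons, peak_id = consensus_id), sim$layout$regions)
seqs <- cons |> mutate(sequence = purrr::pmap_chr(
  list(chrom, start, end, strand),
  function(ch, s, e, st) extract_sequence(sim$genome,
    list(chrom = ch, start = s, end = e, strand = st))))
dup <- predict_binding_sites(seqs, sim$mirnas)
occ <- occupancy(dup, peaks = cons)
head(occ, 3)
#> # A tibble: 3 × 4
#>   peak_id      m delta region
#>   <chr>    <int> <dbl> <chr>
#> 1 cons0001     1  1.45 3UTR
#> 2 cons0002     1  1.47 3UTR
#> 3 cons0003     3  4.96 3UTR

strat <- stratify_quartiles(occ, region = "3UTR")
pg <- map_peaks_to_genes(cons, select(sim$layout$genes,
                                      chrom, start, end, strand, gene_id))
rep_ <- repression_by_level(strat, pg, sim$expression)
tidy(rep_)
#> # A tibble: 4 × 6
#>   level n_genes median_log2fc median_shift  ks_D     ks_p
#>   <dbl>   <int>         <dbl>        <dbl> <dbl>    <dbl>
#> 1     1      75        -0.127       0.0504 0.09  6.53e- 1
#> 2     2      75        -0.270      -0.0921 0.15  9.96e- 2
#> 3     3      75        -0.276      -0.0982 0.14  1.47e- 1
#> 4     4      75        -0.560      -0.382  0.402 9.09e-10
```

All 300 planted peaks are recovered at J20 (at J40 and J80 the sets shrink
to the peaks planted with higher overlap). Each consensus peak gets a site
count `m` and a degree of occupancy `delta`; `cons0003` holds three sites
and a correspondingly higher Δ. The repression table shows what the model
predicts: median log2 fold change decreases monotonically from level 1 to
level 4, and the top occupancy level is strongly left-shifted against the
background (KS D = 0.40, p ≈ 9e-10) while level 1 is indistinguishable from
it. `autoplot(rep_)` draws the level-wise CDFs;
`autoplot(position_frequency_matrix(dup))` draws the per-miRNA
binding-position heatmap that `hierarchical_clusters()` /
`kmeans_clusters()` group into binding modes.

A thin command-line wrapper is included at `inst/cli/agoclip`
(`simulate`, `callpeaks`, `merge`, `consensus`, `run` subcommands over the
same functions), and `run_pipeline()` executes the whole workflow
stage-by-stage with restartable on-disk artifacts.

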