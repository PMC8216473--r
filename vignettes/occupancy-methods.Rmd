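---
title: "Methods: consensus peaks and the miRNA degree of occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus peaks and the miRNA degree of occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agoclip)
```

This vignette explains the models implemented in `agoclip`, the assumptions
behind them, the parameters a user might reasonably change, and the
numerical and design choices made where more than one defensible option
existed.

## Replicate reproducibility by Jaccard-index consensus

Ago2 CLIP-seq peaks called independently in each replicate are combined as
follows. All peaks from all replicates form the nodes of an overlap graph;
two peaks are connected when they come from *different* replicates and
overlap by at least one base (same-replicate peaks never connect — merging
within a replicate is the peak caller's job). Every connected component
spanning at least `min_replicates` replicates is a candidate consensus peak,
reported with union bounds over its members.

Whether a component is *reproducible* is decided from the Jaccard indices of
its cross-replicate peak pairs, computed on base positions of the 0-based
half-open intervals. Three aggregation rules are provided because, with more
than two replicates, "a pair of peaks meets the threshold" admits several
readings:

* `any_pair` (default) — at least one cross-replicate pair reaches the
  threshold. This is the most permissive reading consistent with the
  observed nesting of the consensus sets across thresholds.
* `all_pairs` — every cross-replicate pair reaches it.
* `group` — the intersection across replicates of each replicate's merged
  footprint, divided by the union of all footprints, reaches it.

All three are threshold-monotone: the consensus set at 0.8 is contained in
the set at 0.4, which is contained in the set at 0.2. The test suite checks
each rule against a brute-force implementation that materializes base
position sets, on a thousand random fixtures.

The *merge method* baseline (`merge_method()`) pools all replicates' reads
before a single peak-calling pass. It is more sensitive — sub-threshold
coverage in individual replicates can sum over the pool — but enforces no
reproducibility. The bundled caller (`call_peaks()`) is deliberately plain:
maximal coverage runs at depth ≥ `min_coverage` and length ≥ `min_length`.
The consensus method is agnostic to the caller that produced the per-replicate
peaks.

## The occupancy model

Each peak is treated as a miRNA-binding unit whose sites cooperate. Two
assumptions shape the score: identified sites are taken to be independent of
miRNA expression level (sites are found only for the top-expressed miRNAs in
the first place), and sites within one peak are assumed to cooperate
regardless of their spacing (so distance terms are deliberately absent;
`site_spacing()` reports the spacing distribution so users can check the
assumption against the 8–60 nt range usually quoted for cooperative sites).

Scoring proceeds in three layers:

1. **β per heteroduplex.** Five additive terms, each in (0, 1]:
   energy (`mfe / min_mfe`), overall pairing (`n_paired / len_mirna`), seed
   pairing, motif pairing, and seed-bulge absence. The literal printed form
   of the energy term, −MFE/Min(MFE), is negative whenever both energies are
   negative; only the `mfe/min_mfe` reading makes the term a positive,
   bounded contribution consistent with the score's additive design, so that
   is what `beta_score()` computes (β ≤ 5, with equality exactly for a
   bulge-free, fully paired duplex at the dataset's minimum energy).
2. **μ per binding site.** Duplexes whose target footprints overlap by ≥ 1 bp
   merge transitively into a site; within a site each miRNA keeps only its
   best-energy duplex, and μ = ln Σ β over the coalition. The log means a
   site shared by *k* equal-score miRNAs gains only ln *k*: promiscuous
   sites are damped, reflecting that they respond to the pool of targeting
   miRNAs rather than to any one of them.
3. **Δ per peak.** The degree of occupancy is the plain sum of μ over the
   peak's sites, with `m` the site count.

Choices a user can change, and why the defaults are what they are:

* **`min_mfe` scope** (`dataset`, default, vs `per_mirna`): the paper-style
  score never says which minimum normalizes the energy term. The dataset
  minimum makes β comparable across peaks, which quartile stratification
  needs; per-miRNA scope is available for analyses focused on one miRNA's
  site ranking.
* **Log base**: natural. Any base rescales every Δ by the same constant and
  leaves quantile levels unchanged (asserted in the tests).
* **Seed window**: positions 2–8 (7mer) by default; 6mer and 8mer windows
  are selectable wherever seeds are matched. Seed matching is Watson–Crick
  only; G:U wobble is allowed in duplex extensions but not in the anchor.
* **Imported scores**: miRanda relative scores and TargetScan context scores
  replace β inside μ's sum verbatim. Context scores are negative, which a
  log cannot take; the imported-score path maps them to absolute values and
  says so in a message. The mapping is isolated behind
  `score_source = "imported"`.

## The hybridization engine

`hybridize()` computes a minimum-energy antiparallel co-fold of a miRNA and
a target window with the seed block forced onto its anchor, under an
explicit additive model: pair energies G:C −3, A:U −2, G:U −1 kcal/mol;
+3/nt for bulges, +2/nt for internal loops, +4 initiation; unpaired dangling
ends are free; gaps between consecutive pairs are capped at `max_gap`
(default 10) nt per strand. A duplex is reported only if its optimal energy
is negative.

This is intentionally *not* a nearest-neighbor thermodynamic model. The
design goal is an energy whose optimum is exactly checkable: the test suite
enumerates every legal co-fold for hundreds of short random miRNA/window
pairs and requires the dynamic program to match to machine precision.
Because β divides by the dataset minimum energy, downstream results depend
on the energy *ranking*, not its absolute scale; the model parameters are
pluggable through `energy_model()` for sensitivity analyses. The motif
terms default to the longest contiguous paired stretch on the target (their
ratio is then 1 by construction) and are recomputed only when externally
supplied motif features are imported; de novo motif discovery is out of
scope.

## Stratification, repression, and the evaluation statistics

`stratify_quartiles()` cuts peaks (after an optional region filter,
conventionally 3'UTR, where repressive sites concentrate) into `n_levels`
levels at linear-interpolation quantile boundaries of Δ; a value equal to a
boundary goes to the lower level, level 1 is lowest occupancy. If all values
are tied every peak lands in level 1 with a warning. The simple-count
baseline applies the same cut to `m`.

`repression_by_level()` joins stratified peaks to genes (maximal-overlap
assignment, lexicographic tie-break) and compares each level's log2 fold
changes with the all-gene background — targets included, matching the usual
"cumulative distribution of all genes" convention — using the two-sample KS
test with the asymptotic two-sided p-value. Because the KS test is
two-sided, the direction of the effect is reported separately as the signed
median shift. Genes reached by peaks in several levels count in each level
by default (`dedupe_genes = "max_level"` assigns each gene only to its top
level). A level with no mapped genes yields NA statistics and a warning
rather than an error.

The benchmarking statistics follow standard conventions where the methods
they mirror leave details open: the specificity protocol uses a paired
one-sided Wilcoxon signed-rank test (reference > shuffle), dropping zero
differences, with the exact null distribution whenever the differences are
tie-free and n ≤ 25, a full 2^n sign enumeration for small tied cases, and a
continuity-corrected normal approximation otherwise; miRNA shuffles are
mononucleotide permutations (composition-preserving); quantile normalization
for the top-expressed-miRNA ranking uses the mean-of-order-statistics
reference with average ties; interval midpoints floor at even lengths so
precision distances are deterministic integers.

Binding-position profiles count, per miRNA, how often each position is
paired across its duplexes; rows are scaled to [0, 1] by their maximum
(row-sum normalization is a flag — the display convention is stated only as
a 0–1 range, so both are defensible and the clustering outcome on
well-separated modes is the same). Profiles exist only for the internal
engine, which knows its pairing masks; imported predictions carry a single
score and are excluded from this analysis. Clustering is `hclust`
(Euclidean, complete linkage) or seeded `kmeans` with `n_init` random
restarts; base R has no k-means++ initialization, and restarts give the same
determinism-under-seed guarantee.

## The synthetic-data generator

`simulate_clip_dataset()` builds a complete, fully traceable study:

* **Genome and annotation** — plus-strand gene cassettes (100 nt 5'UTR,
  200 nt CDS, 250 nt 3'UTR, 60 nt gaps) tiled over four chromosomes, with
  i.i.d. uniform background sequence. Uniform background makes the expected
  number of chance 7mer anchors analytically checkable (≈ L·4⁻⁷ per
  strand), which the tests use.
* **Replicate peaks** — one planted peak per target-gene 3'UTR; each
  replicate's interval is the same width (100 nt) shifted along a chain so
  that adjacent replicate pairs realize a configured Jaccard index
  (defaults cycle through 0.25, 0.5, 0.9, exercising all three thresholds).
  For more than two equal-width intervals on a line, all pairwise J cannot
  equal one value simultaneously; the ground truth therefore records the
  full intended pairwise matrix implied by the chain geometry, and the
  realized values match it to within integer rounding (< 0.02). Decoy peaks
  private to single replicates are planted in background-gene 3'UTRs and
  must never survive consensus.
* **Sites** — each planted peak receives 1–4 sites (probabilities 0.4 /
  0.3 / 0.2 / 0.1), spaced 18 nt apart around the peak center with a shared
  ±5 nt jitter, so sites sit centrally (the precision protocol's premise)
  and multi-site peaks stay within the footprint. A promiscuous site (15%
  of sites by default) embeds an 8-nt word matching two miRNAs whose seeds
  are 1-nt shifts of each other — the generator builds its miRNA set in
  such pairs, mimicking family-like shared seeds. Half the sites also embed
  6 nt of complementarity to miRNA positions 10–15, giving the duplex
  energies genuine variance.
* **Expression** — log2FC(gene) = −slope · (true site count) + N(0, sd),
  slope 0.15 and sd 0.4 by default; background genes are pure noise. Linear
  repression in site count is the weakest structure sufficient to test the
  monotone level-repression prediction without assuming particular effect
  sizes.

Everything is a pure function of the configuration (one integer seed);
identical configurations give byte-identical outputs.

What the generator does **not** emulate: realistic CLIP read-count
distributions, crosslink-induced mutations, GC content or composition bias,
minus-strand genes (strand handling is exercised separately in unit tests),
secondary structure of the target outside the duplex, and miRNA expression
gradients. Tests passing on this synthetic data therefore demonstrate that
the algorithms recover planted structure under clean conditions — not that
the defaults are tuned for any particular real dataset.

## Problem sizes and numerical conventions

The default simulated study uses 2000 planted peaks, 3 replicates, 25
miRNAs and 2000 background genes — large enough for stable quartiles
(500 peaks per level) while a full pipeline pass stays in the low minutes on
one core. The specificity protocol replicates six 80-peak datasets against
five shuffles each, the smallest design with a meaningful exact signed-rank
p (1/64 when all six datasets are concordant). Exactness tolerances in the
tests are 1e-9 for the score identities and machine precision for the
dynamic-program oracle; the stratification boundary rule (ties to the lower
level) and floored midpoints remove all platform-dependent tie-breaking.

All coordinates everywhere in the package are 0-based half-open (BED
convention); 1-based inputs are not supported. Duplicate gene rows in
expression tables collapse to their mean (order-independent); duplicate
duplexes of one miRNA at one site collapse to the best energy; miRNA FASTA
files with T instead of U are normalized on read.

## Known limitations

* The additive energy model ranks duplexes plausibly but its absolute
  kcal/mol values are not thermodynamic predictions.
* Consensus aggregation beyond two replicates is genuinely ambiguous in the
  method it follows; `any_pair` is the default reading and the other two are
  one flag away, but results at high replicate counts can differ between
  them.
* Imported TargetScan context scores pass through an absolute-value mapping
  before the log; rank order within a coalition is preserved, but the
  resulting μ values are not comparable with β-based μ.
* `run_pipeline()` drops the `pairing_mask` column's structure to a compact
  string in its on-disk TSV; round-tripping is exact, but external tools
  reading the file see the mask only as a 0/1 string.
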