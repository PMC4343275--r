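---
title: "Reconstructing mutational chronology from ploidy-sorted tumor subpopulations"
author: "ploidyseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing mutational chronology from ploidy-sorted tumor subpopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyseq)
```

## The problem

Polyploid tumors often contain several subpopulations of cells with distinct
total DNA content. Flow-sorting nuclei by DNA content separates such a tumor
into ploidy fractions — here a diploid normal fraction (D, 2 N), a
hypodiploid tumor fraction (H, 1.7 N) and two sub-tetraploid fractions
(AA, 3.1 N and AB, 3.3 N) — each of which can be deep-sequenced on its own.
Because mutations accumulate along cell lineages, the sharing pattern of
somatic mutations across subpopulations records the order in which they
arose: mutations present in every tumor fraction are *early*, mutations
shared by exactly two fractions are *intermediate*, and mutations private
to one fraction are *late*. From these patterns one can reconstruct the
ancestral tumor genomes (n1, the ancestor of all tumor fractions; n2, the
ancestor of AA and AB), build lineage trees, and discriminate between
competing models of how the near-tetraploid fractions arose.

`ploidyseq` implements this analysis end to end, together with a
clonal-evolution simulator with fully known ground truth, so that every
stage — genotyping, copy-number profiling, LOH detection, structural-variant
calling, tree building, doubling-model comparison and in-silico bulk
mixing — can be validated against planted truth without any external data.

## The simulator

`build_reference()` generates a toy genome (default 60 Mb over three
chromosomes) with a GC track, assembly gaps and simple/satellite repeats.
`build_lineage()` generates a clone tree in one of three modes:

* **dual endoreduplication** — the default and the history the analysis is
  designed to detect: the hypodiploid population splits into two clones;
  each independently doubles its genome; AA is a mixture of the two doubled
  clones; AB descends from one of them.
* **cell fusion** — the alternative: a long-diverged hypodiploid lineage
  forms AA by fusing with an H-related cell and AB by endoreduplication.
* **linear** — the naive single-doubling history used as a contrast: both
  AA and AB descend from one doubling in a single H-derived cell, so no
  mutation can be shared by H and AA yet absent from AB (the single-cell
  bottleneck).

Mutations (SNVs, indels, SVs) are assigned to branches; a clone carries the
union of mutations on its root path. Genome doubling doubles both total and
mutant copy numbers; fusion sums the two parents' copies; copy losses and
LOH events remove the mutant homolog first and gains amplify the reference
homolog (a deterministic bookkeeping rule that reproduces the biologically
important phenomenon of ancestral markers being *lost* from a descendant
lineage).

`simulate_observations()` turns the tree into data. At every site a sample's
alt fraction is the copy-weighted mutant fraction over its clone mixture
(this equals the mixture-weighted mean of per-clone mutant/total ratios
whenever clones share total copy number); depth is Poisson with mean
`coverage × local copy ratio`, and alt reads are Binomial with success
probability `af(1−e) + (1−af)e/3` for error rate `e`. Germline heterozygous
SNPs are planted at 1/2 in the diploid; split-read mappings are emitted
around each planted SV with Poisson support proportional to coverage and
allele fraction, staggered non-breakpoint ends and configurable mapping
quality; per-bin read counts carry a quadratic GC bias for the loess
correction to remove. Every output type draws from its own child RNG stream
of one master seed, so adding an output never perturbs the others, and
identical configuration plus seed gives byte-identical results.

### Study conditions (defaults)

The default configuration *is* the study design: 53X mean coverage per
fraction; cell fractions D/H/AA/AB = 0.40/0.42/0.10/0.08; 2,000 planted
somatic SNVs, 400 indels and 60 SVs; 30% of the genome at copy 1 in the
hypodiploid founder (mean ploidy 1.7 N); sequencing error rate 0.002;
germline het SNP density 1/2000 bp; 500 read-depth bins (~120 kb each).

Three defaults deserve explanation because the underlying quantities are
not published:

* **AA clone mixture `f = 0.4`.** The fraction of AA contributed by the
  AB-related doubled clone is unknown. A symmetric mixture (`f = 0.5`)
  makes the dual-endoreduplication model's allele-frequency predictions
  coincide exactly with the fusion model's (both give 25%/50% for the AA-AB
  class), i.e. the two histories become unidentifiable; a strongly
  asymmetric mixture pushes one marker class near the 20/5 detection limit
  at 53X. The default 0.4 is a mild asymmetry that keeps the models
  identifiable while keeping every marker class at allele fraction ≥ 0.2.
* **Branch mutation weights.** Chosen to echo the published sharing
  proportions (about 22% early, about a quarter AB-private), with the AA-AB
  marker branch planted before the doubling (so the class sits at 50% allele
  frequency in AB, the quantity the doubling models predict) and more
  heavily than the AA-H branch. The latter is not incidental: Hamming
  distances over a mixed subpopulation are not tree-additive (the AA column
  is a union of two clones' mutation sets), and the four-point condition
  shows the reconstructed topology follows whichever of the AA-AB / AA-H
  classes is larger. The published trees place H basal with AA and AB as
  sisters, which requires the AA-AB class to dominate.
* **Event geometry.** Planted copy-number events (about 1 Mb) and LOH blocks
  (2.5 Mb) are placed non-overlapping with at least 0.5 Mb separation, and
  losses carried by 50/50 clone mixtures are planted as homozygous
  deletions: a single-copy loss diluted by an equal mixture lands at ratio
  0.75, within noise of the 0.8 calling threshold, and adjacent same-state
  events fuse into one segment and corrupt sharing-pattern accounting.
  These are resolvability conditions of the toy genome, not claims about
  real tumors.

### What the simulator does not model

Read sequences and alignment artifacts (mapping bias, strand bias,
PCR duplicates), subclonal drift within a flow fraction beyond the planted
clone mixtures, copy-number drift after doubling, mutation-rate
heterogeneity along the genome, and sequencing-error context dependence.
Passing recovery tests therefore demonstrates the correctness of the
*pipeline logic* under the stated statistical model, not robustness to
real-data artifacts.

## Genotyping and chronology

`call_presence()` applies the published calling rules: loci deeper than
2,500 reads are down-sampled (implemented as deterministic proportional
capping with the alt count rounded down — reproducible, unlike random
subsampling), a variant is *eligible* only if its capped depth reaches 20 in
every sample including the normal, and it is *present* in a sample iff it
shows at least 5 alt reads there. `filter_somatic()` removes variants
present in D; because the published filter applies one set of thresholds to
tumor and normal samples alike, normal presence uses the same 5-alt-read
rule by default, with a stricter any-alt-read exclusion available as a
switch.
`classify_chronology()`, `venn_counts()` and `infer_ancestor()` are then
pure set operations; `mutation_spectrum()` collapses substitutions onto the
pyrimidine strand into the six standard classes, and `af_by_chronology()`
compares class mean allele fractions with Welch t-tests.

Ground truth for recovery is *planted per-sample presence* (true allele
fraction > 0), not raw branch membership: a planted LOH or deletion event
genuinely removes an ancestral mutation from a descendant lineage, so the
truthful sharing pattern of such a marker excludes that lineage.

## Copy number

`make_variable_bins()` allocates bins to chromosomes proportionally to
uniquely mappable weight and, within a chromosome, chooses boundaries so
each bin receives an equal share of simulated uniform reads. The default is
the analytic limit of that construction (equal mappable length per bin);
passing `n_sim_reads` performs the literal finite sampling. Counts are
loess-corrected for GC (span 0.3, degree 1 — common read-depth practice)
and median-normalized.

Segmentation is KS-based with a two-phase scheme: segments are first split
recursively at the point maximizing the size-normalized KS statistic
`D√(mn/(m+n))` down to a minimum width of 3 bins, then adjacent segments
that a two-sample KS test cannot distinguish at α = 0.01 are merged back,
most-similar pair first. The pruning phase is essential: a short event
flanked on both sides by long neutral runs never yields a significant
single left/right split (the statistic is diluted by the shared neutral
mass), so a pure accept-gated binary recursion silently misses interior
events; split-then-prune keeps the same KS decisions while remaining able
to isolate them. The size normalization prevents the opposite failure mode,
where a 3–4-bin flank trivially maximizes raw D. Ties between equal splits
go to the leftmost; exact KS p-values are used where sample sizes permit.

Segments with mean ratio ≥ 1.4 are gains and ≤ 0.8 losses (inclusive, the
published thresholds); `compare_cna()` matches maximal same-state runs
across samples by overlap and tallies sharing patterns.

## LOH

High-confidence germline heterozygous SNPs require a heterozygous D
genotype and a D alt fraction in [0.25, 0.75] (read as inclusive). Per
tumor, the minor allele frequency (MAF) is folded onto [0, 0.5] and averaged
in 1-Mb sliding windows of *non-gap* sequence advanced by 500 kb; a window
is flagged iff its mean MAF is strictly below 0.25. Windows with no
informative SNPs never open or extend a block (absence of evidence is not
LOH), the trailing sub-window chromosome remainder is evaluated as a final
shorter window, and overlapping flagged windows merge into blocks reported
in genomic coordinates. Fold enrichment of SNV-block overlap is the observed
overlap fraction divided by the block-covered fraction of the analyzed
(non-gap by default) genome length, which is exposed as an explicit argument
since the published expectation's denominator is not stated.

## Structural variants

Split-read mappings are deduplicated within samples (both ends within 3 bp
and identical non-breakpoint ends), pooled across samples, and clustered by
single linkage where both ±1-bp breakpoint intervals overlap and the
predicted type matches. Within each cluster an all-by-all comparison counts,
for each member, the members within ±1 bp at both ends; the most supported
member is the representative (leftmost on ties). The five published filters
are applied as flags: ≥3 supporting reads; ≥50 bp for intrachromosomal
calls (interchromosomal calls have no size and are exempt); neither ±1-bp
breakpoint interval overlapping a simple/satellite repeat by more than half;
mean mapping quality strictly greater than 30; and non-breakpoint-end
stagger of at least 3 bp in total, implemented as the positional span
(max − min) summed over both sides since a total stagger could equally be
read as summed pairwise offsets (that alternative remains a configuration
choice). Callsets merge
when same-type calls agree within ±10 bp at both ends, keeping the
split-read coordinates. Junction genotyping counts reads aligned across a
breakpoint contig with ≥20 bases on each side of the junction: one normal
read marks the call germline; tumors need two reads for a positive genotype.

## Lineage trees

Binary presence vectors (with D included as an all-absent taxon — the
anchor that makes rerooting by the diploid meaningful) give Hamming
distances; segmented per-bin copy ratios give Euclidean distances.
Neighbor joining is the standard Saitou–Nei agglomeration with
lexicographically smallest pair on Q-ties; negative branch lengths are
clamped to zero with the deficit moved to the sibling edge, raw lengths
retained as an attribute. Trees are rerooted on the edge adjacent to D.
On additive matrices the implementation recovers the generating tree
exactly (and agrees with an independent reference implementation); tests
verify both.

## Doubling models

`expected_af()` encodes the closed-form allele-frequency predictions under
the assumption of one mutant copy per pre-doubling haploid set and no
post-doubling drift: fusion fixes the AA-AB class at exactly 25% in AA
(one of four copies) and 50% in AB; dual endoreduplication predicts `f/2`
in AA for carrying-clone fraction `f` and 50% in AB; the
linear-single-doubling model renders the AA-H class impossible.

`evaluate_models()` minimizes the summed squared discrepancy over a 0.01
grid of `f`. Because the dual model *nests* the fusion predictions
(`f = 0.5` reproduces 25%/50% exactly), the raw minimized residual of the
dual model can never exceed fusion's, and raw-residual comparison would
never select fusion no matter the data. The verdict therefore applies a
parsimony rule: a model with a free parameter must improve the residual by
more than a complexity tolerance (default 10⁻³, i.e. a mean allele-frequency
deviation of about 0.03 — well above counting noise on a few hundred
markers at 53X) over a parameter-free model to be preferred. Raw residuals
are always reported alongside. Observed class means fed to the comparison
are computed over sites that are copy-neutral in both AA and AB (segmented
ratio within 0.2 of 1), mirroring standard copy-neutral filtering for
frequency-based inference: chromosome-loss and CNA regions change the
copy-configuration arithmetic the models assume.

`loh_rescue_test()` asks whether AA-H markers can be explained as early
mutations lost from AB by LOH: it reports the fraction of the class inside
AB-specific LOH blocks and its fold enrichment over chance, with the
verdict "cannot explain" when the explained fraction falls below one half.

## Bulk mixing

`mix_observations()` reconstructs an in-silico bulk tumor: per site, bulk
depth is Poisson at the target coverage, reads are assigned to source
fractions multinomially by weight (cell numbers by default; a mass-weighted
switch multiplies by ploidy), and alt reads are drawn binomially from each
source's observed alt fraction. `detect_in_mixture()` applies the identical
thresholds and matched-normal exclusion used for the fractions, and
`detection_efficiency()` reports the recovered fraction of the
subpopulation-resolved mutation set, stratified by chronology class. Under
the default conditions efficiency rises with coverage and late (private)
mutations — diluted to low bulk allele fractions by the minor fractions
that carry them — are recovered far less often than early ones.

## Orchestration and reproducibility

`run_ploidyseq(ploidyseq_config(seed = ...))` executes the whole pipeline
and returns a classed report; `write_report()` emits the standard
interchange files (multi-sample VCF with DP/AD, BED/BEDPE, SEG-like TSV,
Newick trees, a JSON summary and a frozen YAML config echo). All thresholds
default to the published values (20/5/2,500; 0.25–0.75; 1 Mb/500 kb/0.25;
1.4/0.8; 3 reads/50 bp/MQ > 30/3 bp stagger/±10 bp merge; 20-base junction
flanks with the 1-versus-2-read genotype rules). Identical configuration
and seed regenerate every file byte-identically.

Problem sizes used throughout the test suite — a 60 Mb genome, 2,000
somatic SNVs, 500 bins, 53X — are the package's chosen desk-scale study
conditions; the real-genome constants of the published design (50,009 bins
with a 54-kb median on hg18) are documented here but deliberately not
reproduced at toy scale.

## Known limitations

* Presence/absence genotyping near the 5-alt-read threshold is subject to
  binomial dropout; class mean allele fractions conditioned on detection
  are slightly inflated for low-frequency classes.
* Hamming distances over mixed subpopulations are not additive, so
  distance-based topology reflects the dominant marker class rather than a
  true clone phylogeny — the same caveat applies to the published trees.
* The KS segmentation scheme is a documented stand-in for an unpublished
  original; alternative formulations (e.g. circular binary segmentation)
  would differ in detail.
* The doubling-model comparison assumes strict allele fixation within
  clones; subclonal drift (which the observed 32% versus predicted 50% in
  AB suggests) is reported as residual discrepancy, not modeled.
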