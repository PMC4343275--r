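# ploidyseq

Reconstructing the mutational chronology and clonal lineage of a polyploid
tumor from sequencing of flow-sorted ploidy subpopulations.

## The problem

Many solid tumors contain subpopulations of cells with distinct total DNA
content. Sorting nuclei by DNA content splits such a tumor into ploidy
fractions — a diploid normal fraction **D** (2 N), a hypodiploid tumor
fraction **H** (1.7 N), and two sub-tetraploid fractions **AA** (3.1 N) and
**AB** (3.3 N) — each of which can be deep-sequenced separately. Somatic
mutations then act as stable lineage markers: a mutation present in all
tumor fractions is **early**, one shared by exactly two fractions is
**intermediate**, and one private to a single fraction is **late**.

From per-fraction presence/absence calls the package

* classifies mutational chronology and builds Venn/sharing summaries,
* infers the ancestral genomes `n1 = H ∩ AA ∩ AB` and `n2 = AA ∩ AB`,
* profiles copy number by variable binning, GC loess correction and
  Kolmogorov–Smirnov segmentation (gain/loss at ratio ≥ 1.4 / ≤ 0.8),
* detects loss of heterozygosity as 1-Mb sliding windows (500-kb step) of
  germline-het minor allele frequency with mean MAF < 0.25,
* clusters split-read mappings into SV breakpoints with the five published
  filters (≥3 reads, ≥50 bp, repeat overlap, MQ > 30, ≥3 bp stagger),
* builds neighbor-joining lineage trees (Hamming distances for mutations,
  Euclidean for copy ratios) rerooted at the diploid sample,
* scores competing genome-doubling models against observed allele
  frequencies — cell fusion predicts AA-AB markers at exactly
  AF = 25% in AA (one of four chromosome copies) and 50% in AB (two of
  four after endoreduplication); dual endoreduplication predicts `f/2` in
  AA for carrying-clone fraction `f` — and tests whether LOH can explain
  the AA-H marker class,
* simulates bulk-tumor sequencing by in-silico mixing and measures how many
  subpopulation-resolved mutations survive at 30X/50X/100X.

Everything runs against a built-in clonal-evolution simulator
(`build_reference()`, `build_lineage()`, `simulate_observations()`) that
plants SNVs/indels/SVs/CNAs/LOH on a clone tree with one or two
whole-genome-doubling events and emits binomial read counts at configurable
coverage, so every stage is testable against known ground truth.

## Worked example

```r
library(ploidyseq)

report <- run_ploidyseq(ploidyseq_config(seed = 1))
print(report)
#> ploidyseq_report (dual_endoreduplication mode, seed 1)
#>   somatic variants: 2211 (1845 SNV, 366 indel), SV calls: 42
#>   chronology: early 442, intermediate 619, late 1150
#>   LOH blocks: 27 (4 AB-specific); rescue: LOH cannot explain the AA-H markers
#>   preferred doubling model: dual_endoreduplication
#>   bulk detection efficiency: 30X 41%, 50X 56%, 100X 72%

print(report$model_fit)
#> Genome-doubling model comparison
#>   cell_fusion              residual 0.00277
#>   dual_endoreduplication   residual 0.00001 (best f = 0.39)
#> Preferred model: dual_endoreduplication
```

Reading the output: of the 2,211 somatic variants detected at 53X, only
20% are shared by all three tumor fractions (early); the doubling-model
comparison recovers the dual-endoreduplication history the data were
simulated under (the fitted clone mixture `f = 0.39` matches the planted
0.40), and the LOH rescue test shows that AA-H markers are *not* explained
by AB-specific LOH — the diagnostic that rejects a naive single-doubling
history. In-silico bulk mixing shows that a conventional 30X bulk
experiment would have recovered only 41% of the mutations the
subpopulation design resolves, with late (private) mutations hit hardest.

The published predictions behind the model comparison are available
directly:

```r
expected_af("cell_fusion", "AA-AB", "AA")            # 0.25
expected_af("dual_endoreduplication", "AA-AB", "AB") # 0.5
evaluate_models(data.frame(class = "AA-AB", subpop = c("AA", "AB"),
                           af = c(0.13, 0.32)))$preferred
#> "dual_endoreduplication"
```

`write_report(report, "out/")` emits the standard interchange files:
multi-sample VCF (DP/AD), LOH-block BED, SEG-like segment table, SV BEDPE,
Newick trees and a JSON summary, plus a frozen YAML config echo; identical
configuration and seed regenerate every file byte-identically.

See the methods vignette (`vignettes/ploidyseq-methods.Rmd`) for the models,
their assumptions, all tunable parameters and the simulator's design
choices.

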