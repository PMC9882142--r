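# dualvar

Desk-scale implementations of the bespoke computational stages of a
long-read (nanopore-style) diploid genome pipeline, for method developers
and tool builders who need each stage testable in isolation and
end-to-end against known truth:

* **Dual assembly** — a haploid draft assembly plus read alignments
  becomes a locally phased diploid assembly: read filtering (min read /
  alignment length 5 kb, max divergence 0.09, max unaligned fraction
  0.20), pileup het-SNP calling, read-backed phasing and haplotagging,
  chunked plurality-consensus polishing with tandem-repeat-aware chunk
  boundaries, and inversion signature detection from split alignments.
* **Assembly-based SV calling** — insertions, deletions and inversions
  (≥ 50 bp) from diploid contig-to-reference alignments (minimap2 with
  the pinned preset `asm20 -B 2 -E 3,1 -O 6,100`), with grouping of
  indels fragmented inside VNTR intervals into single replacement
  records, and a diploid genotype merge.
* **Joint phasing** — small variants and SVs phased together by
  reference-expansion allele support: per-allele sequences extracted
  with 12 bp (small) / 64 bp (SV) flanks, read subsequences scored with
  the emission model ε^d·(1−ε)^(L−d), and a maximum-likelihood
  two-haplotype partition optimized by spanning-tree orientation plus
  flip hill-climbing (exactly optimal on small blocks, verified against
  enumeration).
* **Haplotype methylation** — CpG strand collapsing, per-region
  haplotype means from bedMethyl input, and a differential caller
  flagging regions whose |Δ| (between-haplotype difference) is more than
  three robust deviations above the absolute median difference.
* **Evaluation metrics** — switch/Hamming phasing error, distance-bounded
  SV set comparison (anchor distance ≤ 2 kb, size ratio ≥ 0.7, sequence
  similarity ≥ 0.7), small-variant precision/recall/F1, NGx, and SV
  catalog annotation (≥ 10% reciprocal overlap; allele frequency < 1% ⇒
  rare).
* **Simulator** — diploid genomes with het SNPs, indels, SVs including
  VNTR copy-number changes, lognormal reads with homopolymer-biased
  errors, and haplotype-specific methylation, all with full ground truth.

The methods vignette (`vignettes/methods.Rmd`) describes the models,
parameters and design decisions in detail.

## Worked example

Simulate a 1 Mb diploid sample (200 SVs of 50–2,000 bp, 50 of them VNTR
copy-number changes, het SNPs at 1/1000, 30× reads of 20 kb mean at 1%
error) and run the whole pipeline:

```r
library(dualvar)
state <- run_pipeline(sim_config(seed = 1), "example_run")
str(state$metrics)
```

```
List of 11
 $ sv_precision  : num 1
 $ sv_recall     : num 0.985
 $ sv_f1         : num 0.992
 $ sv_tp         : int 197
 $ sv_fp         : int 0
 $ sv_fn         : int 3
 $ switch_error  : num 0
 $ hamming_error : num 0
 $ n_phased_het  : int 1053
 $ meth_precision: num 1
 $ meth_recall   : num 1
```

Reading the output: of the 200 simulated structural variants, 197 are
recovered (recall 0.985) with no false calls (precision 1), compared
under the distance-bounded matcher; all 1,053 phased heterozygous
variants are in the correct relative phase against truth (switch and
Hamming error 0); and every simulated haplotype-differential methylation
region is flagged with no false flags. `example_run/` keeps every
intermediate: the dual assembly (`assembly_dual.fasta`), the diploid SV
calls (`sv.vcf`), the jointly phased call set with PS tags
(`phased.vcf`), regional methylation calls (`methdiff.tsv`), metrics
(`metrics.json`) and a run manifest.

Individual stages are plain functions over plain data structures, e.g.

```r
truth <- simulate_diploid(sim_config(seed = 1, genome_len = 2e5))
svs   <- read_vcf("example_run/sv.vcf")
compare_sv_sets(truth$truth_variants, svs)   # PRF + match table
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dualvar.R", package="dualvar"))')" \
    run --out example_run --seed 1
```

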