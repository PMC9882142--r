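---
title: "Models and methods behind dualvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dualvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dualvar is a desk-scale toolkit for the bespoke computational stages of a
long-read (nanopore-style) diploid genome pipeline: turning a haploid
draft assembly into a locally phased diploid ("dual") assembly, calling
structural variants (SVs) from the diploid contigs with tandem-repeat-aware
grouping, jointly phasing small and structural variants from read allele
support, and calling haplotype-differential methylation. A built-in
simulator generates diploid genomes, reads, and methylation with full
ground truth, so every stage can be tested end-to-end against known
answers. This vignette explains the models, the parameters that matter,
and the design decisions taken where the methods were genuinely open.

## The synthetic diploid sample

`simulate_diploid()` builds a uniform-random reference chromosome with
embedded VNTR loci (tandem arrays of a random unit, 25 bp by default,
8–20 copies), then draws three classes of heterozygous variation:

* **SNPs** at `snp_rate` (default 1/1000 bp), each assigned to one
  haplotype;
* **small indels** at `indel_rate` (default 2/10,000 bp) with geometric
  lengths (mean 3 bp, capped below the 50 bp SV threshold);
* **structural variants**: `n_svs` = 200 by default, of which one per
  VNTR locus (50 loci) is realized as a whole-unit copy-number change —
  the exact situation in which alignment ambiguity later fragments one
  allele difference into several sub-threshold indels. The remaining SVs
  are insertions, deletions and (rarely) inversions of 50–2,000 bp.
  Inversions default to a 2% share, reflecting how rare sequence-resolved
  inversions are relative to indel-type SVs in human call sets.

SVs are placed with at least 500 bp of separation. The package models
*isolated* SV events; compound clusters of interacting SVs (an inversion
inside the span of an insertion's alignment footprint, for example) are a
genuinely harder representation problem that the simulator deliberately
does not generate. Variants never overlap on the reference, so applying
the phased alleles to the reference reconstructs each haplotype exactly —
a byte-level invariant the test suite checks.

Reads are sampled per haplotype at `coverage/2` with lognormal lengths
(mean 20 kb). Errors are injected per base (default 1%), split between
mismatches, insertions and deletions, with the indel rate multiplied
inside homopolymers of ≥ 4 bp — mirroring where nanopore indel errors
concentrate. The exact read-to-haplotype alignment (a CIGAR over the
injected errors) is recorded for oracle use. With `tile_reads = TRUE` a
deterministic 2× tiling is added so exactness tests are not at the mercy
of coverage gaps. Methylation is simulated on reference CpGs inside
non-overlapping promoter-like regions: a bimodal baseline (hypo ≈ 0.1 /
hyper ≈ 0.9 per region), a configurable fraction of regions shifted by
Δ = 0.5 on one haplotype, truncated Gaussian site noise (SD 0.05), and
Poisson coverage.

All draws derive from one seed through fixed per-stage offsets, so adding
a feature to one stage does not shift another stage's stream, and
identical configurations give byte-identical outputs.

What passing tests on this simulator do *not* show: performance on real
base-caller error profiles (which are context-correlated, not i.i.d.),
on segmental duplications and satellite arrays (absent from a random
genome), or on compound SV clusters. The simulator is a correctness
harness, not a benchmark of biological difficulty.

## Dual assembly

`hapdup()` converts a haploid draft plus read alignments into two
locally phased haplotype sequences.

**Read filtering.** Reads are dropped if shorter than 5,000 bp, if their
best alignment spans under 5,000 bp, if alignment divergence exceeds
0.09, or if more than 20% of the read is unaligned. The first three
defaults follow established long-read assembly-evaluation practice; the
unaligned fraction is this package's own quantification of "large
unaligned parts" and is exposed in `read_filter_config()`. The rule
exists because reads from unassembled repeat copies misalign to their
assembled paralogs and would otherwise fabricate haplotypes.

**SNP calling and haplotagging.** A pileup site is a het SNP candidate
when depth ≥ 8 and the two top bases each reach 25% frequency; homozygous
differences from the draft are kept for polishing but are uninformative
for phasing. Het SNPs are phased with the same maximum-likelihood
machinery used for joint phasing (below), and each read is tagged H1/H2
by majority vote over the phased alleles it covers; ties are left
untagged and untagged reads are excluded from polishing — the
conservative choice for phased consensus.

**Chunked consensus polishing.** Each haplotype is rebuilt by column-wise
plurality consensus over its tagged reads, in nominal 10 kb chunks.
Nominal chunk boundaries are shifted off *inconsistent-indel regions*:
maximal intervals where ≥ 2 reads carry indels of ≥ 5 bp whose
coordinates differ by at least 10 bp while their padded intervals
overlap. Inside a tandem array one real indel is placed at a different
unit boundary by every read, so plurality votes cancel; regions within
500 bp of each other are merged because this placement scatter spans the
whole array. Within such regions (when this haplotype actually carries
the inconsistent indels) the column consensus is replaced by a
mini-consensus: the medoid spanning-read subsequence re-polished by
banded global alignments of all spanning copies, so individual read
errors are outvoted.

Structural indels that the aligner renders as *split* alignments rather
than CIGAR ops are recovered separately: consecutive same-strand
segments of one read with a near-zero gap on one side and ≥ 50 bp on the
other are insertion/deletion junction signatures; signatures clustering
within 200 bp are accepted when the carriers outnumber the reads aligned
straight through the junction. Inversions are detected from
forward–reverse–forward split patterns (breakpoints clustered within
500 bp, ≥ 3 supporting reads by default), assigned a haplotype by the
supporting reads' haplotags, and applied by reverse-complementing the
interval. A rearrangement supported only by untagged reads is applied to
both haplotypes ("both") — a flagged convention, not an inference.

Output modes: *dual* (one sequence per input contig per haplotype,
preserving contiguity, possibly containing phase switches between phase
sets) and *split* (contigs cut midway between phase sets so each piece
is a single parental haplotype).

The polisher is a deliberate simplification of likelihood-based
long-read polishing: column plurality plus the chunking rule and the
mini-consensus, rather than a full maximum-likelihood model over
alignments. The trade is fidelity at very low coverage for transparency
and testability; at the package's design point (≥ 5× per haplotype) the
error-free-input behaviour is byte-exact and is asserted in the tests.

## Assembly-based SV calling

`svcall_from_alignments()` calls SVs from diploid contig-to-reference
alignments. Contig alignment is delegated to minimap2 with a fixed
parameter string — `asm20 -B 2 -E 3,1 -O 6,100` — recorded in
`sv_call_config()`; the low long-gap extension cost favours representing
long SVs inside one alignment, and pinning the aligner parameters is
part of making the calls reproducible.

Raw variants come from three sources: every I/D CIGAR op and mismatch
run; junctions between consecutive same-strand split segments of one
contig (net query-vs-target gap difference as a replacement record); and
strand-flipped split segments (inversions). Positions are left-anchored
with one shared reference base, VCF-style.

**VNTR grouping.** Given a VNTR annotation, all indel records of one
haplotype anchored inside one interval are replaced by a single
replacement record: reference substring → substring with the member
edits applied, net length change, `grouped_from` = member count. The
record spans the *whole* VNTR interval rather than the first-to-last
affected base: inside a tandem array the same allele can be written with
the indels at any unit boundary, and only the full-interval span makes
the grouped record invariant to that choice (the test suite asserts this
invariance by shifting indel placement). SNPs are never grouped. Two
+30 bp insertions in one array thus become one +60 bp SV that passes the
50 bp threshold which neither fragment would pass alone; a +30/−30 pair
nets to zero and is classified back to INDEL.

**Diploid merge.** Same-type records from the two haplotypes merge to
1|1 when anchors are within 500 bp, sizes agree to a 0.7 ratio and (for
insertions) sequences agree to 0.7 edit similarity; singletons become
1|0 / 0|1; different alleles at one anchor become a multiallelic 1|2.
The merge tolerances deliberately mirror the benchmarking comparator so
that calling and evaluation are consistent. Insertion similarity is
computed on the minimal (affix-trimmed) representation and is tolerant
to tandem-phase rotation (the shorter sequence is also matched inside a
doubled copy of the longer), because the same inserted array reported
one unit later is the same allele.

## Joint phasing by reference-expansion allele support

`phase_variants()` phases a merged set of small and structural variants
from read support. For each variant, per-allele sequences are extracted
from the reference with a flanking expansion: 12 bp for small variants
and 64 bp for SVs, with 50 bp of allele-length difference separating the
two regimes (`phasing_config()`). The larger SV expansion absorbs the
breakpoint placement ambiguity of read alignments around SVs. Each read
fully spanning the window contributes the subsequence whose alignment
columns project into it; reads only partially overlapping a window are
dropped at that locus rather than scored against a truncated allele,
which would bias toward shorter alleles. With edit distance $d_a$ to
allele $a$ of length $L_a$ and error rate $\varepsilon$ (default 0.10),
the emission likelihood is

$$ P(r \mid a) = \varepsilon^{d_a}\,(1-\varepsilon)^{L_a - d_a}, $$

normalized over alleles. For $d_A = 0$, $d_B = 3$ this gives
$P(A) = 9^3/(9^3+1) \approx 0.99863$ at $\varepsilon = 0.1$.

Phasing itself maximizes the total read log-likelihood
$\sum_r \max_h \sum_{i \in r} \log P(r \mid a_{h}(i))$ over the $2^{n-1}$
assignments of het alleles to haplotypes: a graph over het variants is
built with edge weights equal to the summed cis-versus-trans log-odds
over shared reads, edges need ≥ 2 linking reads (connected components
become phase sets), components are oriented along a maximum spanning
tree and refined by single-site flip hill-climbing with deterministic
restarts on small components. On components of ≤ 12 sites the test suite
checks the hill-climbed optimum equals exhaustive enumeration. This
explicit partition optimizer replaces a banded-HMM formulation with the
same emission model; it was chosen because its objective can be verified
against brute force. Outputs are canonicalized (first het site of every
phase set is REF-first) so results are deterministic; homozygous records
pass through phased, inheriting the surrounding phase set.

The practical value of joint phasing is that an SV can be the only
linking variant across a small-variant desert; the test suite constructs
exactly that situation and checks that the flanking blocks join only
when the SV is included.

## Haplotype-differential methylation

CpG sites on the two strands are one position apart; `methdiff()` first
merges each +/− pair into one site with summed coverage and
coverage-weighted methylation. Regions are summarized per haplotype as
the unweighted mean of site fractions over sites with ≥ 5 reads; regions
with fewer than 5 usable CpGs on either haplotype are dropped with a
reason. The between-haplotype difference is
$\Delta = \bar m_{h1} - \bar m_{h2}$.

A region is called differential when $|\Delta|$ is more than three
deviations above the absolute median difference:

$$ z = \frac{|\Delta| - \mathrm{median}(|\Delta|)}{\max(s, s_{\mathrm{floor}})},
\qquad \text{flag if } z > 3, $$

with $s$ the scaled median absolute deviation of the *signed* $\Delta$
about its median (1.4826 × MAD), and $s_{\mathrm{floor}} = 10^{-3}$ so a
degenerate all-identical population flags nothing. The deviation unit is
a genuinely open choice: scaling by the spread of $|\Delta|$ itself
flags ≈ 1.5% of a pure-noise population, because a folded normal's own
3-MAD tail is that heavy — which would make the rule a quantile cut, not
an outlier detector. The signed-spread unit keeps the null flag rate
near 0.02% while leaving Δ = 0.5 effects at z ≫ 3. A plain
standard-deviation unit is available behind `method = "sd"`. The
population over which the statistic is computed is whatever region set
the caller provides (promoters, CpG islands, SV flanks from
`regions_from_svs()`); at least 20 regions are required for the scale to
mean anything.

## Evaluation metrics

* `switch_hamming()` — comparison is restricted to sites het and phased
  in both call sets; the switch rate is the fraction of adjacent site
  pairs whose relative phase disagrees with truth, and the Hamming rate
  the fraction of sites on the wrong haplotype under the better of the
  two global block orientations, pooled with count weights. The
  implementation is property-tested against exhaustive enumeration.
* `compare_sv_sets()` — distance-bounded SV matching: same chromosome
  and type class, anchors within 2,000 bp, size ratio ≥ 0.7, insertion
  sequence similarity ≥ 0.7 (rotation-tolerant, on minimal
  representations); greedy one-to-one assignment by a combined
  distance-plus-size score with deterministic tie-breaks. This keeps the
  headline semantics of distance-parameterized SV benchmarking without
  replicating any specific tool's full scoring.
* `small_variant_prf()` — exact normalized-allele plus unordered-genotype
  matching inside optional confident regions, split by SNP/indel. This
  is stricter than haplotype-aware comparison engines and may undercount
  true positives at complex loci; at desk scale on normalized simulated
  calls the two coincide.
* `ngx()` — NGx contiguity against a given genome size.
* `annotate_sv_frequency()` — catalog matching at ≥ 10% overlap,
  interpreted as *reciprocal* overlap for deletions/inversions (the
  unidirectional reading is configurable); insertions, spanless on the
  reference, match by anchor distance and a size ratio. Records with
  best matched allele frequency < 1%, or no match, are flagged rare.

## Numerical and engineering choices

* Internal coordinates are 0-based half-open everywhere; VCF's 1-based
  anchor convention exists only at the serialization boundary (a
  property test asserts offset *k* serializes at POS *k*+1).
* `M` CIGAR ops are accepted as match-or-mismatch; divergence computed
  from such CIGARs counts only indel columns and is documented as a
  lower bound.
* The bedMethyl reader is pinned to the 9+2 column layout; other
  dialects are rejected loudly rather than guessed.
* Mini-consensus alignment uses a banded unit-cost global aligner (band
  auto-widened to the length difference plus 32); bands this wide are
  loose for ≤ 1% error copies of the same locus.
* Ties are broken deterministically throughout (plurality ties prefer
  the draft base; greedy matching breaks ties by position then input
  order; phase sets are canonicalized REF-first), so identical inputs
  give identical outputs.
* Problem sizes in the tests: the end-to-end check runs a 1 Mb diploid
  genome at 30× with 200 SVs; exactness checks run 120 kb at 12×;
  statistical checks use 1,000 simulated regions or 200–500 random
  instances. These sizes were chosen so the whole suite exercises every
  stage at meaningful depth while remaining a desk-scale computation.

## Known limitations

* The polisher is not a full likelihood model; below ~5× per-haplotype
  coverage its consensus degrades faster than a proper ML polisher
  would.
* Only inversions are handled among balanced rearrangements; no
  duplication or translocation classes.
* Compound, interacting SV clusters are out of scope end-to-end (the
  simulator does not generate them and the caller's representation of
  them is unspecified).
* Segmental duplications and satellite repeats — the hard cases of real
  genomes — have no analog in the random simulated genome.
* The methylation caller tests region lists; it does not segment the
  genome into DMRs de novo.
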