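---
title: "Knockout-controlled m5C calling and codon-occupancy profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout-controlled m5C calling and codon-occupancy profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

RNA 5-methylcytosine (m5C) is detected by bisulfite sequencing: bisulfite
deaminates unmethylated cytosines to uracil (read as T), while m5C resists
conversion. A cytosine's *non-conversion ratio* — the fraction of reads still
calling C — is therefore a proxy for methylation stoichiometry. The approach
is haunted by artifacts: structured RNA and incomplete conversion produce
non-converted positions that are not methylated. The decisive control is
genetic: an organism in which every relevant m5C methyltransferase (the NSUN
family) is catalytically dead ("noNSUN") carries no enzymatic m5C, so any
position non-converted *in both* genotypes is an artifact, and positions
non-converted *exclusively in the wild type* are genuine,
methyltransferase-dependent sites.

The downstream biology this package quantifies is translational: tRNA wobble
m5C (C34 of the UUG-decoding tRNA Leu-CAA) supports decoding of UUG codons,
and its loss slows UUG translation under heat stress. Ribosome profiling
measures this as elevated P-site *codon occupancy* at UUG in the null
genotype, and as reduced *translation efficiency* (TE) of UUG-rich
transcripts.

`methribo` implements both analysis arms plus a synthetic-data generator
with planted ground truth, so every stage can be validated against a known
answer at desk scale.

# The calling model

For each cytosine with per-replicate coverage higher than 10 in every
replicate of both genotypes (strictly: coverage >= 11), pooled
non-conversion ratios are computed on summed counts across replicates. A
site is:

* `nsun_dependent` if the pooled wild-type ratio exceeds 0.1 while the
  pooled knockout ratio stays at or below 0.1;
* `nsun_independent_artifact` if both pooled ratios exceed 0.1;
* `unmethylated` otherwise; `insufficient_coverage` if any replicate fails
  the floor.

Two ambiguities in the published rule were resolved as follows. First,
"coverage higher than 10" is read strictly (>= 11) and applied per
replicate, while ratios are computed on pooled counts: pooling stabilizes
low-coverage sites, and per-replicate ratios are retained in the output for
audit. Second, "exclusively in wild-type" carries no numeric cutoff for the
knockout side; the symmetric reuse of the stated 0.1 threshold is the
least-surprising choice and is exposed as `ko_max_ratio`.

The deamination (conversion) rate is estimated as converted / (converted +
non-converted) over rRNA cytosines, after excluding known methylated sites —
including them would deflate the efficiency estimate by exactly the summed
stoichiometry of the excluded sites.

The threshold sweep counts, for each threshold t in 0.25–0.40, positions
whose wild-type ratio is >= t while the knockout ratio is < t (putative
m5C), and the genotype-swapped count (an artifact-rate estimate). Note that
the count is guaranteed non-increasing in t only when counterpart ratios sit
below the lowest threshold — the regime that holds in practice, where
knockout ratios concentrate near 1 − deamination ≈ 0.01. On adversarial
inputs the two-sided definition is not monotone, which is why the package
asserts monotonicity only in that regime.

# The profiling model

Ribosome-protected fragments are uniquely aligned to the transcriptome,
length-stratified, and gated on 3-nt periodicity: a length is retained when
the modal frame of CDS-overlapping 5' ends holds at least
`min_frame_fraction` (default 0.5) of reads. The P-site first nucleotide is
the 5' end shifted +12 nt for all retained lengths (no per-length
calibration — the single fixed offset is part of the emulated protocol).
In-frame P-sites map to codon index (p − cds_start)/3; off-frame P-sites are
dropped and counted, and the first 10 codons of every gene are discarded.
The chain conserves counts exactly:

    CDS-assigned footprints = off-frame dropped + first-10 removed + table sum.

Bulk codon occupancy of codon X is the P-site count of X divided by one
third of the background count, where the background tallies X at the +1, +2
and +3 codons relative to the A-site — nucleotide offsets +6, +9, +12 from
the P-site first nucleotide, the standard reading of downstream-codon
normalization. The mean-of-three aggregation makes a uniform ribosome
distribution normalize to exactly 1. Positions whose background window runs
past the last sense codon are skipped from both tallies, keeping the
numerator and denominator over the same position set.

Per-codon genotype fold change is the ratio of mean occupancies
(noNSUN/WT), tested by Welch's t-test on log2 occupancies across replicates
(the Welch variant is robust to unequal replicate variance; the emulated
analysis does not state its t-test flavor). Codons with an undefined or
non-positive occupancy in any replicate are flagged and excluded from
testing.

A documented limitation: downstream-codon normalization is not perfectly
local. A planted stall at one codon inflates the background of codons
downstream of it, deflating *all* occupancies in the affected genotype by a
factor of roughly 1 + (m − 1)·f (m the dwell multiplier, f the codon's
frequency), about 2.5% under the default planted effect. The recovered fold
change is accordingly a slight underestimate, and codons at multiplier 1
show a small genuine shift. Deliberately stall-codon-clustered genes make
this worse, which is why the dwell-recovery benchmark runs on a transcriptome
without them.

Gene-level TE divides first-10-codon-excluded footprint counts by RNA-seq
abundance, each library CPM-normalized over the evaluable genes (RNA count
>= `min_rna`, default 10). CPM rather than DESeq2 size factors keeps TE
self-contained; differential-expression modelling is out of scope. A gene is
enriched in a codon when its within-gene proportion (among sense codons,
stops excluded) is at least 3-fold the pooled transcriptome proportion, the
boundary included. Gene-set TE comparisons use Welch's t-test on log2 TE,
either against a seeded size-matched random control within a sample, or for
the same set between two samples (the directional knockout-vs-wild-type
contrast).

The polysome fraction of an absorbance trace is the trapezoidal area at or
beyond the monosome/polysome boundary over the total area, with the trace
linearly interpolated at the boundary so piecewise-linear traces integrate
exactly.

# The synthetic-data generator

The generator emulates the structure of the emulated study's data, not its
scale:

* **Reference** — 80 mRNAs (150–300 codons, ATG…stop, no internal stops,
  30-nt UTRs), 20 tRNAs ending in CCA with cytosines forced at the
  variable-loop positions 48–50 and a C34 on exactly one tRNA (Leu-CAA),
  one mitochondrial tRNA-Met, and 4 rRNAs (nuclear and mitochondrial).
  One transcript per gene.
* **Codon usage** — sense codons are sampled uniformly over the 61-codon
  table. Real codon usage is biased, but uniform usage gives every codon
  comparable statistical power in occupancy analyses, which is what the
  recovery benchmarks need; nothing in the analysis code depends on it.
  A configurable subset of mRNAs (default 6) is enriched in a focal codon
  (default TTG at 10% of codons, comfortably past the 3-fold rule) to
  provide stall-prone transcripts.
* **Methylation plan** — planted sites with per-site stoichiometry:
  variable-loop tRNA sites, the single wobble-34 site, rRNA sites, rare
  low-stoichiometry mRNA sites, and genotype-independent artifact sites.
  Sites are placed at least one read length from transcript ends because
  uniform fragment starts under-cover termini; terminal positions would
  mostly be removed by the coverage filter anyway.
* **Bisulfite reads** — sense-strand fixed-length fragments (RNA bisulfite
  chemistry is strand-preserving); per-molecule Bernoulli methylation at
  planted sites (zero at dependent sites in the null genotype), C→T
  conversion of unmethylated Cs with probability 0.99, then uniform
  substitution errors (0.1%), no indels. Mean coverage 50x.
* **Footprints** — P-sites sampled over (gene, sense codon) positions with
  probability proportional to expression x loading x dwell; 5' end 12 nt
  upstream; lengths 26–32 nt (mode 28–29); 5% off-frame jitter of ±1 nt;
  120,000 footprints per sample. RNA-seq is emitted as Poisson counts
  independent of dwell (a full read-level path exists behind a flag).
* **Replicate variability** — each sample multiplies every codon's dwell by
  a lognormal factor (`dwell_cv`, default 5%). Without it, replicates
  differ only by counting noise and a 3v3 t-test is overpowered against
  percent-level systematic effects, which no real experiment resolves.
  "Uniform dwell" in the neutrality benchmarks means no codon-to-codon
  *and* no replicate-to-replicate variation.
* **Gene-level TE effect** — the dwell model alone *increases* footprint
  counts of stall-codon-rich genes (density rises at the stall), which
  would raise their apparent TE — the opposite of the biology being
  emulated, where stalling reduces translational output. The generator
  therefore also multiplies the ribosome loading of stall-codon-enriched
  genes by `stall_te_factor` (default 0.5) under the genotype/condition
  carrying the planted dwell effect. This plants the gene-level TE
  reduction alongside the codon-level occupancy increase.
* **Seeding** — one master seed; every sample draws from a stream derived
  by a fixed integer mix of the master seed and a documented per-sample
  offset (`sample_stream()`), so adding a sample never perturbs existing
  ones and identical configurations are byte-identical across runs.

What the generator does **not** model: hm5C/f5C chemistry, mitochondrial
codon-table differences, fragment-length or GC bias, adapter/quality
trimming, PCR duplicates, rRNA contamination of footprint libraries, indels.
Passing benchmarks therefore demonstrate correctness of the analysis logic
under a clean generative model, not robustness to every artifact of real
libraries.

# Aligner design

References at this scale (tens of kilobases) allow an exact seed-and-verify
aligner instead of an FM-index: with a mismatch budget m, m+1 non-overlapping
k-mer seeds guarantee by pigeonhole that every alignment within budget is
examined, and every candidate is verified exhaustively. In bisulfite mode,
candidate search runs in C→T-collapsed space and verification applies the
asymmetric rule (read T matches reference C; read C does not match reference
T). A read is kept only with a unique best-scoring location; ties are
discarded, not broken. Defaults: 2 mismatches for 75-nt bisulfite reads, 1
for 26–32-nt footprints. The contract (unique best hit, collapsed-space
asymmetric matching) is the fixed part; equivalence with any particular
genome-scale aligner's option set is not claimed. Before alignment,
reference tRNAs get their 3' CCA appended (idempotent) and
bisulfite-identical sequences — distinguishable only by C>T substitutions —
are merged into a representative that keeps the C polymorphism, preserving
unique alignability.

# Benchmark problem sizes and power

The benchmark defaults were fixed from a power calculation, not tuned on
outcomes. Per-codon P-site counts at 120k footprints over ~18k eligible
codon positions are ~2000, giving a per-replicate occupancy SD of ~3%; the
fixed expression-weighted composition bias of the normalization (which does
not shrink with depth) contributes ~2% at 80 genes x 150–300 codons with
expression sdlog 0.75. Together the neutrality band of ±10% sits >4 sigma
from the mean for all 61 codons, and a 2.5-fold planted dwell effect is
recovered within ±15% with large margin. The bisulfite arm at 50x coverage
and deamination 0.99 bounds the false dependent-site rate by the binomial
tail (a 0.1 ratio at coverage >= 11x per replicate, ~300x pooled, is >10
SDs from the 1% background), and 100 planted sites at stoichiometry >= 0.5
are each >5 SDs above threshold, so recall failures are dominated by
coverage dropouts, which the planting margin avoids. Each benchmark runs in
well under five minutes on one CPU.

# Degenerate inputs and numerical choices

* Zero-variance t-tests (identical replicates) are flagged `tested = FALSE`
  rather than producing spurious p-values.
* Occupancies with an empty background are `NA` and excluded from testing;
  a positive background with zero P-site count gives occupancy 0.
* Cytosine positions with only non-C/T calls keep coverage 0 ("other" calls
  are sequencing errors, not conversion evidence) and are reported, not
  dropped.
* All coordinates are 0-based half-open internally; TSV exports use 1-based
  inclusive positions (`pos_1based`), the common pileup convention.
* Random control sets for TE contrasts are drawn outside the planted
  enriched sets when a planted effect exists: at the 80-gene desk scale a
  fully random draw would frequently include a stall gene and test an
  alternative rather than the null. The across-seed 5% calibration of the
  test is run on a uniform-dwell (null) simulation, where no exclusion is
  needed.

# Known limitations

The aligner is exact but desk-scale; it is not a replacement for a
genome-scale bisulfite or spliced aligner. The calling rule is the published
thresholding rule; no per-site statistical test or multiple-testing
correction is applied. TE uses full-CDS RNA counts (whether the emulated
analysis excluded the first 10 codons on the RNA side too is unstated).
Downstream-codon normalization has the non-locality described above. The
generator's independence assumptions (no codon autocorrelation beyond the
planted enrichment, no overdispersion beyond `dwell_cv`) make the benchmarks
necessary, not sufficient, evidence for behaviour on real libraries.
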