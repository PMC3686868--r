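---
title: "Species-partitioned RNA-seq for xenograft samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-partitioned RNA-seq for xenograft samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenopartition)
```

## The problem

A human tumour xenograft is a mixed-RNA system: the graft (human tumour
cells) and the host (mouse stroma — endothelium, leukocytes, fibroblasts)
contribute to one RNA pool, typically at roughly a 10:1 human:mouse ratio.
Because orthologous human/mouse exons average only ~85% nucleotide
identity, short reads can be assigned to their species of origin directly
from sequence, without manipulating the RNA, customising the protocol, or
knowing the mixing ratio in advance. `xenopartition` implements that
strategy at desk scale: it aligns each read against both species'
references, keeps only reads that map uniquely to exactly one species, and
quantifies expression with a mappability-corrected RPKM, together with the
concordance statistics used to compare detection calls across platforms.

## The mapping policy

Reads (nominally 50 b) are trimmed before alignment: the first and last
base plus five 3'-end bases are removed, leaving a 43-base effective
sequence. A candidate locus is accepted when the trimmed read matches with
at most 2 mismatches in its first 25 bases (the seed, anchored at the 5'
end of the read as sequenced) and at most 3 mismatches overall. The seed
length and both budgets are `alignment_policy()` parameters; the total
budget is an explicit integer cap because a reproducible pipeline needs a
deterministic acceptance rule rather than a quality-weighted one. Alignment
is mismatch-only — no indels — which is the regime the trimming and budget
arithmetic is designed for.

The internal aligner is exhaustive within these budgets: the 25-base seed
is split into three disjoint 8-mers, and since two mismatches cannot hit
all three parts, every valid locus is recovered from an exact 8-mer index
lookup and verified in full (the pigeonhole guarantee). The test suite
checks the resulting hit sets against a brute-force sliding-window scan at
every offset and strand of 100 kb references. `N` never matches anything,
in reads or references. For real data, hits can instead be ingested from
SAM (`read_sam_hits()`, mapping quality > 0); the internal aligner remains
the reference implementation.

## Splice-junction library

Reads crossing exon–exon boundaries cannot match the genome, so each
species also gets a junction library: for every distinct genomic breakpoint
(chromosome, strand, donor end, acceptor start) across all transcripts, the
last 42 bases of the upstream exon are joined to the first 42 of the
downstream exon (whole exon if shorter). The 42-base flank is the effective
read length minus one, so any read overlapping the breakpoint by at least
one base on each side can align; it should be recomputed if the trim policy
changes. Junctions shared by transcripts appear once — the breakpoint, not
the transcript, is the identity, which is the only species-consistent
non-redundancy key.

Minus-strand junction sequences are emitted in transcription orientation
(reverse complement of the plus-strand concatenation). This makes the
library stranded, and gives the antisense filter a well-defined meaning: a
read aligning to the minus strand of a junction sequence is treated as a
false-positive hit and removed before uniqueness is assessed. Genome
minus-strand hits are kept — the genome index is unstranded.

## Partition logic

Within one species, after the antisense filter, a read is `unique` when
exactly one hit survives and `multimapped` otherwise — including the case
of one genome hit plus one junction hit, which is how intron-spanning reads
that also match a pseudogene are removed. Across species the rules are set
logic: unique in one species and unmapped in the other retains the read for
that species; any surviving hit in both species discards it as
cross-species; multimapped in exactly one species discards it as
multi-mapped. A read whose only alignments anywhere were antisense junction
hits gets its own discard class. The classes are disjoint and exhaustive,
so class counts always sum to the read count — asserted on every run. One
interaction deserves note: a read unique in species A whose only B-side
evidence was an antisense junction hit is kept as `unique_A`, because
antisense hits are discarded *before* the cross-species test, matching the
stated order of operations (antisense filter, then uniqueness, then
cross-species removal).

The proportion of retained reads unique to the host species estimates the
sample's species composition (`estimate_species_mix()`), with no prior
knowledge of the mixing ratio.

## Non-unique loci and the adjusted RPKM

Some genomic windows cannot produce uniquely mapped reads because their
sequence recurs elsewhere in the combined two-species reference.
`build_uniqueome()` marks every window start whose k-mer (default k = 50,
the nominal read length) occurs at two or more start positions anywhere in
the concatenated genomes. Only plus-strand k-mers are compared by default —
the definition is a literal sequence search over the concatenated reference
— with `both_strands = TRUE` available where reverse-complement collisions
matter. Windows containing `N` are marked non-unique by policy: reads are
never mapped across `N`, so those loci cannot contribute unique reads.
Any implementation is acceptable if it reproduces the exhaustive
hash-multiset definition; the tests enforce exact equality with a
brute-force oracle at several k.

Expression is quantified per transcript as

\[ \mathrm{RPKM}' = \frac{N}{\left((L-U)/10^3\right)\,\left(T/C\right)} + 0.001 \]

where \(N\) is the read count over the transcript (intersect semantics: a
read counts once for every transcript whose exon union it overlaps by at
least one base, and junction reads count for every transcript containing
the breakpoint; no fractional or EM reassignment), \(L\) the exonic length,
\(U\) the number of non-unique loci whose window lies inside the exon union
(same support as \(L\), so \(L-U\) is a meaningful mappable length and
\(0 \le U \le L\)), \(T\) the species' total of uniquely mapped reads in
the sample, and \(C = 10^6\). This is classic RPKM with the transcript
length replaced by its mappable length. The 0.001 pseudocount is added to
the RPKM itself — not to \(N\) — so that `log2` of undetected transcripts
is finite; logs are base 2 throughout. When \(L - U \le 0\) the transcript
has no mappable length and the RPKM is returned as `NA` and excluded
downstream. The composition lives in one function (`rpkm()`) so an
alternative correction could be swapped without touching callers.

At gene level the transcript with the most reads represents its parent gene
(ties broken by lexicographically smallest transcript id, keeping output
deterministic), and a gene is detected when its representative has at least
one read — a threshold whose effect can be examined with
`threshold_sweep()`.

## Concordance between platforms

Detection agreement between two platforms over a common gene universe is
summarised by the 2×2 table (A detected on both, B on neither, C by
platform 1 only, D by platform 2 only) and scored with a correspondence
score, the Matthews correlation with (A, B, C, D) in the roles of
(TP, TN, FP, FN):

\[ CS = \frac{AB - CD}{\sqrt{(A+C)(A+D)(B+C)(B+D)}} \]

The formula is undefined on several boundaries, so the conventions are
pinned explicitly: perfect correspondence (C = D = 0) returns 1, total
disagreement (A = B = 0) returns −1, and any other zero denominator factor
returns 0 ("no better than random"). Display percentages such as
"95% (144/152)" round half-up to integers; raw ratios are always kept in
the machine-readable output. Expression agreement (`codetected_r2()`) is
the squared Pearson correlation computed only over genes detected on both
platforms, on each platform's native comparable scale (e.g. log2 RPKM
against −ΔCT).

Microarray probes at risk of cross-species hybridisation are found by
scanning each 25-mer probe against the other species' transcriptome for
matches within 3 mismatches (`probe_cross_species_risk()`). Both strands
are scanned by default because probe orientation relative to the mRNA
depends on platform chemistry; `forward_only = TRUE` restricts the scan. A
probeset is susceptible when any of its probes hits, and a gene when any of
its probesets is.

## The synthetic two-species generator

`simulate_genome_pair()` and `simulate_reads()` make the whole pipeline
testable without downloads. The defaults are the study conditions the
package targets: ortholog exon identity 0.85, host mixture fraction 0.15
(within the ~8–17% range typical of xenograft RNA), 50-base reads, one
transcript per gene with 2–5 exons of 120–300 b (introns 100–300 b,
intergenic gaps 200–500 b), log-normal per-transcript rates, and a per-base
sequencing error rate of 0.005 — a round figure for a trimmed short-read
platform after the low-quality bases are removed. Divergence between
ortholog exons is placed uniformly at random (no CpG or UTR structure):
the simplest model consistent with an average-identity statistic. Reads
are drawn per transcript proportional to rate × length, uniformly along
the spliced transcript (so a predictable fraction straddles junctions),
and are emitted strand-agnostically, matching the unstranded genome
mapping.

What the generator does *not* emulate: repeat families and low-complexity
sequence (so synthetic non-unique fractions are near zero, far below the
~15–18% of real mammalian genomes), fragment-size and GC bias, paralogy
within a species, pseudogenes, and realistic platform error profiles.
Passing tests therefore demonstrate the correctness of the set logic,
counting and score arithmetic, and recovery under idealised divergence —
not performance on real repeat-rich genomes.

## Problem sizes and numerical choices

The test suite exercises the k-mer mask against its oracle on ~50 kb
two-species workspaces at k ∈ {5, 12, 50}; the aligner against the
sliding-window oracle on 100 kb of references with 1,200 mixed
random/adversarial reads; mixture recovery at host fractions
{0.05, 0.10, 0.15, 0.20} with 50,000 reads each (estimates within ±0.02 of
truth); expression recovery on the default simulation (Spearman rank
correlation between true rates and RPKM ≥ 0.9 on transcripts with ≥ 10
reads); and the probe scan against an exhaustive Hamming oracle on a
300 kb transcriptome. These sizes were chosen so each property is checked
at a scale where the brute-force oracle is still exact.

Other conventions: internal coordinates are 0-based half-open everywhere,
with the GTF/BED converters owning the off-by-one (GTF inclusive start =
internal start + 1); all random generation is seeded through `sim_config()`
and reproduces byte-identical outputs; partition output is deterministic
(ties in gene representatives broken lexicographically; no unordered
iteration reaches any output).

## Limitations

* Mismatch-only alignment; indels and colour-space encodings are out of
  scope (trimming arithmetic is reproduced in base space).
* Desk-scale references: the seed index and the mask are built in memory
  and are not intended for whole mammalian genomes.
* Forward single-end reads only.
* Differential expression testing is deliberately not included; the
  package exports the five-column count table and the library-size/median
  size factors (`size_factors()`) that a count-based DE package consumes.
  Note this size-factor rule is the plain library-size ratio, not the
  median-of-ratios default of DESeq-style packages.
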