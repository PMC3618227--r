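---
title: "Methods: somatic tiering and integrative tumor genome analysis"
author: "somatier authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic tiering and integrative tumor genome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatier)
```

# Scope

`somatier` implements the downstream analysis of a paired tumor-normal
whole-genome and transcriptome sequencing study of a single tumor (the
bundled worked example is a B3 thymoma): filtering candidate somatic calls
by a per-variant confidence score calibrated against an orthogonal
validation set, excluding known population SNPs, classifying the survivors
into four functional tiers, annotating transcript consequences,
segmenting copy-number profiles and calling arm-level events, quantifying
the SNP depletion that hemizygous losses imprint on tumor call sets,
filtering structural-variant candidates by discordant-pair support and
reasoning about the resulting fusion transcript, and finally integrating
mutant-allele expression from RNA pileups.

Upstream machinery - read alignment, the sequencing vendor's variant
caller, deduplication, transcript quantification internals, and the
SIFT/PolyPhen2 predictors - is out of scope; their outputs are ingested as
data. Because the original study deposited no sequence data, everything is
exercised on inputs printed in its tables or on synthetic data produced by
the package's own generator.

# The somatic score filter and its calibration

Each candidate somatic variant carries a non-negative confidence score.
Filtering keeps variants with score *strictly greater* than the threshold
(default 0.1); the strictness mirrors the source analysis, which kept
calls "higher than" its cutoff, and is pinned by boundary tests.

`sensitivity_specificity()` evaluates a threshold against a validation
truth set (locus, score, confirmed yes/no from re-sequencing):
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) with score > t as the
positive call. At the default threshold on a 104-locus truth set the
reference operating point is roughly 94% sensitivity and 60% specificity,
and the synthetic validation generator encodes exactly that: confirmed
loci score above threshold with probability equal to the configured
sensitivity, unconfirmed ones with one minus the configured specificity,
uniformly within each side. Raising the threshold can only lower
sensitivity and raise specificity; this monotonicity is a property test.

# Known-SNP exclusion and the tier ladder

Known-variant exclusion removes any candidate whose (chromosome, position)
appears in any supplied population set, regardless of allele or frequency,
*before* tiering - an excluded variant never reaches any tier. The
remaining variants walk a precedence ladder, first match wins:

1. **Tier 1** - coding non-synonymous, frameshift, in-frame indel, splice
   site or miRNA locus, and *not* inside a segmental duplication;
2. **Tier 2** - UTR or ncRNA effect, or conservation score > 500 on the
   0-1000 phastCons-style scale;
3. **Tier 3** - not repeat-masked;
4. **Tier 4** - everything else.

Two genuinely open points were settled as follows. A coding variant inside
a segmental duplication is *demoted down the ladder* (to tier 3, or 4 when
repeat-masked) rather than given a fifth category: segmental duplication
only disqualifies tier 1, and the ladder already expresses "how much do we
trust/care" for the rest. A position uncovered by the conservation track
scores 0, because conservation tables omit unaligned bases. When no
conservation track is supplied at all, the clause is skipped with a
warning rather than failing the run. Both tier-2 clauses can fire at once;
both are recorded in the `reasons` trail, the tier is the same either way.

# Consequence annotation

One transcript per gene. Effects are decided by position class (CDS >
splice site > UTR > intron; gene biotype wins for ncRNA/miRNA genes), and
for CDS SNVs the affected codon is retranslated on the annotated strand to
separate synonymous from non-synonymous calls and to emit labels in the
conventional style (`R585H`, `S1756del`, `L1067fs`). Indels touching the
CDS are frameshift when the length difference is not a multiple of three,
in-frame otherwise. The splice-site window is the first and last two
intronic bases - the canonical donor/acceptor dinucleotides - which is the
minimal defensible reading of "splicing sites".

Translation uses an explicit codon table, terminates at the first stop,
and reports the offset of any non-ACGT base; `Biostrings::translate`
serves as an independent oracle in the tests, so the two routes stay
separate. The deleteriousness rule is deliberately simple: a variant is
"damaging" when SIFT *or* PolyPhen2 says so; with both predictions absent
the question is undefined and raised as an error rather than defaulted.

# Copy-number segmentation

Probe-level log2 ratios are segmented by recursive rank-based binary
splitting. Within a candidate segment of $n$ probes with ranks $r_i$, each
admissible boundary $k$ is scored with the standardized rank-sum statistic

$$ z_k = \frac{\left| \sum_{i \le k} r_i - k(n+1)/2 \right|}
              {\sqrt{k(n-k)(n+1)/12}}, $$

the boundary maximizing $z_k$ is proposed, and the split is accepted when
its permutation p-value (the max statistic over boundaries under probe
shuffling) is below `alpha`. Accepted splits recurse into both halves.
Defaults: minimum 5 probes per segment, `alpha = 0.01`, 1000 permutations,
a fixed seed (restored after use, so the caller's RNG state is untouched).
Ranks make the statistic robust to heavy-tailed probe noise; the
permutation test on the *maximum* controls the false-split rate per tested
boundary family, which a 200-replicate null simulation verifies.

Segments are called gain/loss/neutral by strict log2 thresholds
(default ±0.2, the conventional single-copy bound for impure tumors; the
generator simulates events at ±0.4 with probe noise sd 0.1). An arm is
called when one state covers more than half of it (coverage fraction 0.5,
a majority rule - "arm level" should mean most of the arm), and agreeing
p and q calls merge into a whole-chromosome event. Chromosomes without an
annotated centromere only receive whole-chromosome calls.

# SNP depletion under hemizygous loss

In a hemizygous loss, one haplotype disappears from the tumor cells, and
with it every heterozygous germline SNP whose variant allele sits on the
lost haplotype - about half of the heterozygous SNPs in the region. The
per-chromosome measure is $100 (N - T)/T$ (percent more SNPs in normal
than tumor), and the loss/neutral group contrast uses a two-sided Welch
t-test, chosen because the two groups have very unequal variances (the
reference analysis reports spreads of about 11% vs 2%); the test named in
the source is unstated. Identical groups (zero variance) yield an `NA`
p-value rather than an error. The comparison unit is the chromosome,
matching the reference analysis's presentation; the loss labels are an
explicit argument, so arm-level units are a caller-side choice.

The generator implements a single coherent tumor model: with purity $p$
(default 0.8, matching a specimen with >80% cancer cells) a lost SNP is
still observed with probability $1 - p$ (the admixed normal cells carry
it), so the expected depletion on a loss chromosome with heterozygous
fraction $h$ (default 0.6, a typical human het:hom ratio of 2:1) is
$100\,(hp/2)/(1 - hp/2)$; at purity 1 and $h = 0.6$ this is the 42.9%
closed form the tests check by Monte Carlo. The same purity parameter
drives RNA pileup allele fractions ($p/2$ in neutral regions, $p/(2-p)$
under loss, $p/(2+p)$ under a single-copy gain). Independent per-SNP
no-call noise (default 1%) gives neutral chromosomes the small nonzero
scatter real call sets show.

# Structural variants and fusion transcripts

Candidate junctions are kept when supported by strictly more than 20
discordant pairs *and* spanning strictly more than 5 kb - both bounds
strict, mirroring "more than 20" and "larger than 5 kb". On the bundled
ten-cluster example exactly three candidates survive.

Each breakend records which side of its chromosome the derivative retains
(`+` keeps lower coordinates, `-` higher; junction files commonly encode
directionality this way, and the convention is stated rather than
inherited). Orientation is named by the transcriptional direction facing
the junction from each side: a retained fragment containing a gene's 5'
end is transcribed *toward* the junction, so its 3' direction faces it.
Two 3'-facing partners give a tail-to-tail (3'-3') fusion - both poly-A
tails lost, hence undetectable by poly-A-capture RNA sequencing, which is
exactly how detectability is modeled; 5'+3' is a conventional
head-to-tail chimera (poly-A retained, detectable); 5'+5' head-to-head
retains no promoter and no transcript is predicted.

The predicted transcript follows the driver (the partner that kept its
promoter; the left partner breaks ties): its spliced exons up to the
breakend, the retained intron up to the junction when the breakend is
intronic (flagged `retained_intron`), then the other partner's retained
sequence read in the direction the derivative imposes. Reading frame
continues from the driver's CDS; the sequence downstream of the last
complete exon-encoded codon is scanned for the first stop, and the offset
is reported in codons from that point - the bundled example places an
in-frame TAA four codons into the retained intron. A stop that coincides
base-for-base with the acceptor gene's own terminator is not premature.
Nonsense-mediated decay is predicted when a premature stop lies more than
50 nt upstream of the transcript's final junction (the standard 50-nt
boundary rule; the breakpoint junction counts as a junction, consistent
with exon-junction-complex deposition on a spliced-and-joined transcript).

# Expression integration

FPKM is computed from its definition,
`fragments / ((exon_length/1000) * (total_mapped/1e6))`; quantification
internals (read assignment, confidence intervals) are ingested, not
re-implemented. RNA read accounting computes retained reads as
`mapped * (1 - duplication_rate)` - for the case-study inputs
(188e6 mapped, 36.6% duplicates) this gives 119.192e6; the source prints
119.02e6, an arithmetic inconsistency the package reports as computed
rather than matches. Each tier-1 gene receives exactly one status:
`not_transcribed` when FPKM rounds to 0.00 (two decimals, matching how
the reference tables treat zero-expression genes), `no_reads` when
transcribed but uncovered at the variant site, `wild_type_only` at
fraction 0, `mutant_skewed` at or above the skew threshold (default 0.8,
a parameter - the reference calls 90% "preferentially expressed" without
defining a cutoff), else `both_alleles`.

# The synthetic-data generator

The generator emulates every input the pipeline consumes at desk scale
(13 chromosomes x 400 kb, 20 genes, 1e4 germline SNPs, ~1e2 somatic
variants), so the full analysis runs in seconds while every stage can be
checked against known truth: protein-coding genes are written into the
random sequence as ATG + sense codons + TAA, somatic variants are placed
to realize configured per-feature-class counts, intergenic space is
tiled into labelled kilobase blocks that become the segmental-duplication,
repeat-mask and conservation tracks, the known-SNP set contains every
germline position plus decoys, and probe/cluster/pileup/validation tables
follow the models above. Every generator is deterministic under the
config seed (byte-identical files), and seeding is local - generators
restore the caller's RNG state.

What the generator does *not* emulate: realistic mutational signatures or
trinucleotide context, mapping artifacts beyond flat score distributions,
focal copy-number events, subclonal structure, or read-level data. Passing
tests therefore demonstrate that the analysis logic is correct under its
stated model, not that the thresholds would be optimal on a particular
real dataset.

# Coordinates, dialects and numerical choices

In-memory coordinates are 1-based closed throughout, the native convention
of the R/Bioconductor interval stack (IRanges/GenomicRanges) used for all
interval arithmetic; BED and bedGraph conversion happens at the
rtracklayer boundary, and the boundary semantics are pinned by tests
(a BED interval `10 20` contains 1-based point 11 but not 10). Variant
tables travel in two minimal dialects: a five-column TSV and an
eight-column VCF-style row with the somatic score under INFO key `SS`;
anchored indels are normalized to the empty-allele convention on read.
Variant class is always re-derived from the alleles, never trusted from
an input column. Multi-base variants are anchored at their range start
for track lookups.

Problem sizes in the tests and acceptance script (2,600-probe profiles,
104-locus validation sets, 200 null replicates, 15-replicate Monte Carlo
for the depletion closed form) were chosen so the whole suite completes in
about a minute while keeping Monte-Carlo standard errors well inside the
asserted tolerances.

# Known limitations

One transcript per gene, no isoform selection; splice-site reasoning stops
at the canonical dinucleotides; fusion prediction assembles sequence only
within the two partner genes and does not model breakpoint microhomology
or PCR-confirmability; copy-number segmentation assumes independent probe
noise; the depletion model treats haplotype loss as SNP-independent
coin flips rather than phased blocks. These match the resolution of the
analysis the package reproduces.
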