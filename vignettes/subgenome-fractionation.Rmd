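---
title: "Quantifying subgenome fractionation in an allotetraploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subgenome fractionation in an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After an interspecific hybridization and genome doubling, an allotetraploid
carries two complete parental chromosome sets — two *subgenomes*, here
called L and S after the long and short chromosome sets of an allotetraploid
frog. The two subgenomes do not erode symmetrically: one typically loses
more sequence, more genes and more regulatory elements than the other
(*biased fractionation*). `allofrac` implements a self-contained analysis
of this process against a diploid outgroup genome T: deletion calling from
whole-genome homology blocks, randomization tests of what kinds of sequence
the deletions removed, a test of the non-allelic homologous recombination
(NAHR) signature, codon-level evolution statistics and unitary-pseudogene
dating, nonsense-polymorphism and protein-complex summaries, and
regulatory-peak conservation and enrichment statistics.

Every stage is exercised end to end on a synthetic triplet-genome system
with a ground-truth ledger, so all parameter-recovery claims in the test
suite are about quantities the generator implanted on purpose.

## Deletion calling

A deletion "from" subgenome S is evidenced on the retained subgenome L as a
region that

1. aligns reciprocally to the outgroup but has zero reciprocal alignment to
   the sister subgenome (candidate footprint); candidate fragments within
   10 bp are merged, and candidates overlapping assembly gaps (N-runs of at
   least 10 bp) for more than 25% of their length are discarded;
2. has at least one reciprocal sister-subgenome block in each 500-bp flank;
3. has a small residual gap between the sister-side projections of the two
   flank anchors: at most 4 kb, and at least three times smaller than the
   retained span.

Two readings of the size rule are possible; we apply the 4-kb bound to the
*deleted-side* residual gap and compare it with the retained-side span.
This reading makes large clean deletions (big retained span, near-zero
residual gap) callable, which is the regime the size-frequency spectrum of
real calls occupies; the alternative reading (bound on the retained span)
would exclude exactly those calls. "Reciprocally aligned" for a flank means
an overlap of at least 50 bp (`min_flank_overlap`), a guard against 1-bp
anchors that the source method leaves unspecified. The flank anchor is the
block nearest the candidate, ties broken by block length. Merging happens
before gap-filtering, following the order in which the filters are stated.

## Randomization enrichment

Deleted basepairs overlapping a feature class (exons, introns, promoter or
enhancer peaks, ...) are compared with the mean and SD of 1000
per-chromosome shuffles of the deletions (`bedtools shuffle -chrom`
semantics: length preserved, chromosome preserved, uniform placement).
We report the log2 fold difference, a z-score and a two-sided normal-tail
p-value — the direction of the effect is carried by the sign of the fold,
since the underlying z-score recipe does not state a sidedness — with
Benjamini–Hochberg adjustment across all reported tests. Because the
deleted copy cannot be annotated, each class uses the homeologous feature
set of the *other* subgenome, projected through the inter-subgenome
alignment, as a proxy for the pre-deletion state. L and S are compared per
class by a Mann–Whitney test on per-chromosome fold values (the chromosome
is the statistical unit; pooling randomization replicates would overstate
n). Shuffled intervals may overlap each other by default; a
rejection-sampling non-overlapping mode exists because overlap-free packing
can bias nulls on dense chromosomes.

The test's null calibration is checked explicitly: with deletions placed
independently of a feature class, the fraction of nominal p < 0.05 over 200
simulated feature sets (200 randomizations each) must stay near the nominal
level.

## The NAHR signature

NAHR between homologous repeats on the same chromosome deletes the sequence
between them. Two observable consequences are tested on the retained
homeologs of called deletions: repeat elements overlapping retained regions
are longer than those overlapping length-matched random regions
(Mann–Whitney on the two length samples), and the 1-kb flanks of a retained
region resemble each other more than random same-chromosome window pairs.
"Resemble" is operationalized as global (Needleman–Wunsch) alignment
identity — matches over alignment columns — under a pinned scoring of
match +1, mismatch −1, gap open −2, gap extend −1; identity values are
scoring-dependent, so the scoring is recorded in the result. Note that the
random-region repeat sample is length-biased (long elements are hit more
often), which makes the length ratio conservative relative to a naive
density argument.

## Codon statistics and pseudogene dating

Per-gene "triangles" tie the outgroup ortholog and both homeologs in one
codon alignment. The ancestor at the L/S split is reconstructed per column
by Fitch parsimony on the rooted triplet ((L,S),T): ingroup agreement wins,
otherwise the outgroup arbitrates, and three-way disagreements become `N`
and drop out of rate counting. At the divergences involved (per-branch
synonymous divergence near 0.2), a three-taxon maximum-likelihood
reconstruction differs negligibly from parsimony, which is why the simpler,
oracle-testable method is used.

Ka/Ks per branch uses Nei–Gojobori (1986) counting with Jukes–Cantor
correction: per-codon synonymous site fractions averaged over both
sequences, multi-substitution codons averaged over all minimal substitution
paths (paths through stop codons excluded unless every path is blocked),
substitutions to stop codons counted as nonsynonymous in the site
calculation, and codon columns with gaps, ambiguity or stops excluded. The
implementation is a 64×64 codon-pair lookup table built once per session;
the test suite checks it exhaustively against an independent
path-enumeration oracle on all two-difference codon pairs.

A unitary pseudogene is dated from its nonsynonymous excess. If a gene
evolved at constrained ratio $\omega_f$ until losing constraint $t$ My ago
and neutrally ($\omega = 1$) afterwards, the branch-average ratio over a
branch of $T$ My is

$$\omega_{obs} = \frac{\omega_f\,(T - t) + t}{T}
  \quad\Longrightarrow\quad
  t = T\,\frac{\omega_{obs} - \omega_f}{1 - \omega_f},$$

clamped to $[0, T]$. $\omega_f$ is taken from the functional homeolog's
branch (the most direct reading of "the gene's evolving rate average");
with additional one-to-one orthologs it would be the mean over functional
branches. $T$ defaults to 34 My (the subgenome split), with the
hybridization marker at 17 My; neither is estimated by this package — they
are required configuration. Confidence intervals come from resampling
aligned codon columns with replacement to the original codon count, 1000
replicates by default, 2.5/97.5 percentiles, with the point estimate always
taken from the unresampled alignment; replicates without synonymous signal
are dropped, and the interval is flagged unreliable when more than half
drop. Percentile bootstrap intervals on a clamped estimator undercover
slightly near the boundaries of $[0, T]$, which is why the recovery tests
require 85% rather than nominal 95% coverage.

## Gene-loss bookkeeping

Four non-exclusive pseudogene features are evaluated per copy: a premature
stop codon (frame anchored to the codon alignment, so a downstream
frameshift cannot fabricate stops), a frameshift (a gap run whose length is
not a multiple of 3), a coding sequence at least 50% shorter than *both*
the homeolog and the outgroup ortholog, and loss of at least 75% of the
homeolog's promoter (the H3K4me3 peak overlapping its TSS, falling back to
TSS ± 500 bp) where "lost" means unaligned to the tested subgenome or
projected into called deletions. A *likely pseudogene* additionally
requires expression at least tenfold below the homeolog with the homeolog
expressed (TPM ≥ 1 by default; a stricter no-expression mode exists for
date histograms). Exclusive cause classes give deletion-linked features
priority over point features, matching the observation that deletions are
the prevalent cause; the priority is a parameter.

Nonsense (premature-stop) variants are annotated by substituting the
alternate allele into the coding frame, strand-aware, for SNPs passing the
depth filters (total depth ≥ 10, alternate observations ≥ 4); agreement
with a whole-CDS mutate-and-translate oracle over random variants,
including minus-strand genes, is part of the acceptance suite. Dimer
retention compares the observed fraction of fully represented complexes
with both members single-copy against $q^2$ under independent loss; $q$
defaults to the member single-copy rate estimated from the classified
dimers ($q = (n_{one} + 2 n_{both})/(2n)$) because the published expected
fraction is not reproducible from the printed counts alone, and can be
overridden.

## Regulatory landscape

A peak is conserved when its projection through the whole-genome alignment
overlaps a peak in the target genome (≥ 1 bp by default). A peak is
subgenome-specific when zero basepairs of it align to either other genome —
the literal reading of "lacking any conservation"; a tolerance parameter
exists. Annotation enrichment of a peak subset uses the hypergeometric
upper tail with all same-mark peaks as the population, a peak counting as
overlapping an annotation when more than 50% of it is covered, with the
conventional reporting thresholds (p, fold, prevalence) exposed as
parameters. Active transcription is thresholded at background mean + 2 SD
per mark over random regions, both marks required, boundary values passing;
the labels are invariant under rescaling all signal by a positive constant.
The enhancer-proximity test partitions genes at TSS-to-nearest-enhancer
distance ≤ 5 kb (boundary inclusive) and compares log2 TPM by
Mann–Whitney.

Shared statistical kernels: the Mann–Whitney test enumerates all
assignments exactly (correct under ties) when $n + m \le 14$ and otherwise
uses the tie-corrected normal approximation without continuity correction;
chi-squared 2×2 tests are Pearson without continuity correction;
the hypergeometric tail and BH adjustment delegate to R's `phyper` and
`p.adjust`.

## The synthetic system

`simulate_system()` lays out every feature in a shared ancestral coordinate
space per chromosome and derives each genome by removing segments
(deletions; lineage-specific sequence as seen from the other genomes),
applying backbone substitutions, and splicing in coding sequences evolved
under the constraint model. Alignment blocks, annotations, variants,
per-gene codon alignments and the truth ledger all come from the same
layout, so blocks are exact by construction except across implanted events.

The defaults are the study conditions the pipeline is meant to recover: a
2:1 deletion bias against S (300 vs 150 deletions on a 10-Mb, 5-chromosome
system), log-normal deletion sizes (median 500 bp, capped at 3.5 kb so all
implanted deletions satisfy the call filters), subgenome split at 34 My and
hybridization at 17 My, neutral rate 0.0059 subs/site/My (per-branch
synonymous divergence ≈ 0.2), functional $\omega \sim \mathrm{Beta}(2, 8)$
(mean 0.2), pseudogenized copies biased 70:30 toward S with relaxation
times uniform on the branch, homeolog log-expression correlation 0.6 with a
small L bias (log2 bias 0.08 ≈ 6%), 40% of enhancer peaks conserved with
the outgroup and 20% subgenome-specific, and a subgenome-restricted repeat
family absent from the outgroup. Genes are 300 codons (400 in the dating
experiments — a typical vertebrate CDS length); coding sequences are
single-exon, which keeps the nonsense-annotation and truncation logic
exercised without modelling splicing.

Implanted pseudogene causes map onto the four feature classes: an explicit
premature stop; a 31-bp coding deletion (a frameshift that is also a real,
callable deletion); removal of 60% of the CDS; removal of 90% of the
promoter. NAHR-flagged deletions get an identical repeat copied across both
edges of the future retained region, with length (default 1.4 kb)
chosen so that both 1-kb flanks of the retained region expose the same
repeat interval — a global aligner then sees the homology without large
offset gaps. Subgenome-specific peaks sit in sequence removed from both
other genomes; "diverged" peaks sit in aligned sequence without a partner
peak, so conserved/diverged/specific fractions are all controlled.

What the generator does *not* emulate: realistic repeat evolution and
nested insertions, CpG and context-dependent mutation bias, indel length
hotspots, introns and alternative transcripts, chromatin-signal intensity
(peaks are intervals, not coverage tracks), alignment error, and assembly
artifacts beyond literal N-runs. Recovery tests therefore demonstrate
correctness of the statistical machinery on clean homology structure, not
robustness to aligner noise — on real data the deletion caller inherits
whatever reciprocality errors the whole-genome aligner makes.

## Numerical choices and degenerate inputs

All internal coordinates are 0-based half-open; GFF3 converts at the
boundary; VCF positions convert on read. Projection through a minus-strand
block reverses orientation but reports forward coordinates. Randomization
p-values with a zero-SD null are reported as degenerate (p = 1 when
observed equals expected, else 0) with a flag rather than NaN. Ka/Ks with a
proportion at or beyond the Jukes–Cantor singularity (p ≥ 0.75) is flagged
saturated; $\omega$ is undefined when Ks = 0. Mann–Whitney with all values
tied returns p = 1. The per-bin deletion size ratio reports `Inf` with a
flag when one side's bin is empty. Bootstrap replicates with no synonymous
signal are dropped, never imputed.

## Problem sizes used by the checks

The test and acceptance runs use a 10-Mb, 5-chromosome system for deletion
recovery (300 + 150 implanted deletions), 200 feature sets × 200
randomizations for null calibration, 200 genes × 200 bootstrap replicates
for dating recovery, 1000 random variants for the nonsense oracle, and a
2.4-Mb system for the byte-identity determinism check. These sizes were
chosen so each property is measured with useful statistical resolution on a
single desktop core; all of them are configuration, not constants.

## Limitations

Rearrangements and inversions are out of scope (the caller assumes
colinear, plus-strand flank anchors and drops candidates whose anchors
disagree). The NG86 estimator is adequate at these divergences but
underestimates at high divergence; it is pluggable. Dating assumes a single
loss-of-constraint time and full neutrality afterwards; partial relaxation
biases $t$ downward. The promoter-loss feature depends on the quality of
the homeolog's peak call. The complex-retention expectation assumes
independent loss across members, which is exactly the hypothesis being
tested, not a fitted model.
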