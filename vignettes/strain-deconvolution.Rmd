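---
title: "Coverage-based strain deconvolution, methylome calling and comparative genomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based strain deconvolution: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsieve)
```

This vignette is the package's account of the science behind each stage:
the models, the assumptions they rest on, the tunable parameters, what the
synthetic community generator does and does not emulate, and the design
choices made where the problem left the design open.

## The deconvolution model

A long-read metagenome of two near-identical strains has a characteristic
coverage structure when reads are mapped to a mixed draft assembly. Let
the dominant strain contribute depth $D_1$ and the minor strain $D_2$
($D_1 > D_2$). Then

* shared backbone regions collect both strains' reads: depth $D_1 + D_2$;
* regions unique to the dominant strain: depth $D_1$;
* regions unique to the minor strain: depth $D_2$.

Read binning turns this structure into strain assignments. For each read,
the depth profile $d(i)$ (number of best alignments covering position
$i$) is summarized over the read's alignment footprint — the median by
default, because a footprint that dips into a flanking region at one end
should not drag the read out of its bin — and the read enters every bin
whose depth intervals contain that statistic.

The default bins encode the published operating points of this workflow:
high $= (110, \infty)$, low $= [25, 120] \cup (225, \infty)$. The
boundary semantics are deliberate: the "greater than" cutoffs are strict,
the 25–120 range is inclusive at both ends, and the overlap of the two
bins above 225x (and in the narrow 110–120 band) routes deeply covered
shared sequence into *both* bins, so both strains can be assembled across
their common backbone. Bin refinement afterwards excludes reads whose
footprint sits below 100x, and contig triage keeps contigs with mean
depth above 190x.

These absolute cutoffs assume a community whose shared backbone is
around 300x. `assign_bins(relative = TRUE)` rescales every bound by
`median(depth) / calibration_depth` (calibration default 300) so the same
bin geometry can be reused at other sequencing depths. The thresholds
separate the strains when $D_2$ and $D_1$ fall inside the low and
high-only windows respectively; with the simulator defaults
($D_1 = 200$, $D_2 = 100$, backbone $300$) each class sits 2 standard
deviations or more from the nearest cutoff under Poisson depth noise,
which is what makes the binning recovery property hold robustly rather
than by seed luck.

**Scoring binning against truth.** Recall is membership: a strain-unique
read must be present in its strain's bin. Precision is computed over
*exclusively* routed reads only. A read in both bins is the scheme's
deliberate shared-sequence fallback — it will be used for both
assemblies, which is conservative, not wrong; the error mode that matters
is a read routed exclusively to the wrong strain. `binning_performance()`
implements exactly this definition.

**Multi-contig targets.** Depth is computed per target and assignments
aggregate across targets; a read's footprint statistic comes from the
single target its best alignment names. This is an assumption the
workflow's description leaves open.

## Genome finishing

A closed circular chromosome assembled from long reads carries its origin
twice: the contig's start reappears at its end. `circularize()` seeds
candidate overlap lengths by matching the sequence's first bases against
its terminal region, verifies each candidate base by base, and accepts
overlaps with mismatch fraction at most `max_mismatch_frac`
(default 0, i.e. exact). The longest qualifying overlap is trimmed. Two
tie-break rules are explicit rather than silent: when several overlap
lengths qualify (degenerate termini such as homopolymers) the longest
still wins but the result is flagged `ambiguous`; and the circular
sequence is reported as its lexicographically smallest rotation, so the
same chromosome cut at different points canonicalizes identically —
`circularize(linearize(g, cut, k))` recovers the same canonical form for
any cut.

Junction support is counted on the doubled representation (genome
concatenated with its own leading bases) so that alignment records stay
linear: a read supports the junction when its single best alignment
covers `junction ± flank` contiguously.

## The methylome model

Single-molecule sequencing slows at modified bases, so per-site kinetics
(log-transformed interpulse durations) carry a methylation signal. For
each genomic position and strand the input is a pair of summaries:
observed mean/sd/n and an unmethylated control mean/sd/n. The score is a
one-sided Welch two-sample t-test of `obs_mean > ctrl_mean`:

$$ t = \frac{\bar{x}_o - \bar{x}_c}{\sqrt{s_o^2/n_o + s_c^2/n_c}}, $$

with Welch–Satterthwaite degrees of freedom, and the modification QV is
the Phred-like $-10\log_{10} p$, capped at 1000. The Welch flavour is the
right default because observed and control sample sizes and variances
differ by construction; the cap keeps saturated sites finite. Calls are
retained at QV ≥ 100 (boundary inclusive), which corresponds to
$p \le 10^{-10}$ — across the ~$2\times10^5$ tests of a 100 kb genome the
expected number of false calls under the null is $2\times10^{-5}$, which
is why an unmethylated genome yields an empty call set and why motif
discovery on such a genome returns nothing. Only 6mA and 4mC are ever
typed (A and C bases); 5mC is not callable without chemical conversion of
the template, so cytosine calls are 4mC or unknown.

**Motif discovery** is a greedy specific-to-degenerate search. Contexts
(±7 bases, 5'→3' on the called strand) are extracted around every
retained call. The seed is the exact word, anchored at the methylated
base, that explains the most remaining calls subject to a genome-wide
methylated fraction of at least `min_frac` (default 0.3) — the fraction
constraint is what stops short generic words (every called adenine has
*some* 2-mer context) from seeding. The seed is then generalized one
IUPAC position at a time; a generalization is accepted only if it *gains*
methylated occurrences and keeps the genome-wide fraction above
`min_frac`, which lets `GGACC` grow into `GGNCC` (each step adds planted
sites) but stops `GATC` from degenerating into `RATC` (the added
occurrences are unmethylated). Explained sites are removed and the search
repeats until fewer than `min_sites` (default 20) remain. The search caps
pattern length at 12 and degenerate positions at 3; the known
methyltransferase recognition motifs of this family of genomes fit well
inside both caps.

**Counting conventions.** A self-reverse-complementary (palindromic)
motif matches the same locus on both strands; occurrences are reported
once per locus (forward orientation) by default, with
`count_per_strand = TRUE` as the alternative, since public motif tables
do not always state which convention they use. The intergenic fraction of
a motif is the fraction of detected occurrences whose methylated base
lies outside every gene model — the denominator choice (detected, not
methylated, occurrences) is recorded here because summary tables in the
literature leave it implicit. Mean coverage is per strand, averaged over
methylated occurrences.

## Comparative genomics

*GC statistics.* Windows are non-overlapping and anchored at position 0;
GC% excludes ambiguous bases from the denominator; skew is $(G-C)/(G+C)$
with the empty-denominator case reported as 0 and flagged. The deviant
window scan counts full windows whose GC differs from the genome mean by
at least 5 percentage points; the trailing partial window is excluded
from the count but still reported by `genome_stats()`.

*ANI.* The fragment scheme follows the OrthoANI definition: non-
overlapping 1020 bp fragments (tails discarded), each located on the
other genome by unique k-mer diagonal voting (k = 13) and aligned by
banded extension, fragment pairs retained when reciprocal best with
identity ≥ 70% over ≥ 50% coverage, ANI the mean identity over retained
pairs symmetrized across both directions. Self-comparison is exactly
100.0 with one pair per fragment, and on genomes with i.i.d. substitution
rate $r \le 0.05$ the estimate tracks $100(1-r)$ closely — with 1%
substitutions the alignment-column identity is slightly above 99% because
gap-free mismatch columns are the only penalty.

*Hit filtering and orthologs.* Query coverage is `aln_len / query_len`,
which exceeds 1 through gap columns — the only reading under which an
upper exclusion bound of 120% is meaningful. The exclusion bounds are
strict (≤ 75% and ≥ 120% are removed). Best-bidirectional-hit pairs use
max bitscore with evalue then lexicographic subject id as tie-breaks, and
the identity filter is applied before choosing bests (a flag inverts
this, since descriptions of the procedure are ambiguous on the order).
Hits normally arrive as 12-column tabular files from an external search
engine; the built-in exact Smith–Waterman aligner (Biostrings underneath,
with an explicit empty-alignment score floor of 0) generates hits only
for small synthetic gene sets and refuses genome-scale inputs past a size
cap.

*Gene presence.* A gene base is covered when any read alignment overlaps
it (depth ≥ 1); a gene is absent at zero coverage and partial when more
than 25% of its length is uncovered. "Any coverage" is the weakest
defensible reading of "uncovered" and is recorded here as a choice.

## The synthetic community generator

The generator emulates the statistical structure the pipeline assumes,
with every condition fixed once:

* **Genomes.** One random backbone (default 300 kb); each strain applies
  its own substitutions at rate 0.006 (putting the two strains at ~98.8%
  pairwise identity, the intra-species range), 2 inversions and 2
  relocations of ~5 kb segments, and inserts 3 unique regions of ~15 kb —
  about 14% of the genome strain-unique, mirroring the unique-gene
  fraction observed between closely related strains of this kind, at the
  size scale of genomic islands. Rearranged segments reject overlaps
  rather than merging, which keeps truth bookkeeping exact.
* **Reads.** Log-normal lengths parameterized by the published median
  (2,558 bp; shape 0.55) clipped to the 500 bp–27 kb admission window;
  uniform substitution/insertion/deletion errors at equal rates (total
  10%), with no context bias — matching the error profile of the
  single-molecule platform the pipeline was designed around. Depths:
  combined 300x at a 2:1 dominant:minor ratio. Every read carries a truth
  alignment; `emit_sequences = FALSE` skips sequence construction for
  depth-only experiments at genome scale.
* **Draft-assembly projection.** `project_alignments()` maps truth
  alignments onto the contig set a mixed assembly would contain (shared
  backbone plus one contig per unique region), assigning each read to the
  contig holding the largest share of its footprint — the
  single-best-alignment contract. Depth consequently dips near insertion
  boundaries, as it does in real mixed assemblies.
* **Kinetics.** Site baselines vary (N(0, 0.3)); observed and control
  summaries are exact finite-sample draws (normal means, scaled-chi
  standard deviations) with per-pass sd 0.5, control n 500, observed n
  Poisson around the per-strand depth; methylated sites shift the
  observed mean by delta (default 1.0, i.e. 2 sd). Because the null is
  exactly the model the Welch test assumes, the scorer is calibrated by
  construction — a deliberate choice so that threshold behaviour can be
  tested analytically.

What the generator does **not** emulate: chimeric reads, context-specific
error or kinetic biases, pulse-level signal, partial (hemi-)methylation
patterns beyond independent per-site Bernoulli thinning, and more than
two strains. Tests passing on this generator therefore validate the
pipeline's logic and calibration, not its robustness to instrument
artefacts.

## Problem sizes and numerical choices

The validation suites run the binning recovery at the full study geometry
(300 kb backbone, ~36,000 reads), the methylome recovery on 100 kb at
200x per strand (200,000 scored sites), ANI on ~56 kb genomes (55
fragments per direction), and circularization on 8–15 kb circles with
500 bp overlaps — sizes chosen so each property is measured with
comfortable statistical margins while a full run stays in the minutes
range on one core.

Numerical details worth recording: p-values are computed on the log scale
(`pt(..., log.p = TRUE)`) so QVs near the cap do not underflow; the
best-alignment tie-break is matches, then block length, then input order;
circularization caps candidate overlaps at half the sequence; and the
canonical-rotation routine handles degenerate (periodic) sequences by
exhausting the comparison depth before taking the first candidate.

## Known limitations

* The binning stage consumes alignments; it does not produce them for
  real-scale data (use any long-read mapper emitting PAF; minimal SAM is
  accepted without CIGAR-aware identity).
* Assembly itself (error correction, contig construction, scaffolding)
  is out of scope; the package operates before and after that step.
* `aligned_fraction()` depends on the chaining behaviour of whatever
  aligner produced its input; it is not claimed to reproduce any
  particular published aligned-fraction value.
* Motif discovery assumes motifs are anchored words around the methylated
  base within the search caps; bipartite motifs with long spacers would
  need a larger `max_len` and would slow the search accordingly.
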