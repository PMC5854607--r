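# strainsieve

Strain deconvolution, genome finishing, methylome calling and comparative
genomics for long-read metagenomes of near-identical prokaryotic strains.

When a culture or enrichment harbours two (or more) strains of the same
species at different abundances, a long-read metagenome assembly collapses
their shared backbone and leaves strain differences as coverage anomalies:
shared regions carry both strains' reads and are very deep, regions unique
to the dominant strain sit at its depth, and regions unique to the minor
strain sit at a fraction of that. `strainsieve` implements the
computational pipeline that exploits exactly this structure, together with
a synthetic community generator so every stage can be validated against
ground truth at desk scale.

## What the package computes

**Coverage-based read binning.** Reads are routed to named coverage bins
by the depth of the region their single best alignment covers
(`d(i)` = number of alignment intervals containing position *i*; a read's
footprint statistic is the median depth over its interval). The default
two-bin scheme assembles the dominant strain from reads on regions
deeper than 110x and the minor strain from reads on 25-120x or >225x
regions; reads above 225x (shared conserved backbone) deliberately enter
both bins. Bin refinement drops reads on regions below 100x and deep
contigs are selected at >190x mean depth.

**Genome finishing.** `circularize()` detects the duplicated terminal
overlap of a closed chromosome (longest suffix-prefix match within a
mismatch tolerance), trims it and reports the canonical (lexicographically
smallest) rotation; `spanning_reads()` counts reads bridging the junction
on the doubled representation.

**Methylome.** Per-site polymerase kinetics (log interpulse durations,
observed vs. unmethylated control) are scored with a one-sided Welch
two-sample t-test; the modification QV is Phred-like, `-10 log10 p`,
capped at 1000, with calls retained at QV >= 100. Around the called
bases a greedy specific-to-degenerate search discovers IUPAC recognition
motifs (6mA and 4mC), and `motif_summary()` reports per motif the
occurrences detected, the methylated fraction, the intergenic fraction
and mean per-strand coverage.

**Comparative genomics.** GC content/skew scans with deviant-window
detection (1 kb windows, >= 5 percentage points from the genome mean);
fragment-based average nucleotide identity in the OrthoANI scheme
(1020 bp fragments, reciprocal best fragment pairs at >= 70% identity
over >= 50% coverage); 12-column hit-table filtering (identity >= 90%,
query coverage strictly between 75% and 120%); best-bidirectional-hit
ortholog pairs; unique-gene sets; aligned genome fraction at >= 95%
identity; and gene presence/partial/absent classification from read
coverage (partial when more than 25% of the gene is uncovered).

**Synthetic community generator.** `simulate_strain_pair()` builds two
strain genomes from one shared backbone (strain-specific substitutions,
inversions, relocations and unique insertions), `simulate_reads()` draws
long reads (log-normal lengths, median 2,558 bp, clipped to 500 bp-27 kb,
uniform substitution/indel errors) with per-read truth alignments, and
`simulate_kinetics()` emits per-site kinetic summaries with planted
methylation so that the downstream t-test is exactly calibrated.

## Worked example

```r
library(strainsieve)

cfg  <- strain_sim_config(seed = 1)          # 300 kb backbone, 300x shared
pair <- simulate_strain_pair(cfg)
sim  <- simulate_reads(pair$genomes, strain_depths(cfg), cfg,
                       emit_sequences = FALSE)
proj <- project_alignments(sim$alignments, pair)   # draft-assembly view
prof <- compute_depth_all(proj)
asg  <- assign_bins(proj, prof)              # default >110x / 25-120x & >225x
table(high = asg$high, low = asg$low)
```

```
       low
high    FALSE  TRUE
  FALSE     0  1653
  TRUE   3034 29438
```

Reads on the ~300x shared backbone land in both bins (29,438), reads on
dominant-unique regions (~200x) in the high bin only (3,034), and reads
on minor-unique regions (~100x) in the low bin only (1,653). Scored
against the simulator's truth for reads wholly inside strain-unique
regions, precision and recall of the strain assignment exceed 0.99 on
both sides (see `scripts/acceptance.R`).

The methylome stage on a 100 kb genome with GATC (99%) and GGNCC (60%)
planted at 200x per strand recovers exactly those two motifs:

```
  motif methyl_index mod_type n_detected n_methylated frac_methylated
1  GATC            1      6mA        412          409        99.27184
2 GGNCC            3      4mC        412          249        60.43689
```

## Command line

A thin CLI over the package functions is installed with the package:

```sh
strainsieve simulate --seed 1 --outdir sim_out
strainsieve bin --alignments sim_out/truth.paf --outdir bin_out
strainsieve run --config my.cfg --genome genome.fasta --kinetics kin.tsv --outdir out
```

Configuration files are flat `key = value` text mirroring
`pipeline_config()` fields.
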