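---
title: "Methods: detecting, assembling and dating nuclear mitochondrial sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting, assembling and dating nuclear mitochondrial sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(numtsome)
```

# The problem

Mitochondrial DNA fragments integrate into nuclear chromosomes and persist
there as NumtS (nuclear mitochondrial sequences). Once inserted, a NumtS
stops evolving under the fast mitochondrial clock and starts accumulating
nuclear-type changes, so the NumtS complement of a genome — its NumtSome —
is a fossil record of past mtDNA leakage. Characterising it requires five
computations, each implemented here as a separate module with a documented
contract:

1. a similarity search between the mitochondrial genome (query) and the
   nuclear genome (subject), yielding high-scoring pairs (HSPs);
2. purging of artefacts: contigs that are mostly mtDNA (sequencing
   contamination assembled into pseudo-contigs) and hits on random or
   unplaced sequences;
3. assembly of surviving HSPs into NumtS loci;
4. descriptive layers: per-base coverage of the mitochondrial genome,
   hotspot calling, repeat-element co-occurrence, summary statistics;
5. evolutionary layers: profile-HMM insertion dating and K2P/NJ phylogenies
   with a strict-clock calibrated timetree.

Every coordinate in the package is 0-based half-open. BLAST tabular files
are converted to and from their native 1-based inclusive convention at the
I/O boundary and nowhere else.

# Detection

`find_hsps()` is a self-contained seed-and-extend aligner: exact
`word_size`-mers (default 11) of the doubled mitochondrial sequence are
indexed, both strands of each subject are scanned, and each seed is
extended with a gapped X-drop dynamic program (match +1, mismatch −2, gap
open 2, gap extend 2, X = 25). The extended interval is realigned with a
banded global alignment to obtain identity, mismatch and gap counts, and an
e-value is computed from the Karlin–Altschul formula with fixed parameters
for the +1/−2 scheme (λ = 1.33, K = 0.621). These e-values are
approximations used only for thresholding at the conventional 1e-3 cut-off;
the aligner is a stand-in for BLAST, not a clone, and real BLAST tabular
output can be substituted at any point through `read_blast_tab()`. Working
on the doubled query makes the mitochondrial genome circular: hits may run
across the origin and are split at position 0 on output, which is exactly
what a linearised reference produces, and rotation duplicates are
collapsed.

Overlapping or nested hits are deliberately *not* collapsed at this stage;
purging and assembly own that decision.

# Purging

`occupancy_filter()` computes, per contig, the width of the **union** of
HSP subject intervals divided by contig length. The union matters:
overlapping hits must not inflate occupancy past 1. Contigs whose occupancy
is *strictly greater* than 0.80 are removed with all their HSPs — a contig
at exactly 80% is kept. `chrom_filter()` then drops hits whose chromosome
name contains (case-insensitively) any of the configured substrings,
defaulting to `random`, `chrun` and `unknown`, which match the UCSC naming
of random and unplaced sequences.

# Assembly

`assemble_numts()` merges same-chromosome, same-strand HSPs transitively
when the genomic gap between them is at most 2000 bp (inclusive at exactly
2000), or when the gap is *bridged* by a repeat element: exactly one repeat
interval overlapping at least 90% of the gap length. Opposite-strand
neighbours never merge, and merging conditions only on genomic distance and
orientation — mitochondrial coordinates of the members are carried along as
a reduced union for reporting, never consulted for merging. Two choices
here were genuinely open and are fixed as configuration defaults: the 90%
bridge-coverage fraction (the notion of a gap being "occupied by a single
repeat" is not otherwise quantified) and the inclusive 2000-bp boundary.
The bridge rule counts how many repeats individually cover ≥90% of the gap
and requires that count to be exactly one; additional small repeats inside
the gap do not veto the merge. Because bridging is not monotone in gap
length, merging is implemented as a true transitive closure (union–find
over qualifying pairs), and the test suite checks it against an O(n²)
brute-force closure on hundreds of random configurations.

# Coverage and hotspots

`mt_coverage()` counts, for every mitochondrial position, how many records
(HSPs by default; each member interval of assembled NumtS in the
alternative mode) contain it, using a difference array and a single
cumulative sum. Intervals with `mt_start > mt_end` wrap across the circular
origin and increment both ends. `call_hotspots()` reports maximal runs of
positions at or above a threshold — by default the 99th percentile of
nonzero counts, with absolute thresholds supported — joining runs that meet
at the origin and annotating each run with the overlapping locus names.

# Repeats and correlations

Flanks are strand-aware (the 5′ flank of a minus-strand NumtS lies
genomically downstream), 2 kb long for co-occurrence counting and 1 kb for
the dating subset, clipped at contig ends. A repeat element is counted in
every region class (5′ flank, locus, 3′ flank) it overlaps by at least one
base, so a boundary-straddling repeat counts twice; counts are also
normalised by the number of NumtS. `interval_subtract()` is the usual BED
subtract operation, and `re_free_subset()` selects NumtS with zero repeat
overlap in locus and both 1-kb flanks — the subset whose compositional
comparison with the mitochondrion is not confounded by repeat content.
`spearman_matrix()` reports rank correlations (average ranks under ties)
with two-sided p-values from the t approximation and a Bonferroni-adjusted
significance threshold; assembly contiguity statistics (N50/L50, gap size)
enter through a plain TSV.

# Insertion dating

The dating statistic for a NumtS is

\[
\Delta = \mathrm{score}_{\mathrm{mt}} - \mathrm{score}_{\mathrm{flank}},
\]

both terms natural-log odds (nats) of the NumtS sequence under a profile
HMM relative to an iid background. A fragment that still resembles its
mitochondrial source scores high against the mitochondrial profile
(Δ > 0, "recent"); one that has homogenised towards its nuclear
neighbourhood scores relatively higher against its own flank profile
(Δ < 0, "old").

The profile architecture is a simplified glocal plan: the full profile must
be traversed while any sequence prefix/suffix is emitted by the background
at zero log-odds; there is no multi-hit state. Match emissions are
pseudocount-smoothed column frequencies, `(count + c) / (n + 4c)` with
c = 1 by default, so a single-sequence profile is heavily smoothed toward
the background; insert states emit the background. Transition
probabilities are fixed and documented in `build_profile()`
(M→M 0.90, M→I = M→D 0.05, I→I = D→D 0.30, remainder to M; terminal
column exits to the end state). The forward recursion is implemented in
C++ and validated against exhaustive path enumeration on small cases to
1e-9 relative accuracy.

Two practical points matter. First, the mitochondrial profile is built
from the NumtS's own mt counterpart region as a single smoothed sequence
(a cross-species mitochondrial alignment is not assumed to exist).
Second, score differences are only meaningful between profiles of
comparable length: a glocal score against a much longer profile is
dominated by delete-state costs rather than composition. The flank profile
is therefore trained on a window of the NumtS's concatenated
(repeat-subtracted) flanks truncated to the NumtS length; if the flanks
carry more than 30% assembly gaps (`N`), a consensus profile over all
other NumtS flanks is used instead.

# Phylogeny

`k2p()` implements the Kimura two-parameter distance with pairwise deletion
of gap/N columns: with transition proportion *P* and transversion
proportion *Q*,

\[
d = -\tfrac{1}{2}\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big),
\]

raising a classed saturation error when the logarithm's argument is not
positive. `nj_tree()` is a Saitou–Nei neighbor-joining agglomeration with
deterministic tie-breaking (lexicographically smallest label pair) and
clamping of negative branch lengths to zero with a warning; trees are
`ape::phylo` objects and round-trip through Newick. Multiple alignment and
maximum-likelihood tree search are consumed, not reimplemented: the module
takes aligned FASTA as input. `species_pattern()` judges a species
monophyletic on the unrooted tree iff some edge bipartition separates
exactly its leaves. `calibrate()` midpoint-roots (or outgroup-roots) the
tree, measures node heights as the maximum root-to-tip path below each
node (which guarantees ages decrease from root to tips), and rescales so
the calibration node sits at the midpoint of the supplied age window,
defaulting to 95–105 Mya; the window endpoints give per-node age intervals.

# The synthetic genome generator

`simulate_genome()` is first-class, tested code, not a fixture. It
produces:

- an iid background nuclear genome (configurable GC, default 0.5 — chosen
  to maximise the contrast between mt-derived and background sequence for
  detection tests) of 5 × 400 kb chromosomes by default;
- a 16-kb mitochondrial genome tiled by named loci, with the control
  region ("CR") last so it abuts the circular origin as the vertebrate
  D-loop does;
- 50 planted NumtS with ages drawn from a grid (default 0, 0.05, 0.10,
  0.15 substitutions/site) and lengths 300–5000 bp, decayed under a K2P
  substitution process (κ = 4, a typical mammalian mtDNA
  transition/transversion ratio) plus single-base indels at
  `indel_rate × age` events/site (default ratio 0.1, about one indel per
  ten substitutions); minus-strand insertions are reverse-complemented;
  40% of insertions contain a 100-bp focal "seeding unit" in the middle of
  the control region, which creates a coverage hotspot there by
  construction;
- contamination contigs: three verbatim mtDNA contigs (occupancy 1) and
  partial contigs at occupancies 0.85, 0.85, 0.5, 0.5 — straddling the
  0.80 purge threshold from both sides;
- repeat annotations placed in the 2-kb flanks, with an optional
  constructed pair of fragments 3 kb apart bridged by exactly one repeat
  to exercise the bridging rule.

Planted insertion points keep at least 8 kb of background between them so
that independently planted NumtS cannot merge during assembly and recovery
can be scored 1:1. Ground truth (final coordinates, strand, mt interval
with `mt_start > mt_end` flagging origin wrap, age) is emitted in BED.
Identical configurations produce byte-identical FASTA/BED output.

What the generator does *not* emulate: real repeat sequence content (only
names and intervals), regional GC and composition heterogeneity of real
nuclear genomes, fixation dynamics of insertions, and assembly gaps beyond
explicit `N` runs. Tests passing on this generator therefore demonstrate
algorithmic correctness under the stated decay model, not performance on a
real assembly — with real data, detection sensitivity is set by BLAST and
the biology, not by this package.

## Simulation sizes used by the checks

The end-to-end recovery check runs the full default genome (5 × 400 kb, 50
insertions, 7 contamination contigs) and requires ≥90% of truth records to
be recovered 1:1 with ≤20 bp boundary error, all five over-threshold
contigs removed and both 0.5-occupancy contigs kept. The dating experiment
uses 30 insertions at ages 0–0.25 in steps of 0.05 on 2 × 200 kb
chromosomes with fragment length fixed at 600 bp: Δ scales with sequence
length, so fixing the length isolates the age response the check is about;
it requires Spearman ρ(age, Δ) ≤ −0.5 and every age-0 NumtS called
"recent" (observed ρ is about −0.97). Oracle checks (merge closure,
coverage/hotspots, forward algorithm, monophyly) run hundreds of small
randomized replicates against brute-force reimplementations.

# Numerical and degenerate-input choices

- Alignment scores are integers; e-values and bit scores are derived with
  fixed ungapped Karlin–Altschul parameters and are approximate.
- The banded statistics realignment uses a linear gap cost equal to
  open+extend, identical to the affine cost for the single-base indels the
  extension produces.
- `mt_coverage()` rejects intervals exceeding the mt length after
  unwrapping; zero-length intervals contribute nothing.
- `k2p()` errors (rather than returning NaN) on saturation and on empty
  column sets after pairwise deletion.
- NJ tie-breaks are deterministic; negative branch lengths clamp to zero
  with a warning rather than silently propagating.
- Constant variables yield `NA` correlations; fewer than three paired
  observations is an error.
- Empty HSP sets flow through purging, assembly, coverage and summaries as
  empty results with intact schemas.

# Command line

`inst/scripts/numtsome-cli.R` exposes the stages as subcommands
(`simulate`, `detect`, `purge`, `assemble`, `coverage`, `repeats`, `date`,
`phylo`, `tracks`, `schedule`, `all`) as a thin wrapper over the exported
functions; `all` runs the stages in dependency order on a simulated
genome. Interspecies compilations reuse the intraspecies code path with a
foreign mitochondrial query; `cross_compilation_schedule()` enumerates the
n intraspecies plus n(n−1) interspecies jobs for a label set.

# Known limitations

- The built-in aligner's e-values are not calibrated for gapped alignment;
  at very permissive thresholds its hit list will diverge from BLAST's.
- Profile-HMM scores are not comparable to HMMER bit scores; only signs
  and differences within this package are meaningful.
- The strict clock and midpoint rooting are simplifications; the timetree
  is only as good as the clock assumption.
- Dating calls on real genomes should be restricted to the repeat-free
  subset, as repeat content otherwise dominates the flank profiles.
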