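---
title: "mirbean: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirbean: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbean)
```

# Scope and model

`mirbean` annotates and characterises miRNAs from multi-organ plant
small RNA libraries without a reference genome. The unit of analysis is
the *tag*: a unique 16–30 nt sequence with one integer read count per
organ library, held in a `TagSet` (a `SummarizedExperiment` with the
sequence in `rowData`). All sequence handling is in the RNA alphabet
(T is aliased to U on input); emitted coordinates are 1-based inclusive.

The stage chain is fixed: preprocess → ncRNA filter → exact conserved
annotation → conservation filter → isomiR chain → precursor validation
(with rescue of discarded hits that align to a validated precursor) →
novel-candidate scoring → target scan → family expression. Each stage is
a pure function of its inputs and parameters, and `runPipeline()` records
every threshold, the seed and output checksums in a manifest, so a rerun
with one config is reproducible bit-for-bit.

# Conserved annotation and the conservation filter

Exact annotation uses hash lookup of the tag sequence in the
deduplicated mature reference set — equivalent to requiring an alignment
with identical size and nucleotide composition, and faster than running
an external aligner. The conservation filter keeps a hit iff it was
detected in at least `min_libraries = 2` organs **and** totals at least
`min_total = 15` reads; both bounds are inclusive ("fewer than 15
appearances" are removed, so exactly 15 stays). Discarded hits are kept
in a side table because precursor evidence can rescue them into the
expression stage.

Per-family locus numbers treat two matures as derivable from one locus
when one is an extension, truncation or shift of the other: a
zero-substitution ungapped alignment with at most 2 nt of terminal
offset per end (the same offset cap as the isomiR matcher). Locus count
is the number of equivalence classes under the transitive closure, which
makes it order-invariant. On the packaged tables this collapses the
eight miR156 matures to 6 loci and the two miR157 matures to 1. The
packaged loci table lists 6 loci for miR159's eight sequences, which the
zero-substitution collapse alone does not reproduce; the table is used
as printed and the discrepancy documented rather than special-cased.
Both published cross-species Pearson coefficients (0.78 with soybean,
0.21 with *Medicago*) reproduce from all 33 rows of that table.

# The isomiR chain

Candidate variants are residual tags with a **strict** total of more
than 10 reads across libraries (per-library thresholds would eliminate
printed variants detected in only two organs). `fuzzyMatch()` scans all
ungapped alignments with per-end terminal offsets ≤ 2 nt, length
difference ≤ 2 nt and ≤ 2 substitutions *inside the overlap* — terminal
overhangs are offsets, never mismatches, which is what lets a 2-nt
shift at equal length (offsets +2/−2) qualify with zero substitutions.
Ties prefer fewer substitutions, then smaller total offset, then the
reference with more observed reads, then the lexicographically smaller
name.

The abundance filter is **inclusive**: a variant is retained when its
total is ≥ 1.5× the observed total of its reference (a printed variant
with 24 reads against a 16-read reference passes only under the
inclusive reading); when the reference was never observed, only the
single most abundant variant of that reference survives. Classes then
partition retained calls: zero substitutions → length variant; otherwise
conserved or non-conserved by whether the reference family is in the
conserved set. Families outside the conserved set whose retained
variants sum to ≥ 1000 reads are promoted; the threshold is a reasoned
substitute for "highly abundant in all four libraries", which the
printed table itself does not satisfy literally (one promoted variant
is absent from one organ). On the packaged isomiR table this chain
retains all 26 variants, reproduces the printed 7/9/10 group split row
by row, and promotes exactly the families 1510, 2199, 4376 and 479.

For the packaged-table re-analysis the reference set is the set of
reference miRNAs printed alongside the variants. Against a full
reference collection the best alignment for a handful of variants would
shift to a different same-family reference (e.g. a pure truncation of an
abundant conserved mature), changing labels that the original analysis
assigned differently; using the printed reference entries is the only
reading consistent with the printed group memberships, and it is how the
fixture run and the acceptance checks are defined. `fuzzyMatch()` itself
takes an arbitrary reference set.

# Folding engine and precursor validation

Folding uses a simplified nearest-neighbour model: stacking energies for
Watson–Crick and G:U pairs from a versioned, strand-reversal-symmetric,
all-negative table shipped in `inst/extdata/stack_energies_v1.tsv`
(values adapted from published Turner-style parameters and
symmetrised), with logarithmic loop penalties — hairpin(n) = 5.4 +
1.08 log(n/3) (n ≥ 3), bulge(n) = 3.8 + 1.08 log n, internal(n) = 1.7 +
1.08 log(n/2) — and interior loops capped at 10 unpaired bases per side.
Multibranch loops are excluded: precursor validation only needs single
stem-loops and a stability score, and the restriction keeps the dynamic
programme exactly checkable against an explicit structure-enumeration
oracle (the test suite verifies equality on hundreds of random
sequences, and that every reported energy recomputes from the reported
dot-bracket). The DP is written in C++ (Rcpp) as is usual for
quadratic-and-worse sequence recursions in this tier of packages.

Candidate windows come from exact full-length occurrences of a mature in
the EST/GSS set (both strands); because the arm carrying the mature is
unknown, three windows are cut per occurrence — mature near the window's
5' end, centred, and near the 3' end — with total extent ≈ 2×`flank`
(default 60 nt, plant precursor scale; the published analyses used
database sequences of similar extent). Validation requires: (a) the
mature entirely on one arm of one stem-loop, tolerating at most 4
loop-proximal unpaired bases (real matures border the terminal loop;
the planted 2-nt 3' overhang geometry feeds 2 such bases); (b) ≥ 60 %
of mature bases paired; (c) ≤ 2 asymmetric bulges of ≤ 3 nt in the
mature/star duplex; (d) normalised MFE ≤ −0.25 kcal/mol/nt. The star
interval is the pairing partner of the mature shifted to leave 2-nt 3'
overhangs. The thresholds follow common plant-miRNA annotation
practice; the cited historical criteria do not pin exact numbers.

Novel candidates take abundant residual tags (≥ 20 reads, 18–25 nt) as
putative matures, and score validated windows from the read signature:
`log(1 + mature) + star_bonus·[star > 0] − penalty·inconsistent/total`
with star_bonus = 2, penalty = 4, keep threshold = 1. The additive form
is a transparent surrogate for probabilistic read-signature scorers: it
preserves their decisive property, that star evidence ranks a candidate
strictly above an otherwise identical one.

# Target prediction

Hybrids are intermolecular only. The same stacking table scores
consecutive pairs; mismatched columns cost 1.1 kcal/mol, bulges (≤ 3 nt)
2.6 + 0.4/nt, and unpaired miRNA termini 0.3/nt, so the exact reverse
complement is provably the optimal same-length window. Diagrams use the
`|`/`x`/`*`/`-` notation with G:U wobbles marked `x` and never counted
as mismatches. Because printed hybrid energies vary strongly with miRNA
length and GC content, the call threshold is a *ratio* to the miRNA's
perfect-complement energy (default 0.7) rather than an absolute cutoff;
TAS3 detection scans directly for two non-overlapping miR390 sites at a
relaxed 0.55 ratio, reporting both sites and their spacing. Site
homology annotation (translated searches) is out of scope.

# Expression

Counts of same-family matures are pooled per library; mature-star
sequences are excluded. Size factors are median-of-ratios over rows
with all-positive counts. They are defined up to the geometric-mean
reference: the invariant the implementation guarantees (and the tests
assert) is that *relative* factors are scale-equivariant — scaling one
column by c scales its factor relative to any other column by exactly
c, and a duplicated-then-doubled column gets exactly twice the
original's factor.

The variance-stabilising transformation replaces a locally fitted
variance function with the parametric negative-binomial closed form:
a single blind common dispersion α is moment-matched across rows
(treating libraries as replicates, Var ≈ μ + αμ²; negative estimates
clamp to 0 with a warning) and
t = (2/√α)·asinh(√(α·q)) is applied to normalised counts q, which tends
to 2√q as α → 0 and is strictly increasing in the counts. The
parametric form is a deliberate deviation chosen for transparency and
testability: the suite verifies the analytic limit exactly and that the
row-variance/row-mean regression slope on NB simulations (α = 0.1, 500
rows) is 0 ± 0.1. Clustering is Euclidean distance with complete
linkage on both axes (the R defaults of the tools the published
analysis named), with leaf orders exported for heatmaps and dendrograms
as Newick strings. Whether the leaf and root libraries remain sisters
under this VST on the packaged 33-family matrix is reported as a soft
check, not asserted: the exact published input matrix (which included
externally rescued entries) is not reconstructable from the packaged
tables — in the packaged run they are sisters.

# The synthetic-data generator

`simConfig()` freezes the study conditions: 60 genes in 40 families over
organs LL/RL/SL/FL; expected canonical-mature reads per gene log-normal
(median 120, sdlog 1), split across organs by Dirichlet(1.5) weights;
negative-binomial counts with dispersion 0.25; isomiR read ratios
relative to the canonical mature of 0.20 (3'+1), 0.18 (3'−1), 0.08
(3'−2), 0.06 (5'−1) and 0.08 (one internal substitution) — 3'
heterogeneity dominating, as it does in real data; star reads at 0.18 of
mature; 25 % of genes withheld from the reference set as novel; planted
target sites (0–2 G:U wobbles) for half the matures; and contamination
tags (ncRNA fragments plus random 16–30-mers) with a 24-nt length mode,
so that unique tags peak at 24 nt while redundant reads peak at 21 nt —
the hallmark size structure of plant small RNA libraries. Star arms are
reverse complements with 0–2 G:U-compatible substitutions, exercising
imperfect duplexes, and the annotated star window leaves 2-nt 3'
overhangs. A single seeded RNG stream makes all outputs byte-identical
per seed. Planted precursors are rejection-sampled until they satisfy
the hairpin validator on their own EST — generator–validator consistency
is part of the generator's contract, not an empirical observation.

What the generator does not emulate: sequencing error profiles,
position-specific quality decay (FASTQ export uses a constant Q40),
multi-locus gene families sharing one mature, RNA editing, and the
genuine 24-nt siRNA biology behind the size mode (contamination tags are
memoryless sequences). Passing recovery tests therefore demonstrates
correctness of the pipeline's logic under the stated statistical
structure, not performance on real libraries.

Ground-truth metrics condition on detectability: conserved recall is
computed over non-novel genes whose *expected canonical* reads total at
least 15 (the quantity the conservation filter sees), novel recovery
over novel genes with at least 20 realised reads. Under the default
conditions three-seed averages give conserved recall ≳ 0.97, precursor
validation 1.0, target recall ≈ 1.0 and novel recovery ≈ 1.0.

# Numerical and interface choices

* Deterministic ordering everywhere: tags by decreasing total then
  sequence; target calls by energy; ties in fuzzy matching resolved by
  the documented cascade. Reruns with one seed are byte-identical.
* Degenerate inputs: empty FASTA → empty result (not an error);
  all-unpaired sequences fold to MFE 0; size factors error with guidance
  when no row is all-positive; zero-read candidates are dropped with an
  undefined score rather than scored 0.
* Problem sizes in the shipped tests and acceptance script — 15–60-gene
  simulations, ≤ 20-nt folding-oracle instances, 500-row VST
  simulations — were chosen so the full validation suite documents the
  method at laptop scale while exercising every code path.
* The pipeline is driven by an in-R structured config
  (`pipelineConfig()`, unknown keys rejected) rather than a shell
  entry point: the package's users run it from R scripts, and
  `scripts/acceptance.R` shows the scripted form.

# Known limitations

The energy model is intentionally reduced (no multiloops, no dangling
ends inside hairpins, simplified loop costs), so absolute MFE values
differ from full thermodynamic folders even though stem-loop geometry
and ranking — all the validator consumes — are preserved. The published
genome-scale outcomes that depended on 2010-era database snapshots
(precursor and novel-candidate counts, EST target counts, raw-read
yields) are out of scope by design; the packaged tables cover everything
recomputable from the printed results.
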