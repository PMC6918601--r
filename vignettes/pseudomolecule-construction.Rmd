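---
title: "From scaffolds to pseudomolecules: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scaffolds to pseudomolecules: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molscaf)
library(data.table)
```

# Scope

`molscaf` implements the post-assembly layer of a large-genome sequencing
project: it consumes sequence scaffolds (from any assembler), alignment
tables of barcoded linked reads (10X Chromium), Hi-C read pairs, and
genetic-map marker alignments, and produces chromosome-scale
pseudomolecules with an AGP layout, together with the diagnostics used to
curate them. Read alignment itself, contig assembly, gap filling and gene
annotation are out of scope; the package starts where the aligners stop,
at coordinate tables.

This vignette explains the model behind each stage, the parameters that
matter, and the design decisions taken where the underlying methods are
conventions rather than mathematics. Every empirical statement here is
recomputed by the test suite (`tests/testthat/`) or the validation script
(`scripts/acceptance.R`); none is imported from elsewhere.

# Molecule reconstruction from barcoded read pairs

A Chromium library partitions long DNA molecules (tens to hundreds of kb)
into droplets; all reads from one droplet share a 16 nt barcode. After
alignment, the physical molecules are reconstructed purely from
coordinates: read pairs with the same barcode on the same scaffold whose
start positions lie within `gap_max` (default 500 kb) of each other are
assigned to one molecule ([`call_molecules()`]); molecules shorter than
1 kb or supported by fewer than `min_pairs` pairs are discarded.

The 500 kb gap closes over the sparse sampling of a single molecule (a
molecule is covered by reads at perhaps 0.1--1x) while staying far below
the typical distance between two same-barcode molecules that happen to
land on one scaffold: with ~1 molecule per barcode per Gb of genome the
collision rate within 500 kb is negligible. Start-to-start gaps are used
(rather than end-to-start) so the rule is independent of read length
under the stated `(barcode, scaffold, start)` sort.

Pairs are pre-filtered at mapping quality ≥ 20 and apparent span ≤ 800 bp
(`read_pairs()`); a Chromium fragment's two reads come from one short
insert, so larger spans are mapping artefacts. Duplicates are collapsed
at the table level — identical `(scaffold, start, end, barcode)` — which
is the coordinate-space equivalent of alignment-level duplicate marking.

# Physical coverage and mis-join detection

Scaffolding errors join sequences that no physical evidence connects.
The detector profiles *molecule coverage*: scaffolds are divided into
200 bp bins and the number of molecules spanning each whole bin is
counted. At a chimeric junction no molecule crosses, so the junction bin
counts exactly the crossing molecules — zero — however the junction is
phased against the bin grid. (An earlier midpoint-based rule missed
junctions that fell between two bin midpoints once molecule ends
localized to within tens of bp of the join; whole-bin spanning removes
that phase dependence. Hi-C link coverage, which is only used to *flag*
regions for review, keeps the midpoint-stabbing convention at 1 kb bins.)

Coverage is then normalized for distance from the scaffold end: no
molecule extends past an end, so raw coverage ramps down there. The
expected count of a bin is the genome-wide mean raw count over all bins
at the same distance-from-nearest-end stratum (one bin wide), with strata
beyond 50 kb — about one molecule length, beyond which end effects
vanish — pooled into a single interior stratum. The cap matters: deeper
strata would be populated only by the longest scaffolds, which in a
chimeric assembly are disproportionately the chimeras themselves, letting
a trough set its own expectation and hide. The reported score is
`log2((raw + 1) / (expected + 1))`.

Breakpoints are bins whose normalized coverage falls below 1/8 (10X) or
1/16 (Hi-C) of the genome-wide average, at least 10 kb (10X) or 50 kb
(Hi-C) from scaffold ends, collapsed per contiguous run to the centre of
the minimum-count stretch, and thinned to one trough per 50 kb (deepest
kept). Two further rules are this package's own:

* **Baseline restriction.** The genome-wide average is taken over
  scaffolds ≥ 100 kb, so that short, end-dominated scaffolds do not
  depress it (all scaffolds are used if none qualify).
* **Flank recovery.** A trough is only called if coverage recovers to at
  least half the genome-wide average within 50 kb on *both* sides
  (evaluated within the trusted zone away from scaffold ends). A real
  chimeric junction sits between two well-covered flanks. A telomeric
  scaffold, by contrast, carries a genuine one-sided ramp — coverage
  decays over a molecule length towards the chromosome end and never
  recovers — and the pooled strata, dominated by the far more numerous
  internal fragmentation ends (where reconstructed coverage stays high
  almost to the cut), cannot absorb it. Without this rule telomeric
  scaffolds produce false cuts; with it, simulated telomere ramps are
  rejected while equal-depth two-sided troughs are kept.

`correct_to_fixpoint()` alternates detection and breaking until a round
yields no cut (bounded by `max_rounds = 10`), re-calling molecules from
the lifted pairs each round so molecule boundaries follow the cuts, and
lifting Hi-C links and marker alignments alongside. Hi-C troughs are
flagged in the audit log for visual review but never cut automatically:
only the 10X evidence is sharp enough for unattended breaking, and
confirmed Hi-C breakpoints can be applied through the curation-edit
table. Every cut is recorded with round, evidence, trough depth, and
original-coordinate position.

# Super-scaffolding on the molecule link graph

Scaffold joining uses a graph whose nodes are scaffolds and whose edges
count *linking molecules*: barcodes whose molecules touch the ends of
exactly two scaffolds (barcodes on three or more scaffolds are ambiguous
and dropped). A molecule supports a scaffold if it has at least
`min_pairs` read pairs there and lies within 100 kb of a scaffold end.
An edge is kept only if supported by `min_molecules` linking molecules
from **at least two libraries** — a single-library artefact (e.g. a
barcode collision amplified by PCR) cannot create a join — and, when both
scaffolds are anchored, only within one chromosome and 5 cM.

Each connected component is reduced to a maximum-weight spanning tree
(igraph MST on negated counts; edges pre-sorted by weight and endpoint
names, so tie-breaks are deterministic), and branches are resolved
iteratively: at a node of degree ≥ 3, incident degree-one tips shorter
than 10 kb are removed first (small repetitive fragments attract spurious
links), then the lowest-weight incident edges are cut until the degree is
at most two. The remaining simple paths are the super-scaffolds; every
scaffold ends up in exactly one (possibly as a singleton).

Member orientation compares the mean within-member positions of
molecules linking it to up to five members on either side: if downstream
links sit at higher coordinates than upstream links the member is
forward. When only one side is informative the mean is compared against
the member midpoint. Members without informative links default to
forward and are flagged, with the supporting molecule count recorded.

The whole construction is swept over `min_pairs` 2..10 ×
`min_molecules` 2..10 and the assembly with the highest super-scaffold
N50 (fixed 100 bp inter-member gap) is kept; N50 ties resolve towards
the more stringent thresholds. Support tables are computed once per
`min_pairs` and edges filtered per `min_molecules`, so the sweep costs
little more than one build; orientation is computed only for the
selected assembly, which the N50 score does not depend on.

# Anchoring to the genetic map

Markers are aligned to the assembly (best hit per marker: longest
alignment, then highest identity, then lexicographically smallest
scaffold for determinism) and joined with a genetic map. A scaffold is
assigned to the modal chromosome of its markers when at least
`min_markers = 2` align and the mode holds a `majority = 0.6` share; its
genetic position is the median cM of the concordant markers. The median
tolerates the occasional mis-mapped marker, which in population-derived
maps is a few percent. Anchors are lifted through every breaking and
merging step by transforming marker positions (`offset + p` forward,
`offset + (member_length - p)` reversed) and recomputing the consensus.

# Hi-C ordering and orientation

Within a chromosome, super-scaffolds are first ordered by consensus cM.
Genetic maps order at coarse scale but are blind within recombination
deserts (the pericentromeric plateau can hold most of a chromosome), so
contact density refines the order. Unit-pair contact weights count links
within 100 kb of the facing ends of both units, normalized by the window
sizes: whole-unit link totals grow with unit length, so long unit pairs
two steps apart would out-weigh a short unit's true adjacency, whereas
near-end density isolates the short-range decay signal.

Units without a cM are inserted greedily at the position maximizing the
gain in summed neighbour contact. Local refinement then accepts moves
that strictly increase the total adjacent-contact weight: adjacent
swaps, single-unit relocations, and 2-opt block reversals. Reversals are
essential — a reversed run changes the objective only at its two
boundaries, so swap and relocation moves can never undo one — but the
contact objective is direction-symmetric, so every move is additionally
required not to reduce cM monotonicity (count of non-decreasing adjacent
cM steps). Reversals inside cM ties are free; reversals across distinct
cM values, including whole-chromosome flips, are rejected. Passes are
bounded (default 30); only strict improvements are taken, so sparse
contacts leave the genetic order untouched.

Orientation uses the decay asymmetry: the end of a unit facing its
left-side neighbours must show more contact with them than the far end.
Links from the two near-end regions (up to 1 Mb, at most half the unit)
to units up to two positions away on each side are compared. Two
flanking units rather than one make the call robust to residual local
order errors; aggregating over the *whole* flank was measurably worse,
because with decay exponent ~1 the long-range tail contributes heavy
noise faster than signal. Units assembled as a single super-scaffold per
chromosome have no ordered neighbours at all, so before Hi-C
orientation, units are oriented by the genetic-map gradient along them
(`orient_by_cm()`): a negative correlation between within-unit marker
position and cM means the unit is flipped. Hi-C overrides where it has
contacts; the cM gradient decides otherwise.

# Curation and outputs

The curation table (`read_edits()`/`apply_edits()`) scripts the manual
inspection cycle: `invert`, `move`, `assign` (into or out of chrUn) and
`break` (delegating to the mis-join machinery). Edits apply in file
order and are audited. The practical loop is: build, plot contact
matrices (`plot_contact_matrix()`) and directionality tracks
(`directionality_bias()`, window 10 bins, pseudocount 1), fix what they
reveal, rebuild. An inverted block shows as a symmetric off-diagonal
block in the matrix and as a sign discontinuity pair in the track — the
validation suite demonstrates both the scar and its disappearance after
the scripted `invert` edit.

`build_pseudomolecules()` lays ordered, oriented units member-by-member
with 100 bp `N` gaps (AGP gap type `U`), collects unplaced scaffolds of
at least 1 kb into `chrUn`, and emits FASTA plus an AGP 2.1 layout that
round-trips bit-exactly through `read_agp()`. Coordinates are 0-based
half-open internally and converted to 1-based inclusive only at the AGP
boundary.

# The simulator and what passing means

`simulate_all()` generates the study condition used throughout the
tests: random nucleotide chromosomes (default 3 × 5 Mb) fragmented into
50 scaffolds each (minimum fragment 25 kb), stored under shuffled names
in random orientation; five inter-chromosomal chimeras formed by
concatenating fragments from different chromosomes at recorded
junctions; barcoded molecules from two libraries at 30-fold physical
coverage with lognormal lengths (mean 50 kb, sd 15 kb) and ~30 read
pairs per molecule — the pair density implied by a 30x-read-coverage
Chromium run scaled to desk-scale physical coverage; Hi-C links with
contact probability `(d + 10 kb)^-1` and 2% inter-chromosomal
background; and markers at 20 per Mb on a 1 cM/Mb map flattened over the
middle 20% of each chromosome, with 5% assigned a wrong chromosome.
Chimera partners are drawn from chromosome-interior fragments: a join at
a telomeric fragment sits on a genuine coverage ramp and has no
two-sided trough even in principle, so it is not representative of the
scaffolding-error class the detector targets.

Evidence is generated on the truth chromosomes and projected through the
recorded segments, so no molecule, link or read pair ever spans a
chimeric junction — the defining property of a false join. Everything is
deterministic in the seed.

The simulator emulates coordinates, not sequences being sequenced: there
are no base errors, no repeats, no multi-mapping, no barcode whitelist
errors, no restriction-site bias, and uniform coverage apart from end
effects. Passing the suite therefore shows that the *algorithms* recover
truth under the stated statistical structure at desk scale; it does not
show robustness to repeat-driven mis-alignment or library artefacts,
which in real projects are handled by the upstream aligner's mapping
quality and by visual curation. Problem sizes in the test suite (15--20
Mb genomes, 8--20 replicates per claim, a hundred-graph tree-optimality
suite) were chosen so the whole suite exercises every claim at full
parameter defaults in a few minutes on one CPU.

# Numerical conventions and degenerate inputs

* Deterministic tie-breaks everywhere: marker best hits (length,
  identity, scaffold name), MST edge order (weight, endpoint names),
  path direction (lexicographically smaller endpoint first), trough
  centre (middle of the minimal-count stretch), sweep selection
  (stringency on N50 ties), modal chromosome (count, then name).
* Empty inputs return typed empty tables; an empty FASTA warns; an
  empty marker table warns and leaves scaffolds unassigned; a chromosome
  without anchored units warns and falls to chrUn.
* Molecules split at a cut keep at least one read pair per piece, with
  pair counts divided proportionally to span; read pairs crossing a cut
  are dropped (a 300 bp pair cannot meaningfully split).
* Orientation of point lifts on reversed members follows
  `offset + (member_length - p)`.

# Known limitations

* Gap sizes between joined scaffolds are fixed (100 bp), not estimated;
  AGP consumers should treat them as unknown-size spacers.
* Hi-C normalization is square-root (coverage) balancing; fragment-level
  covariates (restriction density, GC, mappability) are not modelled —
  adequate for the ordering/diagnostic use here, not for quantitative
  contact analysis.
* The Hi-C ordering refinement is a local search; with very sparse
  contacts or pathological tie structure it returns a cM-consistent
  local optimum rather than a certified global one.
* Breakpoint precision is bounded by read-pair density around the
  junction (about one bin at the default densities), and junctions
  within the end-exclusion zone of a scaffold are undetectable by
  design.
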