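# molscaf

Chromosome-scale pseudomolecule construction from sequence scaffolds,
10X Chromium linked reads, Hi-C and genetic maps — the post-assembly
layer of a large-genome (think wheat or barley scale, run here at desk
scale) sequencing project, as an R package.

Assemblers leave two problems on the table: scaffolds contain
**mis-joins** (chimeras welding unlinked regions together), and they are
orders of magnitude shorter than chromosomes. `molscaf` addresses both
with the complementary long-range evidence types:

* **Molecule reconstruction.** Read pairs sharing a 10X barcode within
  500 kb on one scaffold are clustered into the physical DNA molecules
  they came from (`call_molecules()`).
* **Mis-join correction.** Molecule (and Hi-C) *physical coverage* is
  profiled in bins; a chimeric junction is a coverage trough below 1/8
  of the genome-wide average (after normalizing for distance from
  scaffold ends) with recovering flanks. Detected junctions are cut and
  all evidence is lifted, iterating to a fixpoint
  (`correct_to_fixpoint()`).
* **Super-scaffolding.** A graph with scaffolds as nodes and
  end-touching linking molecules as edge weights (edges require support
  from ≥ 2 libraries and genetic-map compatibility within 5 cM) is
  reduced per component to a maximum-weight spanning tree and then to
  simple paths; thresholds are swept over a 2..10 × 2..10 grid and the
  highest-N50 assembly kept (`sweep_and_select()`).
* **Pseudomolecule construction.** Super-scaffolds are anchored to
  chromosomes by marker consensus, ordered by cM with Hi-C
  contact-decay refinement, oriented by cM gradients and near-end
  contacts, and emitted as FASTA + AGP 2.1 with a `chrUn` bin
  (`order_superscaffolds()`, `orient_by_hic()`,
  `build_pseudomolecules()`). Contact-matrix heat maps and
  directionality-bias tracks (`directionality_bias()`) drive a scripted
  curation cycle (`apply_edits()`).

A seeded simulator (`simulate_all()`) generates truth genomes with
injected chimeras and all evidence tables, so the entire pipeline runs
and validates without external data.

## Worked example

```r
library(molscaf)

# a synthetic study condition: 3 chromosomes x 5 Mb, 50 scaffolds each,
# 5 injected inter-chromosomal chimeras, 2 Chromium libraries, Hi-C
sim <- simulate_all(sim_config(seed = 42))
sim$scaffolds
#> scaffold_set: 145 scaffolds, 15,000,000 bp (with sequence)

res <- run_pipeline(sim$scaffolds, sim$pairs, sim$hic_pairs,
                    sim$markers, sim$genetic_map)
res$fix$audit[action == "cut", .(scaffold, position, trough)]
#>          scaffold position    trough
#> 1: scaffold_00019    86700 -4.868565
#> 2: scaffold_00063    65100 -4.868565
#> 3: scaffold_00097   142300 -4.868565
#> 4: scaffold_00128   148900 -4.868565
#> 5: scaffold_00141   149700 -4.868565
res$sweep$best
#>     min_pairs min_molecules           n50
#>            10             3       5004905
res$pm$lengths
#>    chr2    chr3    chr1
#> 5004905 5004838 5004957

# compare against the simulation truth
ev <- eval_pseudomolecules(res$pm, sim$truth, res$fix$origin)
unlist(ev)
#> frac_correct_chr         mean_tau
#>        0.9999834        1.0000000
```

All five chimeras are cut (the `trough` column is the log2
observed/expected coverage ratio at the cut bin), the sweep assembles
each chromosome into a single super-scaffold (N50 ≈ 5 Mb), and 99.998%
of bases land on their true chromosome in the true order (Kendall's
τ = 1).

The same stages are exposed as a command line (`exec/molscaf`):

```sh
molscaf simulate --seed 42 --out data/
molscaf molecules --pairs data/pairs.tsv --out data/molecules.tsv
molscaf run --seed 42 --out results/
```

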