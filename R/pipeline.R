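#' Run the post-assembly pipeline end to end
#'
#' Orchestrates the full workflow on in-memory inputs: pair filtering,
#' chimera correction to fixpoint, scaffold anchoring, the super-scaffold
#' threshold sweep, anchor lifting, Hi-C ordering and orientation, and
#' pseudomolecule construction. Convenience wrapper used by the command
#' line interface and the validation suite; each stage is equally usable
#' on its own.
#'
#' @param scaffolds a [scaffold_set].
#' @param pairs linked-read pair table ([read_pairs()] or simulator).
#' @param hic_pairs two-sided Hi-C pair table.
#' @param markers marker alignment table.
#' @param genetic_map genetic map table.
#' @param config a [misjoin_config()].
#' @param min_pairs_grid,min_molecules_grid sweep grids (defaults 2..10).
#' @param gap inter-component gap in bp (default 100).
#' @param chrun_min_len minimum scaffold length for chrUn (default 1 kb).
#' @param verbose print stage progress.
#' @return A list with the corrected assembly (`fix`), `anchors`, the
#'   sweep result (`sweep`), the super-scaffold map (`ss_map`), unit
#'   anchors, the chromosome order, and the pseudomolecule build (`pm`).
#' @export
run_pipeline <- function(scaffolds, pairs, hic_pairs, markers, genetic_map,
                         config = misjoin_config(),
                         min_pairs_grid = 2:10, min_molecules_grid = 2:10,
                         gap = 100L, chrun_min_len = 1000L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  pairs <- filter_pairs(pairs)
  say("correcting mis-joins")
  fix <- correct_to_fixpoint(scaffolds, pairs, hic_pairs = hic_pairs,
                             markers = markers, config = config)
  say("anchoring ", length(fix$scaffolds), " scaffolds")
  anchors <- anchor_scaffolds(fix$markers, genetic_map, fix$scaffolds)
  say("sweeping link-graph thresholds")
  sw <- sweep_and_select(fix$molecules, fix$scaffolds, anchors,
                         min_pairs_grid = min_pairs_grid,
                         min_molecules_grid = min_molecules_grid, gap = gap)
  ss_map <- superscaffold_map(sw$membership, fix$scaffolds, gap = gap)
  unit_anchors <- lift_anchors(fix$markers, genetic_map, ss_map)
  unit_links <- lift_link_sides(fix$hic_pairs, ss_map)
  say("ordering super-scaffolds")
  ulen <- unique(ss_map[, .(unit, unit_length)])
  unit_lengths <- setNames(ulen$unit_length, ulen$unit)
  ord <- order_superscaffolds(unit_anchors, unit_links, unit_lengths)
  ord <- orient_by_cm(ord, attr(unit_anchors, "markers"), genetic_map)
  ord <- orient_by_hic(ord, unit_links, unit_lengths)
  say("building pseudomolecules")
  pm <- build_pseudomolecules(ord, ss_map, fix$scaffolds, gap = gap,
                              chrun_min_len = chrun_min_len)
  list(fix = fix, anchors = anchors, sweep = sw, ss_map = ss_map,
       unit_anchors = unit_anchors, unit_links = unit_links,
       chrom_order = ord, pm = pm)
}
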