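#' Anchor scaffolds to chromosomes and genetic positions
#'
#' Joins marker alignments with a genetic map and assigns each scaffold the
#' modal chromosome over its aligned markers, provided at least
#' `min_markers` markers align and the modal chromosome's share reaches
#' `majority`; otherwise the scaffold is left unassigned. The genetic
#' position is the median cM of the concordant (modal-chromosome) markers
#' — the median is robust to the occasional mis-mapped marker.
#'
#' @param markers marker alignment table ([read_marker_alignments()]):
#'   columns `marker`, `scaffold`, `position`.
#' @param genetic_map genetic map ([read_genetic_map()]): columns `marker`,
#'   `chromosome`, `cM`.
#' @param scaffolds optional [scaffold_set]; scaffolds without markers are
#'   then included as unassigned rows.
#' @param min_markers minimum aligned markers for assignment (default 2).
#' @param majority minimum share of the modal chromosome (default 0.6).
#' @return An anchor table: `data.table` with columns `scaffold`,
#'   `chromosome` (`NA` when unassigned), `cM`, `n_markers`,
#'   `n_concordant`.
#' @export
anchor_scaffolds <- function(markers, genetic_map, scaffolds = NULL,
                             min_markers = 2L, majority = 0.6) {
  mk <- as.data.table(markers)
  gm <- as.data.table(genetic_map)
  ann <- mk[gm, on = "marker", nomatch = NULL]
  if (nrow(ann) == 0L) {
    warning("no marker alignments match the genetic map; all scaffolds unassigned")
    anchors <- data.table(scaffold = character(), chromosome = character(),
                          cM = numeric(), n_markers = integer(),
                          n_concordant = integer())
  } else {
    anchors <- ann[, {
      tab <- sort(table(chromosome), decreasing = TRUE)
      ## deterministic modal pick: ties broken by chromosome name
      best <- names(tab)[order(-tab, names(tab))][1L]
      share <- tab[[best]] / .N
      conc <- chromosome == best
      if (.N >= min_markers && share >= majority)
        .(chromosome = best, cM = median(cM[conc]),
          n_markers = .N, n_concordant = sum(conc))
      else
        .(chromosome = NA_character_, cM = NA_real_,
          n_markers = .N, n_concordant = sum(conc))
    }, by = .(scaffold)]
  }
  if (!is.null(scaffolds)) {
    missing <- setdiff(scaffold_names(scaffolds), anchors$scaffold)
    if (length(missing) > 0L)
      anchors <- rbind(anchors,
                       data.table(scaffold = missing, chromosome = NA_character_,
                                  cM = NA_real_, n_markers = 0L,
                                  n_concordant = 0L))
  }
  setorder(anchors, scaffold)
  anchors[]
}

#' Lift anchors onto new units
#'
#' Transforms marker alignments through a membership map (breaking or
#' super-scaffolding) and recomputes the chromosome/cM consensus per new
#' unit with the [anchor_scaffolds()] rules. This implements the
#' lift-and-consensus step used whenever scaffolds are broken or merged.
#'
#' @param markers marker alignment table in member coordinates.
#' @param genetic_map genetic map table.
#' @param map membership map from old members to new units (see [lifting]).
#' @param ... passed on to [anchor_scaffolds()] (`min_markers`, `majority`).
#' @return An anchor table for the new units, plus the lifted marker table
#'   as attribute `markers`.
#' @export
lift_anchors <- function(markers, genetic_map, map, ...) {
  lifted <- lift_points(markers, map, "scaffold", "position")
  anchors <- anchor_scaffolds(lifted, genetic_map, ...)
  setattr(anchors, "markers", lifted)
  anchors
}
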