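#' Mis-join detection and correction parameters
#'
#' Bundles the thresholds of the chimera-correction loop. 10X molecule
#' coverage is profiled in 200 bp bins and a drop below 1/8 of the
#' genome-wide average is called a breakpoint; Hi-C link coverage is
#' profiled in 1 kb bins and drops below 1/16 of the average are flagged as
#' potential breakpoints for review (automatic cutting uses 10X evidence
#' only). Bins within `end_exclusion` of a scaffold end are never called:
#' coverage there is intrinsically low even after end-distance
#' normalization. The genome-wide average is taken over scaffolds at least
#' `baseline_min_len` long, to keep short, end-dominated scaffolds out of
#' the baseline (all scaffolds are used if none reach that length).
#'
#' @param bin_size_tenx,bin_size_hic coverage bin sizes (bp).
#' @param threshold_tenx,threshold_hic breakpoint thresholds as fractions
#'   of the genome-wide average coverage.
#' @param end_exclusion_tenx,end_exclusion_hic scaffold-end exclusion (bp).
#' @param min_separation minimum distance between breakpoints (bp).
#' @param baseline_min_len minimum scaffold length for the baseline (bp).
#' @param flank_bp,flank_frac flank-recovery condition (see
#'   [detect_breakpoints()]).
#' @param gap_max,molecule_min_len,min_pairs molecule-calling parameters
#'   (see [call_molecules()]).
#' @param max_rounds iteration cap for [correct_to_fixpoint()].
#' @return A list of class `misjoin_config`.
#' @export
misjoin_config <- function(bin_size_tenx = 200L, threshold_tenx = 1 / 8,
                           end_exclusion_tenx = 10000L,
                           bin_size_hic = 1000L, threshold_hic = 1 / 16,
                           end_exclusion_hic = 50000L,
                           min_separation = 50000L,
                           baseline_min_len = 100000L,
                           flank_bp = 50000L, flank_frac = 0.5,
                           gap_max = 500000L, molecule_min_len = 1000L,
                           min_pairs = 2L, max_rounds = 10L) {
  structure(as.list(environment()), class = "misjoin_config")
}

#' Detect chimeric breakpoints from a physical-coverage profile
#'
#' Candidate bins are those whose end-normalized coverage
#' `(raw + 1) / (expected + 1)` falls below `threshold_fraction` times the
#' genome-wide average of that quantity, excluding bins within
#' `end_exclusion` of either scaffold end. Contiguous candidate runs are
#' collapsed to their minimum-coverage bin (ties resolved to the middle of
#' the tied stretch), and breakpoints closer than `min_separation` on one
#' scaffold are pruned keeping the deepest trough.
#'
#' @param profile coverage profile from [molecule_coverage()] or
#'   [hic_coverage()].
#' @param threshold_fraction drop threshold: 1/8 for 10X molecule coverage,
#'   1/16 for Hi-C link coverage.
#' @param min_separation minimum breakpoint spacing in bp (default 50 kb).
#' @param end_exclusion bp excluded from each scaffold end.
#' @param baseline_min_len minimum scaffold length contributing to the
#'   genome-wide average (default 100 kb; all scaffolds if none qualify).
#' @param flank_bp,flank_frac flank-recovery condition: a trough is only
#'   a breakpoint if normalized coverage recovers to at least `flank_frac`
#'   times the genome-wide average within `flank_bp` on each side. A true
#'   chimeric junction sits between two well-covered flanks, whereas the
#'   gradual coverage ramp at a natural sequence end (e.g. a telomeric
#'   scaffold, where no molecule can extend past the chromosome end) never
#'   recovers on the distal side and is rejected.
#' @param evidence label recorded with each breakpoint.
#' @return A `data.table` with columns `scaffold`, `position` (bp, the
#'   trough-bin midpoint), `bin`, `trough` (log2 ratio at the trough),
#'   `evidence`.
#' @export
detect_breakpoints <- function(profile, threshold_fraction = 1 / 8,
                               min_separation = 50000L,
                               end_exclusion = 10000L,
                               baseline_min_len = 100000L,
                               flank_bp = 50000L, flank_frac = 0.5,
                               evidence = "tenx") {
  empty <- data.table(scaffold = character(), position = integer(),
                      bin = integer(), trough = numeric(),
                      evidence = character())
  prof <- as.data.table(profile)
  if (nrow(prof) == 0L) return(empty)
  prof <- copy(prof)
  prof[, norm := (raw + 1) / (expected + 1)]
  slen <- prof[, .(len = max(end)), by = .(scaffold)]
  prof[slen, len := i.len, on = "scaffold"]
  base <- prof[len >= baseline_min_len]
  if (nrow(base) == 0L) base <- prof
  gw_mean <- mean(base$norm)
  cand <- prof[norm < threshold_fraction * gw_mean &
               start >= end_exclusion & end <= len - end_exclusion]
  if (nrow(cand) == 0L) return(empty)
  setorder(cand, scaffold, bin)
  cand[, grp := cumsum(c(1L, diff(bin) != 1L)), by = .(scaffold)]
  troughs <- cand[, {
    ## collapse the run to the centre of its minimum raw-count stretch
    ## (raw, not norm: the normalized value wiggles with the expected
    ## strata and would bias the pick within an all-zero trough)
    lowest <- which(raw == min(raw))
    k <- lowest[ceiling(length(lowest) / 2)]
    .(position = as.integer((start[k] + end[k]) %/% 2), bin = bin[k],
      trough = ratio[k], depth = norm[k])
  }, by = .(scaffold, grp)]
  ## flank-recovery: both sides must come back up to flank_frac * mean
  bsz <- attr(profile, "bin_size")
  if (is.null(bsz)) bsz <- as.integer(stats::median(prof$end - prof$start))
  fb <- max(1L, as.integer(flank_bp %/% bsz))
  lev <- flank_frac * gw_mean
  troughs <- troughs[, {
    ## flank bins restricted to the trusted zone away from scaffold ends,
    ## where the pseudocounted norm is meaningful
    sc <- prof[scaffold == .BY[[1]] & start >= end_exclusion &
               end <= len - end_exclusion]
    keep <- vapply(bin, function(b) {
      left <- sc[bin >= b - fb & bin < b, norm]
      right <- sc[bin > b & bin <= b + fb, norm]
      length(left) > 0L && length(right) > 0L &&
        max(left) >= lev && max(right) >= lev
    }, logical(1))
    .SD[keep]
  }, by = .(scaffold)]
  if (nrow(troughs) == 0L) return(empty)
  ## enforce min_separation: greedily keep the deepest trough
  out <- troughs[, {
    setorder(.SD, depth, position)
    kept <- integer(0)
    for (i in seq_len(.N)) {
      if (all(abs(position[i] - position[kept]) >= min_separation))
        kept <- c(kept, i)
    }
    .SD[sort(kept)]
  }, by = .(scaffold)]
  ev_label <- evidence
  out[, evidence := ev_label]
  setorder(out, scaffold, position)
  out[, .(scaffold, position, bin, trough, evidence)]
}

#' Break scaffolds and lift the evidence
#'
#' Cuts scaffolds at the given breakpoints and renames the pieces
#' `<scaffold>_p1`, `<scaffold>_p2`, ... left to right (scaffolds without
#' cuts keep their names). Sequences, when present, are split accordingly.
#' Supplied evidence tables are lifted into piece coordinates: interval
#' records (molecules, pairs) overlapping a cut are split per piece, with
#' molecule pair counts divided proportionally to piece span; two-sided
#' link records have each side reassigned independently; marker records
#' are point-lifted.
#'
#' @param scaffolds a [scaffold_set].
#' @param breakpoints `data.table` with columns `scaffold`, `position`
#'   (from [detect_breakpoints()] or curation).
#' @param pairs,molecules,links,markers optional evidence tables to lift.
#' @return A list with `scaffolds` (new [scaffold_set]), `map` (piece map:
#'   `scaffold`, `piece`, `piece_start`, `piece_end`), and lifted versions
#'   of the supplied evidence tables.
#' @export
break_scaffolds <- function(scaffolds, breakpoints, pairs = NULL,
                            molecules = NULL, links = NULL, markers = NULL) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  bp <- as.data.table(breakpoints)
  info <- scaffolds$info
  if (nrow(bp) > 0L) {
    bad <- bp[!info, on = "scaffold"]
    if (nrow(bad) > 0L)
      stop("breakpoints on unknown scaffolds: ",
           paste(unique(bad$scaffold), collapse = ", "))
    bp <- bp[info, on = "scaffold", nomatch = NULL]
    if (any(bp$position <= 0L | bp$position >= bp$length))
      stop("breakpoint position outside scaffold")
  }
  pmap <- info[, {
    cuts <- sort(unique(bp[scaffold == .BY[[1]], position]))
    bounds <- c(0L, cuts, length)
    np <- base::length(bounds) - 1L
    .(piece = if (np == 1L) scaffold else paste0(scaffold, "_p", seq_len(np)),
      piece_start = bounds[-(np + 1L)], piece_end = bounds[-1L])
  }, by = .(scaffold)]
  new_info <- pmap[, .(scaffold = piece, length = piece_end - piece_start)]
  new_seq <- NULL
  if (!is.null(scaffolds$seq)) {
    new_seq <- Biostrings::DNAStringSet(Biostrings::subseq(
      scaffolds$seq[pmap$scaffold], start = pmap$piece_start + 1L,
      end = pmap$piece_end))
    names(new_seq) <- pmap$piece
  }
  out <- list(scaffolds = scaffold_set(new_info, new_seq), map = pmap[])
  if (!is.null(pairs)) {
    pr <- break_lift_intervals(pairs, pmap, split = FALSE)
    setorder(pr, barcode, scaffold, start)
    out$pairs <- pr
  }
  if (!is.null(molecules))
    out$molecules <- break_lift_intervals(molecules, pmap, split = TRUE)
  if (!is.null(links)) {
    lk <- break_lift_points(links, pmap, "scaffold1", "pos1")
    lk <- break_lift_points(lk, pmap, "scaffold2", "pos2")
    out$links <- canonical_link_sides(lk)
  }
  if (!is.null(markers))
    out$markers <- break_lift_points(markers, pmap, "scaffold", "position")
  out
}

## point lift through a piece map (roll join on piece start)
break_lift_points <- function(dt, pmap, scaffold_col, pos_col) {
  dt <- as.data.table(dt)
  if (nrow(dt) == 0L) return(copy(dt))
  key <- pmap[, .(scaffold, piece_start, ps = piece_start, piece)]
  setkey(key, scaffold, piece_start)
  q <- data.table(scaffold = dt[[scaffold_col]], piece_start = dt[[pos_col]])
  hit <- key[q, on = c("scaffold", "piece_start"), roll = TRUE]
  if (anyNA(hit$piece))
    stop("position outside any scaffold piece (unknown scaffold or negative coordinate)")
  out <- copy(dt)
  set(out, j = scaffold_col, value = hit$piece)
  set(out, j = pos_col, value = as.integer(dt[[pos_col]] - hit$ps))
  out
}

## interval lift; split = TRUE splits records spanning a cut into one
## record per overlapped piece (molecules), dividing any n_pairs column
## proportionally to span; split = FALSE drops records that cross a cut
## (short read pairs)
break_lift_intervals <- function(dt, pmap, split = TRUE) {
  dt <- as.data.table(dt)
  if (nrow(dt) == 0L) return(copy(dt))
  orig_cols <- names(dt)
  pm <- pmap[, .(scaffold, ps = piece_start, pe = piece_end, piece)]
  setkey(pm, scaffold, ps, pe)
  q <- copy(dt)[, `:=`(s = start, e = end)]
  ov <- foverlaps(q, pm, by.x = c("scaffold", "s", "e"),
                  by.y = c("scaffold", "ps", "pe"), type = "any",
                  nomatch = NULL)
  ov <- ov[s < pe & e > ps]  # strict overlap for half-open intervals
  if (!split) ov <- ov[s >= ps & e <= pe]
  ov[, `:=`(start = pmax(s, ps) - ps, end = pmin(e, pe) - ps)]
  if (split && "n_pairs" %in% orig_cols)
    ov[, n_pairs := pmax(1L, as.integer(round(n_pairs * (end - start) / (e - s))))]
  ov[, scaffold := piece]
  out <- ov[, orig_cols, with = FALSE]
  setorder(out, scaffold, start, end)
  out[]
}

#' Iterate detection and breaking to a fixpoint
#'
#' Alternates 10X breakpoint detection and scaffold breaking until a round
#' detects no breakpoints, lifting read pairs, Hi-C links and marker
#' alignments into the corrected coordinates after every round (molecules
#' are re-called from the lifted pairs, so molecule boundaries follow the
#' cuts). After convergence, Hi-C coverage troughs are flagged as potential
#' breakpoints in the audit log, but are never cut automatically — they are
#' meant for visual review and, if confirmed, for the curation-edit
#' interface.
#'
#' @param scaffolds a [scaffold_set].
#' @param pairs filtered linked-read pair table ([read_pairs()]).
#' @param hic_pairs optional two-sided Hi-C pair table.
#' @param markers optional marker alignment table.
#' @param config a [misjoin_config()].
#' @return A list with the corrected `scaffolds`, lifted `pairs`,
#'   `molecules`, `hic_pairs`, `markers`, the number of `rounds` run, and
#'   an `audit` table recording every cut and flag (columns `round`,
#'   `scaffold`, `position`, `evidence`, `trough`, `action`).
#' @export
correct_to_fixpoint <- function(scaffolds, pairs, hic_pairs = NULL,
                                markers = NULL, config = misjoin_config()) {
  stopifnot(inherits(config, "misjoin_config"))
  ss <- scaffolds
  ## origin: current scaffold name -> original scaffold + offset, so cuts
  ## and pieces can always be reported in input coordinates
  origin <- ss$info[, .(scaffold, orig_scaffold = scaffold, orig_offset = 0L)]
  audit <- list()
  converged <- FALSE
  mols <- NULL
  for (round in seq_len(config$max_rounds)) {
    setorder(pairs, barcode, scaffold, start)
    mols <- call_molecules(pairs, gap_max = config$gap_max,
                           molecule_min_len = config$molecule_min_len,
                           min_pairs = config$min_pairs)
    cov <- molecule_coverage(mols, ss, bin_size = config$bin_size_tenx)
    bps <- detect_breakpoints(cov, threshold_fraction = config$threshold_tenx,
                              min_separation = config$min_separation,
                              end_exclusion = config$end_exclusion_tenx,
                              baseline_min_len = config$baseline_min_len,
                              flank_bp = config$flank_bp,
                              flank_frac = config$flank_frac,
                              evidence = "tenx")
    if (nrow(bps) == 0L) {
      converged <- TRUE
      break
    }
    rnd <- round
    cut_log <- bps[, .(round = rnd, scaffold, position, evidence, trough,
                       action = "cut")]
    cut_log[origin, `:=`(orig_scaffold = i.orig_scaffold,
                         orig_position = position + i.orig_offset),
            on = "scaffold"]
    audit[[length(audit) + 1L]] <- cut_log
    br <- break_scaffolds(ss, bps, pairs = pairs, links = hic_pairs,
                          markers = markers)
    origin <- br$map[origin, on = "scaffold",
                     .(scaffold = piece, orig_scaffold = i.orig_scaffold,
                       orig_offset = i.orig_offset + piece_start)]
    ss <- br$scaffolds
    pairs <- br$pairs
    if (!is.null(hic_pairs)) hic_pairs <- br$links
    if (!is.null(markers)) markers <- br$markers
  }
  if (!converged)
    stop("no fixpoint after ", config$max_rounds, " rounds; scaffolds still flagged: ",
         paste(unique(bps$scaffold), collapse = ", "))
  if (!is.null(hic_pairs) && nrow(hic_pairs) > 0L) {
    hcov <- hic_coverage(hic_pairs, ss, bin_size = config$bin_size_hic)
    flags <- detect_breakpoints(hcov, threshold_fraction = config$threshold_hic,
                                min_separation = config$min_separation,
                                end_exclusion = config$end_exclusion_hic,
                                baseline_min_len = config$baseline_min_len,
                                flank_bp = config$flank_bp,
                                flank_frac = config$flank_frac,
                                evidence = "hic")
    if (nrow(flags) > 0L) {
      rnd <- round
      flag_log <- flags[, .(round = rnd, scaffold, position, evidence,
                            trough, action = "flagged")]
      flag_log[origin, `:=`(orig_scaffold = i.orig_scaffold,
                            orig_position = position + i.orig_offset),
               on = "scaffold"]
      audit[[length(audit) + 1L]] <- flag_log
    }
  }
  audit <- if (length(audit) > 0L) rbindlist(audit) else
    data.table(round = integer(), scaffold = character(),
               position = integer(), evidence = character(),
               trough = numeric(), action = character(),
               orig_scaffold = character(), orig_position = integer())
  list(scaffolds = ss, pairs = pairs, molecules = mols,
       hic_pairs = hic_pairs, markers = markers, rounds = round,
       audit = audit, origin = origin)
}

#' Write an audit log as JSON lines
#'
#' @param audit audit table from [correct_to_fixpoint()] or [apply_edits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(audit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(audit)))
    writeLines(jsonlite::toJSON(as.list(audit[i]), auto_unbox = TRUE), con)
  invisible(path)
}

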