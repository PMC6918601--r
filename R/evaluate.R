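#' Evaluate pipeline output against simulation truth
#'
#' Helper metrics comparing pipeline results with the truth tables of the
#' simulator: chimera-cut recall and precision, super-scaffold adjacency
#' and order recovery, ordering/orientation accuracy of pseudomolecule
#' layouts, and base-level chromosome placement.
#'
#' @name evaluation
NULL

#' @describeIn evaluation Compare automatic cuts with true chimeric
#'   junctions. A junction is recovered if a cut lies within `tol_bp` of it
#'   on the same original scaffold; cuts matching no junction are false.
#' @param audit audit table from [correct_to_fixpoint()] (uses rows with
#'   `action == "cut"` and the original-coordinate columns).
#' @param junctions truth junction table (`scaffold`, `position`).
#' @param tol_bp matching tolerance in bp (default 400 = two 200 bp bins).
#' @return A list with `recall`, `n_false`, `n_cuts`, `max_err`.
#' @export
eval_breakpoints <- function(audit, junctions, tol_bp = 400L) {
  cuts <- as.data.table(audit)[action == "cut"]
  jn <- as.data.table(junctions)
  if (nrow(jn) == 0L)
    return(list(recall = NA_real_, n_false = nrow(cuts),
                n_cuts = nrow(cuts), max_err = NA_real_))
  errs <- numeric(0)
  hit <- logical(nrow(jn))
  matched <- rep(FALSE, nrow(cuts))
  for (i in seq_len(nrow(jn))) {
    cand <- which(cuts$orig_scaffold == jn$scaffold[i] &
                  abs(cuts$orig_position - jn$position[i]) <= tol_bp)
    if (length(cand) > 0L) {
      hit[i] <- TRUE
      matched[cand] <- TRUE
      errs <- c(errs, min(abs(cuts$orig_position[cand] - jn$position[i])))
    }
  }
  list(recall = mean(hit), n_false = sum(!matched), n_cuts = nrow(cuts),
       max_err = if (length(errs)) max(errs) else NA_real_)
}

#' @describeIn evaluation Score an oriented super-scaffold membership
#'   against the truth: fraction of true adjacent scaffold pairs that are
#'   adjacent in some path, mean absolute Kendall's tau between member
#'   order and true position (weighted by member count, paths with >= 2
#'   members), and orientation accuracy (members whose orientation matches
#'   the truth after aligning each path's direction to the chromosome;
#'   restricted to members with at least `min_links` informative linking
#'   molecules when the membership carries an `n_links` column).
#' @param membership oriented membership from [orient_members()].
#' @param segments truth segment table from [simulate_genome()].
#' @param min_links minimum informative molecules for the orientation
#'   score (default 10).
#' @return A list with `adjacency_recovery`, `mean_tau`,
#'   `orientation_accuracy`, `n_oriented`.
#' @export
eval_membership <- function(membership, segments, min_links = 10L) {
  mem <- as.data.table(membership)
  seg <- as.data.table(segments)
  tr <- seg[, .(scaffold, chromosome, chr_start, true_orient = orientation)]
  mem <- merge(mem, tr, by.x = "member", by.y = "scaffold", all.x = TRUE)
  ## true adjacencies
  setorder(seg, chromosome, chr_start)
  adj <- seg[, if (.N > 1L) .(a = scaffold[-.N], b = scaffold[-1L]),
             by = .(chromosome)]
  pos <- mem[, .(member, super_scaffold, ord)]
  adj[pos, `:=`(ss_a = i.super_scaffold, ord_a = i.ord), on = c(a = "member")]
  adj[pos, `:=`(ss_b = i.super_scaffold, ord_b = i.ord), on = c(b = "member")]
  adj[, recovered := !is.na(ss_a) & ss_a == ss_b & abs(ord_a - ord_b) == 1L]
  ## per-path order and direction
  paths <- mem[, .N, by = .(super_scaffold)][N >= 2L, super_scaffold]
  taus <- mem[super_scaffold %in% paths,
              .(tau = suppressWarnings(cor(ord, chr_start, method = "kendall")),
                n = .N), by = .(super_scaffold)]
  taus <- taus[!is.na(tau)]
  mean_tau <- if (nrow(taus)) sum(abs(taus$tau) * taus$n) / sum(taus$n)
              else NA_real_
  ## orientation, after aligning path direction to the chromosome
  mem[taus, dir := fifelse(i.tau >= 0, 1L, -1L), on = "super_scaffold"]
  omem <- mem[!is.na(dir) & !is.na(true_orient)]
  if ("n_links" %in% names(omem)) omem <- omem[n_links >= min_links]
  else if ("informative" %in% names(omem)) omem <- omem[informative == TRUE]
  expected <- fifelse(omem$dir == 1L, omem$true_orient,
                      fifelse(omem$true_orient == "+", "-", "+"))
  acc <- if (nrow(omem)) mean(omem$orientation == expected) else NA_real_
  list(adjacency_recovery = mean(adj$recovered), mean_tau = mean_tau,
       orientation_accuracy = acc, n_oriented = nrow(omem))
}

#' @describeIn evaluation Score a chromosome ordering of units (here:
#'   units that are single scaffolds) against truth: weighted mean signed
#'   Kendall's tau between rank and true chromosome position over units
#'   assigned to their true chromosome, fraction of units on the correct
#'   chromosome, and orientation accuracy over units with at least
#'   `min_links` intra-chromosomal links.
#' @param chrom_order `chrom_order` table after [orient_by_hic()].
#' @param links unit-coordinate link table (to count informative links).
#' @export
eval_chrom_order <- function(chrom_order, segments, links = NULL,
                             min_links = 10L) {
  ord <- as.data.table(chrom_order)
  seg <- as.data.table(segments)
  tr <- seg[, .(unit = scaffold, true_chr = chromosome, chr_start,
                true_orient = orientation)]
  ord <- merge(ord, tr, by = "unit", all.x = TRUE)
  ok <- ord[!is.na(true_chr) & chromosome == true_chr]
  taus <- ok[, .(tau = suppressWarnings(cor(rank, chr_start,
                                            method = "kendall")),
                 n = .N), by = .(chromosome)]
  taus <- taus[!is.na(tau)]
  mean_tau <- if (nrow(taus)) sum(taus$tau * taus$n) / sum(taus$n)
              else NA_real_
  keep <- ok
  if (!is.null(links)) {
    lk <- as.data.table(links)
    cnt <- rbind(lk[, .(unit = scaffold1)], lk[, .(unit = scaffold2)])
    cnt <- cnt[, .(n_links = .N), by = .(unit)]
    keep <- merge(keep, cnt, by = "unit", all.x = TRUE)
    keep[is.na(n_links), n_links := 0L]
    keep <- keep[n_links >= min_links]
  }
  acc <- if (nrow(keep)) mean(keep$orientation == keep$true_orient)
         else NA_real_
  list(mean_tau = mean_tau, frac_correct_chr = nrow(ok) / nrow(ord),
       orientation_accuracy = acc, n_oriented = nrow(keep))
}

#' @describeIn evaluation Base-level placement accuracy of a
#'   pseudomolecule build: fraction of assembly bases placed on their true
#'   chromosome, and weighted mean Kendall's tau between true and built
#'   positions of correctly placed blocks.
#' @param pm result of [build_pseudomolecules()].
#' @param truth truth object from [simulate_genome()].
#' @param origin optional origin table from [correct_to_fixpoint()]
#'   mapping current scaffolds to original coordinates (identity assumed
#'   when `NULL`).
#' @export
eval_pseudomolecules <- function(pm, truth, origin = NULL) {
  seg <- as.data.table(truth$segments)
  map <- as.data.table(pm$map)
  if (is.null(origin))
    origin <- map[, .(scaffold = member, orig_scaffold = member,
                      orig_offset = 0L)]
  map <- merge(map, as.data.table(origin), by.x = "member",
               by.y = "scaffold", all.x = TRUE)
  ## intersect each placed member with the truth segments of its original
  ## scaffold (both in original scaffold coordinates)
  win <- map[, .(member, unit, offset, pm_orient = orientation,
                 member_length, orig_scaffold, ws = orig_offset,
                 we = orig_offset + member_length)]
  ov <- seg[win, on = c(scaffold = "orig_scaffold"), allow.cartesian = TRUE,
            nomatch = NULL]
  ov <- ov[scaf_start < we & scaf_end > ws]
  ov[, `:=`(bs = pmax(scaf_start, ws), be = pmin(scaf_end, we))]
  ov[, blen := be - bs]
  ov[, mid := (bs + be) / 2]
  ## true chromosome position of the block midpoint (orientation is the
  ## truth strand of the segment; pm_orient the placement orientation)
  ov[, true_pos := fifelse(orientation == "+",
                           chr_start + (mid - scaf_start),
                           chr_end - (mid - scaf_start))]
  ov[, local := mid - ws]
  ov[, built_pos := fifelse(pm_orient == "+", offset + local,
                            offset + member_length - local)]
  total <- sum(as.numeric(scaffold_lengths_from_truth(truth)))
  correct <- ov[chromosome == unit]
  frac <- sum(as.numeric(correct$blen)) / total
  taus <- correct[, .(tau = suppressWarnings(
    cor(true_pos, built_pos, method = "kendall")), w = sum(as.numeric(blen))),
    by = .(chromosome)]
  taus <- taus[!is.na(tau)]
  mean_tau <- if (nrow(taus)) sum(taus$tau * taus$w) / sum(taus$w)
              else NA_real_
  list(frac_correct_chr = frac, mean_tau = mean_tau)
}

scaffold_lengths_from_truth <- function(truth) {
  truth$segments[, .(len = max(scaf_end)), by = .(scaffold)]$len
}
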