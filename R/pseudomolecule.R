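#' Order super-scaffolds along chromosomes
#'
#' Produces a per-chromosome ordering of super-scaffolds from their genetic
#' positions, refined with Hi-C contact density. Units are first sorted by
#' consensus cM; units without a cM (but anchored to the chromosome) are
#' then inserted greedily at the position maximizing summed contact with
#' their flanking neighbors; finally local refinement is applied while the
#' total contact weight between consecutive units increases (bounded
#' passes): adjacent-pair swaps, then single-unit relocations to the best
#' position in the current order. Genetic positions give the coarse,
#' recombination-limited backbone; contact decay resolves order within cM
#' ties, where recombination provides no signal. Only strict improvements
#' are accepted, so sparse contacts leave the cM order untouched.
#'
#' Contact weights between units are computed from links falling within
#' `end_window` of either end of both units and are normalized by the
#' product of the window sizes: raw whole-unit totals grow with unit size,
#' so a pair of long units two steps apart can out-weigh a short unit's
#' true adjacency, whereas near-end link density isolates the short-range
#' decay signal that identifies true neighbours.
#'
#' @param unit_anchors anchor table for super-scaffolds (`scaffold` column
#'   holding unit names), as from [lift_anchors()].
#' @param links two-sided link table in super-scaffold coordinates.
#' @param unit_lengths named vector of unit lengths (required for
#'   end-window contact weighting; falls back to raw totals when `NULL`).
#' @param end_window near-end window for contact weighting (default 100
#'   kb, capped at half the unit).
#' @param max_passes bound on refinement passes (default 30).
#' @return A `chrom_order` table: `data.table` with columns `chromosome`,
#'   `rank`, `unit`, `orientation` (initialized `"+"`), `cM`.
#' @export
order_superscaffolds <- function(unit_anchors, links, unit_lengths = NULL,
                                 end_window = 100000L, max_passes = 30L) {
  anc <- as.data.table(unit_anchors)
  placed <- anc[!is.na(chromosome)]
  if (nrow(placed) == 0L) {
    warning("no anchored units; nothing to order")
    return(data.table(chromosome = character(), rank = integer(),
                      unit = character(), orientation = character(),
                      cM = numeric()))
  }
  W <- unit_contact_weights(links, unit_lengths, end_window)
  out <- placed[, {
    units <- scaffold; cms <- cM
    Wm <- dense_contacts(W, units)
    has_cm <- !is.na(cms)
    ord <- which(has_cm)[order(cms[has_cm], units[has_cm])]
    for (u in sort(which(!has_cm))) ord <- best_insertion(ord, u, Wm)
    ord <- refine_order(ord, Wm, cms, max_passes)
    .(rank = seq_along(ord), unit = units[ord], orientation = "+",
      cM = cms[ord])
  }, by = .(chromosome)]
  out[]
}

## dense symmetric contact matrix for one chromosome's units
dense_contacts <- function(W, units) {
  n <- length(units)
  Wm <- matrix(0, n, n, dimnames = list(units, units))
  if (nrow(W) > 0L) {
    sub <- W[u1 %in% units & u2 %in% units]
    if (nrow(sub) > 0L) {
      i <- match(sub$u1, units); j <- match(sub$u2, units)
      Wm[cbind(i, j)] <- sub$w
      Wm[cbind(j, i)] <- sub$w
    }
  }
  Wm
}

## symmetric unit-level contact lookup from a link table; with lengths,
## counts only near-end links and normalizes by the window-size product
unit_contact_weights <- function(links, unit_lengths = NULL,
                                 end_window = 100000L) {
  lk <- as.data.table(links)
  if (nrow(lk) == 0L)
    return(data.table(u1 = character(), u2 = character(), w = numeric()))
  if (!"count" %in% names(lk)) lk <- copy(lk)[, count := 1L]
  lk <- lk[scaffold1 != scaffold2]
  if (!is.null(unit_lengths)) {
    near_end <- function(u, p) {
      len <- unit_lengths[u]
      w <- pmin(len, 2 * end_window)
      p < w / 2 | p >= len - w / 2
    }
    lk <- lk[near_end(scaffold1, pos1) & near_end(scaffold2, pos2)]
    if (nrow(lk) == 0L)
      return(data.table(u1 = character(), u2 = character(), w = numeric()))
  }
  ag <- lk[, .(w = sum(as.numeric(count))),
           by = .(u1 = pmin(scaffold1, scaffold2),
                  u2 = pmax(scaffold1, scaffold2))]
  if (!is.null(unit_lengths)) {
    wsz <- pmin(unit_lengths, 2 * end_window) / (2 * end_window)
    ag[, w := w / (wsz[u1] * wsz[u2])]
  }
  setkey(ag, u1, u2)
  ag
}

## contact between order neighbours, 0 off the ends (indices into Wm)
wm_at <- function(Wm, a, b) {
  if (is.na(a) || is.na(b)) 0 else Wm[a, b]
}

## insert unit index u at the adjacency-gain-maximizing position
best_insertion <- function(ord, u, Wm) {
  n <- length(ord)
  if (n == 0L) return(u)
  gains <- vapply(seq_len(n + 1L), function(pos) {
    left <- if (pos > 1L) ord[pos - 1L] else NA_integer_
    right <- if (pos <= n) ord[pos] else NA_integer_
    wm_at(Wm, left, u) + wm_at(Wm, u, right) - wm_at(Wm, left, right)
  }, numeric(1))
  pos <- which.max(gains)
  append(ord, u, after = pos - 1L)
}

## local search on the summed adjacent-contact objective with three move
## types: adjacent swaps, single-unit relocations, and 2-opt block
## reversals (a reversed run changes the contact objective only at its two
## boundaries, so swap/relocation moves alone cannot undo one). A move is
## accepted only if it strictly improves contact AND does not reduce cM
## monotonicity — reversals inside cM ties are free, but the contact
## objective is direction-symmetric and would otherwise happily reverse
## runs of distinct cM values (or whole chromosomes). Bounded passes.
refine_order <- function(ord, Wm, cms, max_passes) {
  n <- length(ord)
  if (n < 2L) return(ord)
  contact <- function(o) sum(Wm[cbind(o[-n], o[-1])])
  mono <- function(o) {
    cc <- cms[o]
    d <- diff(cc)
    sum(is.na(d) | d >= 0)
  }
  cur_w <- contact(ord)
  cur_m <- mono(ord)
  try_move <- function(cand) {
    w <- contact(cand)
    if (w > cur_w + 1e-9 && mono(cand) >= cur_m) {
      ord <<- cand
      cur_w <<- w
      cur_m <<- mono(cand)
      TRUE
    } else FALSE
  }
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (i in seq_len(n - 1L)) {
      cand <- ord
      cand[c(i, i + 1L)] <- cand[c(i + 1L, i)]
      if (try_move(cand)) improved <- TRUE
    }
    for (i in seq_len(n)) {
      rest <- ord[-i]
      u <- ord[i]
      for (j in seq_len(n)) {
        if (j == i) next
        cand <- append(rest, u, after = j - 1L)
        if (try_move(cand)) {
          improved <- TRUE
          break  # ord changed; stale positions, move to next i
        }
      }
    }
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        cand <- ord
        cand[i:j] <- cand[j:i]
        if (try_move(cand)) improved <- TRUE
      }
    }
    if (!improved) break
  }
  ord
}

#' Orient units by the genetic-map gradient along them
#'
#' A unit spanning a region with recombination carries its own direction
#' signal: marker cM values must increase along the chromosome, so a
#' negative correlation between within-unit marker position and cM means
#' the unit is flipped. This is the only direction information available
#' for units without ordered Hi-C neighbours (e.g. a chromosome assembled
#' into a single super-scaffold); [orient_by_hic()] refines the result
#' where inter-unit contacts exist.
#'
#' @param chrom_order a `chrom_order` table.
#' @param markers marker alignments in unit coordinates (e.g. the
#'   `markers` attribute of [lift_anchors()]).
#' @param genetic_map genetic map table.
#' @param min_markers minimum informative markers per unit (default 3).
#' @return The `chrom_order` table with `orientation` updated.
#' @export
orient_by_cm <- function(chrom_order, markers, genetic_map, min_markers = 3L) {
  ord <- copy(as.data.table(chrom_order))
  mk <- as.data.table(markers)[as.data.table(genetic_map), on = "marker",
                               nomatch = NULL]
  rho <- mk[, {
    ok <- is.finite(position) & is.finite(cM)
    if (sum(ok) >= min_markers)
      .(rho = suppressWarnings(cor(position[ok], cM[ok],
                                   method = "spearman")))
    else .(rho = NA_real_)
  }, by = .(scaffold)]
  ord[rho[!is.na(rho) & rho < 0], orientation := "-",
      on = c(unit = "scaffold")]
  ord[]
}

#' Orient ordered units by Hi-C contact decay
#'
#' Contact frequency decays with genomic distance, so the end of a unit
#' that faces its left-side neighbors should show more contact with them
#' than the far end. For each unit, links from its two near-end regions
#' (within `end_region` of each end, at most half the unit) to units up to
#' `flank_rank` positions before versus after it are summed; the
#' orientation placing the higher-contact end towards its side of the
#' chromosome is kept. A few flanking units rather than only the immediate
#' neighbour make the call robust to residual local order errors, while a
#' bounded flank keeps the heavy-tailed long-range contact noise out of
#' the comparison. Units without informative contacts retain their
#' linked-read orientation.
#'
#' @param chrom_order a `chrom_order` table from [order_superscaffolds()].
#' @param links two-sided link table in unit coordinates.
#' @param unit_lengths named vector of unit lengths.
#' @param end_region near-end region size in bp (default 1 Mb, capped at
#'   half the unit length).
#' @param flank_rank how many flanking units on each side enter the
#'   comparison (default 2).
#' @return The `chrom_order` table with `orientation` set to `"+"` (keep)
#'   or `"-"` (flip), plus an `informative` flag.
#' @export
orient_by_hic <- function(chrom_order, links, unit_lengths,
                          end_region = 1000000L, flank_rank = 2L) {
  ord <- copy(as.data.table(chrom_order))
  lk <- as.data.table(links)
  if (!"count" %in% names(lk)) lk <- copy(lk)[, count := 1L]
  ord[, informative := FALSE]
  ranks <- ord[, .(unit, chromosome, rank)]
  sides <- rbind(
    lk[scaffold1 != scaffold2,
       .(unit = scaffold1, pos = pos1, other = scaffold2, count)],
    lk[scaffold1 != scaffold2,
       .(unit = scaffold2, pos = pos2, other = scaffold1, count)])
  sides[ranks, `:=`(chromosome = i.chromosome, rank = i.rank), on = "unit"]
  sides[ranks, `:=`(o_chrom = i.chromosome, o_rank = i.rank),
        on = c(other = "unit")]
  sides <- sides[!is.na(rank) & !is.na(o_rank) & chromosome == o_chrom &
                 abs(o_rank - rank) <= flank_rank]
  if (nrow(sides) > 0L) {
    sides[, len := unit_lengths[unit]]
    sides[, reg := pmin(end_region, floor(len / 2))]
    sides[, region := fifelse(pos < reg, "s",
                              fifelse(pos >= len - reg, "e", NA_character_))]
    sides <- sides[!is.na(region)]
    sides[, dir := fifelse(o_rank < rank, "L", "R")]
    sc <- sides[, .(w = sum(as.numeric(count))), by = .(unit, region, dir)]
    sc <- dcast(sc, unit ~ region + dir, value.var = "w", fill = 0)
    for (col in c("s_L", "s_R", "e_L", "e_R"))
      if (!col %in% names(sc)) sc[, (col) := 0]
    sc[, `:=`(fwd = s_L + e_R, rev = e_L + s_R)]
    ord[sc, `:=`(informative = i.fwd + i.rev > 0,
                 orientation = fifelse(i.rev > i.fwd, "-", orientation)),
        on = "unit"]
  }
  ord[]
}

#' Read and apply curation edits
#'
#' The curation-edit table supports the manual assembly-inspection-
#' correction cycle: each row is one edit, applied in file order.
#' Actions: `invert` flips a unit's orientation; `move` places a unit at a
#' new rank (and optionally a new chromosome); `assign` moves a unit from
#' the unplaced pool onto a chromosome (or off, with chromosome `chrUn`);
#' `break` cuts a scaffold at a position via [break_scaffolds()] (the
#' scaffold must be a singleton unit or unplaced).
#'
#' @param path TSV with header columns `action`, `target`, and optional
#'   `chromosome`, `rank`, `position`.
#' @return `read_edits()`: a `data.table` of edits.
#' @export
read_edits <- function(path) {
  ed <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = c("action", "target")))
  for (col in c("chromosome", "rank", "position"))
    if (!col %in% names(ed)) ed[, (col) := NA]
  ed[, `:=`(rank = as.integer(rank), position = as.integer(position))]
  ed[]
}

#' @rdname read_edits
#' @param chrom_order a `chrom_order` table.
#' @param edits edit table from [read_edits()].
#' @param scaffolds optional [scaffold_set]; required for `break` edits.
#' @return `apply_edits()`: a list with the updated `chrom_order`,
#'   `scaffolds`, and an `audit` table.
#' @export
apply_edits <- function(chrom_order, edits, scaffolds = NULL) {
  ord <- copy(as.data.table(chrom_order))
  ed <- as.data.table(edits)
  audit <- list()
  for (i in seq_len(nrow(ed))) {
    e <- ed[i]
    known <- unique(c(ord$unit, if (!is.null(scaffolds)) scaffold_names(scaffolds)))
    if (!e$target %in% known)
      stop("edit ", i, ": unknown target '", e$target, "'; valid: ",
           paste(head(sort(known), 20L), collapse = ", "),
           if (length(known) > 20L) ", ..." else "")
    if (e$action == "invert") {
      ord[unit == e$target,
          orientation := fifelse(orientation == "+", "-", "+")]
    } else if (e$action == "move") {
      row <- ord[unit == e$target]
      if (nrow(row) == 0L) stop("edit ", i, ": target not placed: ", e$target)
      dest_chr <- if (is.na(e$chromosome)) row$chromosome else e$chromosome
      ord <- ord[unit != e$target]
      ins <- copy(row)[, chromosome := dest_chr]
      ord <- insert_at_rank(ord, ins, dest_chr, e$rank)
    } else if (e$action == "assign") {
      if (e$target %in% ord$unit && identical(e$chromosome, "chrUn")) {
        ord <- ord[unit != e$target]
        ord <- rerank(ord)
      } else if (!e$target %in% ord$unit) {
        ins <- data.table(chromosome = e$chromosome, rank = NA_integer_,
                          unit = e$target, orientation = "+", cM = NA_real_)
        if ("informative" %in% names(ord)) ins[, informative := FALSE]
        ord <- insert_at_rank(ord, ins, e$chromosome, e$rank)
      }
    } else if (e$action == "break") {
      if (is.null(scaffolds)) stop("break edit requires scaffolds")
      br <- break_scaffolds(scaffolds,
                            data.table(scaffold = e$target,
                                       position = e$position))
      scaffolds <- br$scaffolds
      if (e$target %in% ord$unit) {
        row <- ord[unit == e$target]
        pieces <- br$map[scaffold == e$target, piece]
        if (row$orientation == "-") pieces <- base::rev(pieces)
        ord <- ord[unit != e$target]
        ins <- row[rep(1L, length(pieces))]
        ins[, unit := pieces]
        ord <- insert_at_rank(ord, ins, row$chromosome, row$rank)
      }
    } else stop("edit ", i, ": unknown action '", e$action, "'")
    audit[[i]] <- data.table(edit = i, action = e$action, target = e$target)
  }
  list(chrom_order = rerank(ord), scaffolds = scaffolds,
       audit = if (length(audit)) rbindlist(audit) else
         data.table(edit = integer(), action = character(),
                    target = character()))
}

insert_at_rank <- function(ord, ins, chrom, at_rank) {
  sub <- ord[chromosome == chrom][order(rank)]
  rest <- ord[chromosome != chrom]
  pos <- if (is.na(at_rank)) nrow(sub) + 1L else min(at_rank, nrow(sub) + 1L)
  sub <- rbind(sub[seq_len(pos - 1L)], ins, if (pos <= nrow(sub))
    sub[pos:nrow(sub)], fill = TRUE)
  sub[, rank := seq_len(.N)]  # stale ranks would reorder under rerank()
  rerank(rbind(rest, sub, fill = TRUE))
}

rerank <- function(ord) {
  setorder(ord, chromosome, rank, na.last = TRUE)
  ord[, rank := seq_len(.N), by = .(chromosome)]
  ord[]
}

#' Build pseudomolecule sequences and AGP layout
#'
#' Lays ordered, oriented units (and their member scaffolds) out along each
#' chromosome with fixed `gap`-bp runs of `N` between components, collects
#' unplaced scaffolds of at least `chrun_min_len` bp into a `chrUn`
#' concatenation, and emits the AGP layout plus (when sequence is present)
#' the pseudomolecule FASTA.
#'
#' @param chrom_order a `chrom_order` table (after [orient_by_hic()] /
#'   [apply_edits()]).
#' @param ss_map super-scaffold membership map from [superscaffold_map()];
#'   units absent from it are treated as singleton scaffolds.
#' @param scaffolds a [scaffold_set] of the (corrected) assembly.
#' @param gap inter-component gap in bp (default 100).
#' @param chrun_min_len minimum scaffold length for chrUn (default 1 kb).
#' @return A list with `layout` (AGP table, see [agp]), `map` (membership
#'   map scaffold -> pseudomolecule for lifting evidence), `lengths`
#'   (named pseudomolecule lengths), and `assembly` (a [scaffold_set] of
#'   pseudomolecules; sequence present if the input had sequence).
#' @export
build_pseudomolecules <- function(chrom_order, ss_map, scaffolds,
                                  gap = 100L, chrun_min_len = 1000L) {
  ord <- as.data.table(chrom_order)
  sm <- as.data.table(ss_map)
  slen <- scaffold_lengths(scaffolds)
  ## member-level component list per chromosome
  comp <- list()
  for (ch in unique(ord$chromosome)) {
    sub <- ord[chromosome == ch][order(rank)]
    members <- list()
    for (i in seq_len(nrow(sub))) {
      u <- sub$unit[i]
      mm <- sm[unit == u][order(offset)]
      if (nrow(mm) == 0L) {
        if (!u %in% names(slen)) stop("member sequence missing: ", u)
        mm <- data.table(member = u, orientation = "+")
      } else mm <- mm[, .(member, orientation)]
      if (sub$orientation[i] == "-") {
        mm <- mm[base::rev(seq_len(nrow(mm)))]
        mm[, orientation := fifelse(orientation == "+", "-", "+")]
      }
      members[[i]] <- mm
    }
    comp[[ch]] <- rbindlist(members)
  }
  placed <- unlist(lapply(comp, function(x) x$member))
  if (anyDuplicated(placed))
    stop("scaffold placed more than once: ",
         paste(unique(placed[duplicated(placed)]), collapse = ", "))
  unplaced <- setdiff(names(slen), placed)
  chrun <- sort(unplaced[slen[unplaced] >= chrun_min_len])
  if (length(chrun) > 0L)
    comp$chrUn <- data.table(member = chrun, orientation = "+")
  ## AGP rows and membership map
  rows <- list(); maps <- list(); lens <- c()
  for (ch in names(comp)) {
    mm <- comp[[ch]]
    if (nrow(mm) == 0L) next
    mlen <- as.integer(slen[mm$member])
    if (anyNA(mlen)) stop("member sequence missing: ",
                          paste(mm$member[is.na(mlen)], collapse = ", "))
    offs <- cumsum(c(0L, head(mlen + gap, -1L)))
    total <- sum(mlen) + gap * (nrow(mm) - 1L)
    w <- data.table(object = ch, object_start = offs + 1L,
                    object_end = offs + mlen,
                    component_type = "W", component = mm$member,
                    component_start = 1L, component_end = mlen,
                    orientation = mm$orientation, gap_length = NA_integer_)
    rows[[ch]] <- w
    maps[[ch]] <- data.table(member = mm$member, unit = ch, offset = offs,
                             orientation = mm$orientation,
                             member_length = mlen)
    lens[ch] <- total
  }
  layout <- rbindlist(rows)
  ## interleave U gap rows
  layout <- layout[, {
    n <- .N
    gaps <- if (n > 1L) data.table(
      object_start = object_end[-n] + 1L,
      object_end = object_end[-n] + gap, component_type = "U",
      component = NA_character_, component_start = NA_integer_,
      component_end = NA_integer_, orientation = NA_character_,
      gap_length = gap) else NULL
    out <- rbind(.SD, gaps, fill = TRUE)
    setorder(out, object_start)
    out[, part_number := seq_len(.N)]
    out
  }, by = .(object), .SDcols = setdiff(names(layout), "object")]
  setcolorder(layout, c("object", "object_start", "object_end", "part_number",
                        "component_type", "component", "component_start",
                        "component_end", "orientation", "gap_length"))
  validate_layout(layout)
  pmap <- rbindlist(maps)
  assembly <- if (is.null(scaffolds$seq)) {
    scaffold_set(data.table(scaffold = names(lens), length = as.integer(lens)))
  } else {
    seqs <- vapply(names(comp), function(ch) {
      mm <- comp[[ch]]
      pieces <- vapply(seq_len(nrow(mm)), function(i) {
        sq <- scaffolds$seq[[mm$member[i]]]
        if (mm$orientation[i] == "-")
          sq <- Biostrings::reverseComplement(sq)
        as.character(sq)
      }, character(1))
      paste(pieces, collapse = strrep("N", gap))
    }, character(1))
    scaffold_set(seq = Biostrings::DNAStringSet(seqs))
  }
  list(layout = layout[], map = pmap, lengths = lens, assembly = assembly)
}

#' Split an assembly into fixed-size fragments
#'
#' Divides each scaffold into non-overlapping fragments named
#' `<scaffold>:<start>` — the input unit for assembly-to-assembly
#' collinearity comparison.
#'
#' @param scaffolds a [scaffold_set].
#' @param fragment fragment size in bp (default 10 kb); the final partial
#'   fragment of each scaffold is kept.
#' @return A `data.table` with columns `fragment`, `scaffold`, `start`,
#'   `end`.
#' @export
fragment_assembly <- function(scaffolds, fragment = 10000L) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  scaffolds$info[, {
    s <- seq(0L, length - 1L, by = fragment)
    e <- pmin(s + fragment, length)
    .(fragment = paste0(scaffold, ":", s), start = s, end = e)
  }, by = .(scaffold)][, .(fragment, scaffold, start, end)]
}

#' Collinearity between two assemblies from fragment alignments
#'
#' Takes alignments of fixed-size fragments of assembly A onto assembly B
#' (PAF; fragment query names `<scaffold>:<start>` as produced by
#' [fragment_assembly()]) and, for every scaffold pair with at least
#' `min_aligned` aligned fragment bp, computes the Pearson correlation
#' between fragment positions in A and their aligned positions in B, and
#' the fraction of aligned bases mapped in the majority orientation.
#' Genome-wide means are weighted by aligned bp.
#'
#' @param paf path to a PAF file, or an equivalent `data.table` with
#'   columns `qname`, `strand`, `tname`, `tstart`, `aln_len`.
#' @param min_aligned minimum aligned bp per scaffold pair (default 100 kb).
#' @return A list with `pairs` (per scaffold pair: `r`, `concordance`,
#'   `aligned_bp`, `n_fragments`) and weighted means `mean_r`,
#'   `mean_concordance`.
#' @export
collinearity_eval <- function(paf, min_aligned = 100000L) {
  aln <- if (is.character(paf)) {
    fread(paf, header = FALSE, sep = "\t", fill = TRUE, select = 1:12,
          col.names = c("qname", "qlen", "qstart", "qend", "strand",
                        "tname", "tlen", "tstart", "tend", "nmatch",
                        "aln_len", "mapq"))
  } else as.data.table(paf)
  aln[, scaffold := sub(":[0-9]+$", "", qname)]
  aln[, fragment := as.integer(sub(".*:", "", qname))]
  pairs <- aln[, {
    if (.N >= 2L && sum(aln_len) >= min_aligned) {
      conc <- max(tapply(aln_len, strand, sum)) / sum(aln_len)
      .(r = cor(fragment, tstart), concordance = conc,
        aligned_bp = sum(aln_len), n_fragments = .N)
    }
  }, by = .(scaffold, tname)]
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, mean_r = NA_real_,
                mean_concordance = NA_real_))
  list(pairs = pairs[],
       mean_r = with(pairs, sum(r * aligned_bp) / sum(aligned_bp)),
       mean_concordance = with(pairs,
         sum(concordance * aligned_bp) / sum(aligned_bp)))
}
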