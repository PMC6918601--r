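#' In silico restriction digestion
#'
#' Finds all occurrences of a restriction recognition site (IUPAC codes
#' allowed) on both strands and cuts at the first base of each site
#' occurrence (offset configurable). Fragments tile each scaffold without
#' gaps; a scaffold with no site yields a single fragment.
#'
#' @param scaffolds a [scaffold_set] carrying sequence.
#' @param site recognition site, IUPAC string of length >= 4.
#' @param cut_offset offset of the cut position from the site start
#'   (default 0: cut at site start).
#' @return A fragment map: `data.table` with columns `scaffold`, `start`,
#'   `end` (0-based half-open) and `index` (1-based, consecutive per
#'   scaffold).
#' @export
digest_scaffolds <- function(scaffolds, site, cut_offset = 0L) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  if (is.null(scaffolds$seq)) stop("digestion requires sequences")
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition site must be at least 4 bp")
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  if (!all(strsplit(site, "")[[1]] %in% iupac))
    stop("non-IUPAC characters in recognition site: ", site)
  pat <- Biostrings::DNAString(site)
  rc <- Biostrings::reverseComplement(pat)
  patterns <- list(pat)
  if (as.character(rc) != as.character(pat)) patterns <- c(patterns, list(rc))
  info <- scaffolds$info
  out <- vector("list", nrow(info))
  for (i in seq_len(nrow(info))) {
    sq <- scaffolds$seq[[info$scaffold[i]]]
    len <- info$length[i]
    cuts <- integer(0)
    for (p in patterns) {
      m <- Biostrings::matchPattern(p, sq, fixed = FALSE)
      cuts <- c(cuts, BiocGenerics::start(m) - 1L + cut_offset)
    }
    cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
    bounds <- c(0L, cuts, len)
    out[[i]] <- data.table(scaffold = info$scaffold[i],
                           start = bounds[-length(bounds)],
                           end = bounds[-1L],
                           index = seq_len(length(bounds) - 1L))
  }
  rbindlist(out)
}

#' Uniform fragment map
#'
#' Builds a fragment map of fixed-size windows for sequence-free workflows
#' (e.g. simulated assemblies where no restriction sequence is modelled).
#'
#' @param scaffolds a [scaffold_set].
#' @param size fragment size in bp.
#' @return A fragment map as from [digest_scaffolds()].
#' @export
uniform_fragment_map <- function(scaffolds, size = 500L) {
  stopifnot(inherits(scaffolds, "scaffold_set"), size >= 1L)
  scaffolds$info[, {
    bounds <- unique(c(seq(0L, length, by = size), length))
    .(start = bounds[-base::length(bounds)], end = bounds[-1L],
      index = seq_len(base::length(bounds) - 1L))
  }, by = .(scaffold)]
}

#' Build a Hi-C link table from read pairs
#'
#' Assigns each mate of a Hi-C read pair to the restriction fragment
#' containing its position, drops pairs with both mates in the same
#' fragment (uninformative self-ligations), and aggregates the rest into
#' fragment-pair link counts. Link positions are reported at fragment
#' midpoints.
#'
#' @param pairs two-sided pair table (`scaffold1`, `pos1`, `scaffold2`,
#'   `pos2`, optional `mapq`) as from [read_hic_pairs()].
#' @param fragments fragment map from [digest_scaffolds()] or
#'   [uniform_fragment_map()].
#' @param min_mapq minimum mapping quality if a `mapq` column is present.
#' @return A link table: `data.table` with columns `scaffold1`, `pos1`,
#'   `fragment1`, `scaffold2`, `pos2`, `fragment2`, `count`, sides stored
#'   in canonical (lexicographic) order. The number of records rejected for
#'   out-of-bounds positions is attached as attribute `n_rejected`.
#' @export
build_links <- function(pairs, fragments, min_mapq = 0L) {
  lk <- as.data.table(pairs)
  if ("mapq" %in% names(lk)) lk <- lk[mapq >= min_mapq]
  frags <- as.data.table(fragments)
  setkey(frags, scaffold, start)
  assign_side <- function(scafs, pos) {
    q <- data.table(scaffold = scafs, start = pos, qpos = pos)
    hit <- frags[q, on = c("scaffold", "start"), roll = TRUE]
    fifelse(is.na(hit$index) | hit$qpos >= hit$end | hit$qpos < 0L,
            NA_integer_, hit$index)
  }
  lk[, fragment1 := assign_side(scaffold1, pos1)]
  lk[, fragment2 := assign_side(scaffold2, pos2)]
  n_rejected <- lk[is.na(fragment1) | is.na(fragment2), .N]
  lk <- lk[!is.na(fragment1) & !is.na(fragment2)]
  lk <- lk[!(scaffold1 == scaffold2 & fragment1 == fragment2)]
  mids <- frags[, .(scaffold, index, mid = as.integer((start + end) %/% 2))]
  lk[mids, pos1 := i.mid, on = c(scaffold1 = "scaffold", fragment1 = "index")]
  lk[mids, pos2 := i.mid, on = c(scaffold2 = "scaffold", fragment2 = "index")]
  lk <- canonical_link_fragments(lk)
  out <- lk[, .(count = .N),
            by = .(scaffold1, pos1, fragment1, scaffold2, pos2, fragment2)]
  setorder(out, scaffold1, pos1, scaffold2, pos2)
  setattr(out, "n_rejected", n_rejected)
  out[]
}

canonical_link_fragments <- function(lk) {
  flip <- lk$scaffold2 < lk$scaffold1 |
    (lk$scaffold2 == lk$scaffold1 & lk$pos2 < lk$pos1)
  if (any(flip)) {
    s <- lk$scaffold1[flip]; p <- lk$pos1[flip]; f <- lk$fragment1[flip]
    lk[flip, `:=`(scaffold1 = scaffold2, pos1 = pos2, fragment1 = fragment2)]
    lk[flip, `:=`(scaffold2 = s, pos2 = p, fragment2 = f)]
  }
  lk[]
}

#' Binned Hi-C contact matrices
#'
#' Bins intra-chromosomal links of each pseudomolecule (or scaffold) into a
#' symmetric contact-count matrix and balances it by the square root of
#' per-bin total coverage: `M'[i,j] = M[i,j] / (f[i] f[j])` with
#' `f[i] = sqrt(sum_j M[i,j])` (bins with zero coverage keep `f = 1`).
#'
#' @param links link table (or two-sided pair table) in the coordinates of
#'   `chrom_lengths`' objects; a `count` column is honoured if present.
#' @param chrom_lengths named vector of object lengths (or a
#'   [scaffold_set]).
#' @param bin_size bin width in bp (default 1 Mb).
#' @return A named list with one `contact_matrix` object per object: a list
#'   with elements `chromosome`, `bin_size`, `counts` (symmetric matrix),
#'   `normalized`, `f`.
#' @export
contact_matrix <- function(links, chrom_lengths, bin_size = 1000000L) {
  if (inherits(chrom_lengths, "scaffold_set"))
    chrom_lengths <- scaffold_lengths(chrom_lengths)
  lk <- as.data.table(links)
  if (!"count" %in% names(lk)) lk[, count := 1L]
  out <- list()
  for (chrom in names(chrom_lengths)) {
    n <- as.integer(ceiling(chrom_lengths[[chrom]] / bin_size))
    sub <- lk[scaffold1 == chrom & scaffold2 == chrom]
    M <- matrix(0, n, n)
    if (nrow(sub) > 0L) {
      b1 <- pmin(as.integer(sub$pos1 %/% bin_size), n - 1L) + 1L
      b2 <- pmin(as.integer(sub$pos2 %/% bin_size), n - 1L) + 1L
      for (k in seq_along(b1)) {
        M[b1[k], b2[k]] <- M[b1[k], b2[k]] + sub$count[k]
        if (b1[k] != b2[k]) M[b2[k], b1[k]] <- M[b2[k], b1[k]] + sub$count[k]
      }
    } else {
      warning("no intra-chromosomal links for ", chrom)
    }
    f <- sqrt(rowSums(M))
    f[f == 0] <- 1
    out[[chrom]] <- structure(
      list(chromosome = chrom, bin_size = as.integer(bin_size),
           counts = M, normalized = M / outer(f, f), f = f),
      class = "contact_matrix")
  }
  out
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s, %d bins of %s bp, %s links\n",
              x$chromosome, nrow(x$counts), format(x$bin_size, big.mark = ","),
              format(sum(x$counts[upper.tri(x$counts, diag = TRUE)]),
                     big.mark = ",")))
  invisible(x)
}

#' Plot a contact matrix as a heat map
#'
#' @param x a `contact_matrix` object.
#' @param normalized plot balanced values instead of raw counts.
#' @param ... passed to [graphics::image()].
#' @export
plot_contact_matrix <- function(x, normalized = TRUE, ...) {
  M <- if (normalized) x$normalized else x$counts
  graphics::image(log2(M + 1), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = x$chromosome, ylab = "", axes = FALSE, ...)
}

#' Directionality-bias track
#'
#' For each bin i of a contact matrix, compares upstream and downstream
#' contact mass within a window: `U` is the total contact count of bin i
#' with the `window` preceding bins, `D` with the `window` following bins,
#' and the statistic is `log2((U + 1) / (D + 1))`. Inverted or misplaced
#' blocks show up as sign discontinuities at their edges.
#'
#' @param cm a `contact_matrix` object (one chromosome).
#' @param window window size in bins (default 10).
#' @return A `data.table` with columns `bin` (0-based) and `bias`.
#' @export
directionality_bias <- function(cm, window = 10L) {
  stopifnot(inherits(cm, "contact_matrix"), window >= 1L)
  M <- cm$counts
  n <- nrow(M)
  if (window >= n) stop("window must be smaller than the matrix")
  u <- d <- numeric(n)
  for (i in seq_len(n)) {
    if (i > 1L) u[i] <- sum(M[i, max(1L, i - window):(i - 1L)])
    if (i < n) d[i] <- sum(M[i, (i + 1L):min(n, i + window)])
  }
  data.table(bin = seq_len(n) - 1L, bias = log2((u + 1) / (d + 1)))
}
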