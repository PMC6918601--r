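#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the
#' desk-scale study condition used throughout the test suite: three 5 Mb
#' chromosomes fragmented into 50 scaffolds each, five injected
#' inter-chromosomal chimeras, two Chromium libraries at 30-fold physical
#' molecule coverage with lognormal molecule lengths around 50 kb, Hi-C
#' links with power-law contact decay (exponent 1), and 20 markers per Mb
#' with a 1 cM/Mb genetic map compressed to a plateau over the middle of
#' each chromosome (mimicking pericentromeric recombination suppression).
#'
#' @param seed integer seed; every generator output is deterministic in it.
#' @param n_chromosomes,chromosome_length,n_scaffolds genome shape
#'   (scaffold count is per chromosome).
#' @param n_chimeras number of injected inter-chromosomal chimeric joins.
#' @param n_libraries number of Chromium libraries (>= 2; the link-graph
#'   edge rule requires support from more than one library).
#' @param mol_coverage physical molecule coverage (fold).
#' @param mol_len_mean,mol_len_sd molecule length distribution (lognormal,
#'   moments in bp).
#' @param pairs_per_molecule mean read pairs sampled per molecule (Poisson).
#' @param insert_size read-pair span in bp.
#' @param barcode_collision probability a molecule reuses an earlier
#'   barcode.
#' @param hic_link_density Hi-C links per kb of genome.
#' @param decay_alpha,decay_d0 contact decay `P(d) ~ (d + d0)^(-alpha)`.
#' @param hic_inter_frac fraction of inter-chromosomal background links.
#' @param marker_density markers per Mb.
#' @param marker_mismap fraction of markers assigned a wrong chromosome in
#'   the genetic map.
#' @param cm_per_mb genetic map slope outside the plateau.
#' @param cm_plateau two fractions of chromosome length bounding the
#'   recombination-suppressed plateau.
#' @param cm_resolution round cM values to this grid (0 = no rounding);
#'   coarse grids create cM ties that only Hi-C can resolve.
#' @param frag_min_len minimum scaffold fragment length in bp.
#' @param revcomp_prob probability a scaffold is stored reverse-complement
#'   to its chromosome.
#' @param with_sequence generate nucleotide sequence (needed for digestion
#'   and FASTA output; coordinate-level work runs without it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 3L,
                       chromosome_length = 5000000L, n_scaffolds = 50L,
                       n_chimeras = 5L, n_libraries = 2L,
                       mol_coverage = 30, mol_len_mean = 50000,
                       mol_len_sd = 15000, pairs_per_molecule = 30,
                       insert_size = 300L, barcode_collision = 0,
                       hic_link_density = 3, decay_alpha = 1,
                       decay_d0 = 10000, hic_inter_frac = 0.02,
                       marker_density = 20, marker_mismap = 0.05,
                       cm_per_mb = 1, cm_plateau = c(0.4, 0.6),
                       cm_resolution = 0, frag_min_len = 25000L,
                       revcomp_prob = 0.5, with_sequence = TRUE) {
  cfg <- as.list(environment())
  if (cfg$n_libraries < 2L) stop("at least two libraries are required")
  if (cfg$n_chimeras * 2L > cfg$n_chromosomes * cfg$n_scaffolds)
    stop("chimera count exceeds available scaffolds")
  if (cfg$pairs_per_molecule <= 0) stop("pair rate must be positive")
  if (cfg$decay_alpha <= 0) stop("decay exponent must be positive")
  stopifnot(cfg$seed < 2^31 - 10)
  structure(cfg, class = "sim_config")
}

#' Simulate a truth genome fragmented into scaffolds
#'
#' Generates random nucleotide chromosomes, fragments each into scaffolds
#' of random lengths (at least `frag_min_len`), stores each scaffold in a
#' random orientation under a shuffled name, and injects inter-chromosomal
#' chimeras by concatenating scaffolds from different chromosomes at
#' recorded junctions. Molecules, links and markers are later simulated on
#' the chromosomes and projected through the truth segments, so no
#' evidence ever spans a chimeric junction — the defining signal that
#' physical coverage drops to background at false joins.
#'
#' @param config a [sim_config()].
#' @return A list with `scaffolds` (a [scaffold_set]) and `truth`: a list
#'   holding `segments` (scaffold <-> chromosome interval map with
#'   orientation), `junctions` (chimeric breakpoints: `scaffold`,
#'   `position`), and `chrom_lengths`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  L <- config$chromosome_length
  nsc <- config$n_scaffolds
  segs <- list()
  for (ci in seq_along(chroms)) {
    lens <- random_partition(L, nsc, config$frag_min_len)
    bounds <- c(0L, cumsum(lens))
    segs[[ci]] <- data.table(chromosome = chroms[ci],
                             chr_start = bounds[-(nsc + 1L)],
                             chr_end = bounds[-1L])
  }
  segs <- rbindlist(segs)
  n_total <- nrow(segs)
  ## shuffled names so that name order carries no positional information
  segs[, scaffold := sprintf("scaffold_%05d", sample(n_total))]
  segs[, orientation := fifelse(runif(n_total) < config$revcomp_prob, "-", "+")]
  segs[, `:=`(scaf_start = 0L, scaf_end = chr_end - chr_start)]
  ## inject chimeras: append scaffold B of another chromosome to scaffold A
  junctions <- data.table(scaffold = character(), position = integer())
  if (config$n_chimeras > 0L) {
    ## draw partners from chromosome-interior fragments: a join at a
    ## telomeric fragment abuts a genuine coverage ramp (molecules cannot
    ## extend past the chromosome end), so the junction has no two-sided
    ## physical-coverage signal and is not a representative chimera
    interior <- segs[chr_start > 0L & chr_end < L]
    pool <- interior[sample(.N)]
    used <- character(0)
    for (k in seq_len(config$n_chimeras)) {
      cand <- pool[!scaffold %in% used]
      if (nrow(cand) < 2L) break
      a <- cand[1L]
      b <- cand[chromosome != a$chromosome][1L]
      if (nrow(b) == 0L || is.na(b$scaffold)) break
      used <- c(used, a$scaffold, b$scaffold)
      alen <- a$scaf_end - a$scaf_start
      blen <- b$scaf_end - b$scaf_start
      segs[scaffold == b$scaffold,
           `:=`(scaffold = a$scaffold, scaf_start = alen,
                scaf_end = alen + blen)]
      junctions <- rbind(junctions,
                         data.table(scaffold = a$scaffold, position = alen))
    }
  }
  info <- segs[, .(length = max(scaf_end)), by = .(scaffold)]
  seq <- NULL
  if (config$with_sequence) {
    chrseq <- lapply(chroms, function(ch)
      paste(c("A", "C", "G", "T")[sample.int(4L, L, replace = TRUE)],
            collapse = ""))
    names(chrseq) <- chroms
    sset <- segs[order(scaffold, scaf_start)]
    pieces <- vapply(seq_len(nrow(sset)), function(i) {
      s <- substr(chrseq[[sset$chromosome[i]]], sset$chr_start[i] + 1L,
                  sset$chr_end[i])
      if (sset$orientation[i] == "-")
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s
    }, character(1))
    seqdt <- data.table(scaffold = sset$scaffold, piece = pieces)
    seqv <- seqdt[, .(s = paste(piece, collapse = "")), by = .(scaffold)]
    seq <- Biostrings::DNAStringSet(setNames(seqv$s, seqv$scaffold))
  }
  truth <- list(segments = segs[order(chromosome, chr_start)],
                junctions = junctions,
                chrom_lengths = setNames(rep(L, length(chroms)), chroms))
  list(scaffolds = scaffold_set(info, seq), truth = truth)
}

## partition total into n parts of at least min_len
random_partition <- function(total, n, min_len) {
  if (n * min_len > total) stop("cannot fragment: minimum lengths exceed total")
  rest <- total - n * min_len
  w <- runif(n)
  extra <- floor(rest * w / sum(w))
  extra[n] <- rest - sum(extra[-n])
  as.integer(min_len + extra)
}

## project chromosome points onto scaffold coordinates
project_points <- function(segments, chrom, pos) {
  key <- segments[, .(chromosome, chr_start, cs = chr_start, chr_end,
                      scaffold, scaf_start, orientation)]
  setkey(key, chromosome, chr_start)
  q <- data.table(chromosome = chrom, chr_start = pos)
  hit <- key[q, on = c("chromosome", "chr_start"), roll = TRUE]
  ok <- !is.na(hit$scaffold) & pos < hit$chr_end
  sp <- fifelse(hit$orientation == "+", hit$scaf_start + (pos - hit$cs),
                hit$scaf_start + (hit$chr_end - 1L - pos))
  data.table(scaffold = hit$scaffold, pos = as.integer(sp), ok = ok)
}

## project chromosome intervals fully contained in one truth segment;
## intervals crossing segment boundaries are dropped
project_intervals <- function(segments, dt) {
  pm <- segments[, .(chromosome, cs = chr_start, ce = chr_end, scaffold,
                     scaf_start, orientation)]
  setkey(pm, chromosome, cs, ce)
  q <- copy(dt)[, `:=`(s = start, e = end)]
  ov <- foverlaps(q, pm, by.x = c("chromosome", "s", "e"),
                  by.y = c("chromosome", "cs", "ce"), type = "within",
                  nomatch = NULL)
  ov[, start := fifelse(orientation == "+", scaf_start + (s - cs),
                        scaf_start + (ce - e))]
  ov[, end := start + (e - s)]
  ov[, c("s", "e", "cs", "ce", "scaf_start", "orientation",
         "chromosome") := NULL]
  ov[]
}

#' Simulate barcoded molecules and their read pairs
#'
#' Places molecules with lognormal lengths uniformly along the truth
#' chromosomes at the configured physical coverage, assigns each a unique
#' barcode (up to the configured collision rate) and a library, samples
#' Poisson-many read pairs per molecule, and projects the pairs onto
#' scaffold coordinates through the truth segments. Pairs crossing a
#' segment boundary (scaffold end or chimeric junction) are dropped, as
#' split alignments would be in practice.
#'
#' @param truth truth object from [simulate_genome()].
#' @param config the [sim_config()].
#' @return A pair table (`scaffold`, `start`, `end`, `barcode`, `library`,
#'   `mapq`) sorted by `(barcode, scaffold, start)`.
#' @export
simulate_molecules <- function(truth, config) {
  set.seed(config$seed + 1L)
  segs <- truth$segments
  sdlog <- sqrt(log(1 + (config$mol_len_sd / config$mol_len_mean)^2))
  meanlog <- log(config$mol_len_mean) - sdlog^2 / 2
  mols <- list()
  total_prev <- 0L
  for (ch in names(truth$chrom_lengths)) {
    L <- truth$chrom_lengths[[ch]]
    n <- round(config$mol_coverage * L / config$mol_len_mean)
    len <- pmin(pmax(round(rlnorm(n, meanlog, sdlog)), 1000), L - 1L)
    s <- floor(runif(n, 0, L - len))
    mols[[ch]] <- data.table(chromosome = ch, mol_s = as.integer(s),
                             mol_e = as.integer(s + len),
                             mol_id = total_prev + seq_len(n))
    total_prev <- total_prev + n
  }
  mols <- rbindlist(mols)
  n <- nrow(mols)
  mols[, barcode := sprintf("BC%08d", mol_id)]
  if (config$barcode_collision > 0 && n > 1L) {
    hit <- which(runif(n) < config$barcode_collision)
    if (length(hit) > 0L && length(hit) < n) {
      donors <- sample(mols$barcode[-hit], length(hit), replace = TRUE)
      mols[hit, barcode := donors]
    }
  }
  mols[, lib := sprintf("L%d", sample.int(config$n_libraries, n, replace = TRUE))]
  npairs <- rpois(n, config$pairs_per_molecule)
  idx <- rep(seq_len(n), npairs)
  pm <- mols[idx]
  span <- pmax(pm$mol_e - pm$mol_s - config$insert_size, 1L)
  ps <- pm$mol_s + floor(runif(nrow(pm), 0, span))
  pairs <- data.table(chromosome = pm$chromosome, start = as.integer(ps),
                      end = as.integer(pmin(ps + config$insert_size, pm$mol_e)),
                      barcode = pm$barcode, library = pm$lib)
  out <- project_intervals(segs, pairs)
  out[, mapq := 60L]
  setcolorder(out, c("scaffold", "start", "end", "barcode", "library", "mapq"))
  setorder(out, barcode, scaffold, start, end)
  out[]
}

#' Simulate Hi-C read pairs with contact decay
#'
#' Samples intra-chromosomal link distances from the power-law decay
#' `P(d) ~ (d + d0)^(-alpha)` (inverse-CDF sampling, truncated at the
#' chromosome length) plus a background fraction of inter-chromosomal
#' pairs, and projects both sides onto scaffold coordinates. Links never
#' cross chimeric junctions, since they are generated on the truth
#' chromosomes.
#'
#' @param truth truth object from [simulate_genome()].
#' @param config the [sim_config()].
#' @return A two-sided pair table (`scaffold1`, `pos1`, `scaffold2`,
#'   `pos2`, `mapq`) in canonical side order.
#' @export
simulate_hic <- function(truth, config) {
  set.seed(config$seed + 2L)
  segs <- truth$segments
  cl <- truth$chrom_lengths
  genome <- sum(as.numeric(cl))
  n <- round(config$hic_link_density * genome / 1000)
  inter <- runif(n) < config$hic_inter_frac
  chrom1 <- sample(names(cl), n, replace = TRUE, prob = as.numeric(cl))
  p1 <- floor(runif(n) * cl[chrom1])
  d <- sample_decay(sum(!inter), config$decay_alpha, config$decay_d0,
                    max(cl) - 1)
  chrom2 <- chrom1
  p2 <- numeric(n)
  ## place the intra partner up- or downstream, respecting bounds
  ii <- which(!inter)
  up_ok <- p1[ii] - d >= 0
  dn_ok <- p1[ii] + d <= cl[chrom1[ii]] - 1
  dir_up <- fifelse(up_ok & dn_ok, runif(length(ii)) < 0.5, up_ok)
  p2[ii] <- fifelse(dir_up, p1[ii] - d, p1[ii] + d)
  if (any(inter)) {
    jj <- which(inter)
    chrom2[jj] <- sample(names(cl), length(jj), replace = TRUE,
                         prob = as.numeric(cl))
    p2[jj] <- floor(runif(length(jj)) * cl[chrom2[jj]])
  }
  p2 <- pmin(pmax(p2, 0), cl[chrom2] - 1)
  a <- project_points(segs, chrom1, as.integer(p1))
  b <- project_points(segs, chrom2, as.integer(p2))
  keep <- a$ok & b$ok
  lk <- data.table(scaffold1 = a$scaffold[keep], pos1 = a$pos[keep],
                   scaffold2 = b$scaffold[keep], pos2 = b$pos[keep],
                   mapq = 60L)
  canonical_link_sides(lk)
}

## inverse-CDF sample from density (d + d0)^(-alpha) on [0, dmax]
sample_decay <- function(n, alpha, d0, dmax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-9) {
    d <- d0 * ((1 + dmax / d0)^u - 1)
  } else {
    a1 <- 1 - alpha
    lo <- d0^a1
    hi <- (d0 + dmax)^a1
    d <- (lo + u * (hi - lo))^(1 / a1) - d0
  }
  pmin(pmax(round(d), 0), dmax)
}

#' Simulate genetic-map markers
#'
#' Markers are placed uniformly along the truth chromosomes; their genetic
#' position follows a monotone 1 cM/Mb map flattened to a plateau over the
#' configured central fraction of each chromosome (recombination
#' suppression), optionally rounded to a cM grid. A configurable fraction
#' of markers is assigned a wrong chromosome in the genetic map, leaving
#' the alignment position untouched — emulating mis-mapped markers.
#'
#' @param truth truth object from [simulate_genome()].
#' @param config the [sim_config()].
#' @return A list with `markers` (alignment table: `marker`, `scaffold`,
#'   `position`, `aln_len`, `identity`) and `genetic_map` (`marker`,
#'   `chromosome`, `cM`).
#' @export
simulate_markers <- function(truth, config) {
  set.seed(config$seed + 3L)
  if (config$marker_density <= 0) stop("marker density must be positive")
  segs <- truth$segments
  cl <- truth$chrom_lengths
  out_m <- list(); out_g <- list()
  mk_id <- 0L
  for (ch in names(cl)) {
    L <- cl[[ch]]
    n <- rpois(1L, config$marker_density * L / 1e6)
    pos <- sort(floor(runif(n, 0, L)))
    cm <- genetic_position(pos, L, config$cm_per_mb, config$cm_plateau)
    if (config$cm_resolution > 0)
      cm <- round(cm / config$cm_resolution) * config$cm_resolution
    ids <- sprintf("mk_%06d", mk_id + seq_len(n))
    mk_id <- mk_id + n
    map_chr <- rep(ch, n)
    wrong <- runif(n) < config$marker_mismap
    if (any(wrong) && length(cl) > 1L)
      map_chr[wrong] <- vapply(which(wrong), function(i)
        sample(setdiff(names(cl), ch), 1L), character(1))
    pr <- project_points(segs, rep(ch, n), as.integer(pos))
    out_m[[ch]] <- data.table(marker = ids, scaffold = pr$scaffold,
                              position = pr$pos, aln_len = 500L,
                              identity = 0.99)[pr$ok]
    out_g[[ch]] <- data.table(marker = ids, chromosome = map_chr, cM = cm)
  }
  list(markers = rbindlist(out_m), genetic_map = rbindlist(out_g))
}

## monotone physical -> genetic map with a central plateau
genetic_position <- function(pos, L, cm_per_mb, plateau) {
  a <- plateau[1] * L; b <- plateau[2] * L
  eff <- ifelse(pos < a, pos, ifelse(pos < b, a, pos - (b - a)))
  cm_per_mb * eff / 1e6
}

#' Run the complete simulator
#'
#' @param config a [sim_config()].
#' @return A list with `config`, `scaffolds`, `truth`, `pairs` (linked-read
#'   pair table), `hic_pairs`, `markers`, `genetic_map`.
#' @export
simulate_all <- function(config = sim_config()) {
  g <- simulate_genome(config)
  mk <- simulate_markers(g$truth, config)
  list(config = config, scaffolds = g$scaffolds, truth = g$truth,
       pairs = simulate_molecules(g$truth, config),
       hic_pairs = simulate_hic(g$truth, config),
       markers = mk$markers, genetic_map = mk$genetic_map)
}
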