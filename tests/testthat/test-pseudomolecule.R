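anchor_row <- function(unit, chr, cm)
  data.table(scaffold = unit, chromosome = chr, cM = cm,
             n_markers = 5L, n_concordant = 5L)

test_that("distinct genetic positions alone fix the order", {
  anch <- rbindlist(Map(anchor_row, c("u3", "u1", "u2"), "1H", c(30, 10, 20)))
  ord <- order_superscaffolds(anch, data.table(scaffold1 = character(),
                                               pos1 = integer(),
                                               scaffold2 = character(),
                                               pos2 = integer()))
  expect_equal(ord[order(rank), unit], c("u1", "u2", "u3"))
  expect_true(all(ord$orientation == "+"))
})

test_that("contacts break cM ties towards the supported adjacency", {
  anch <- rbindlist(Map(anchor_row, c("a", "b", "c"), "1H", c(10, 20, 20)))
  ## b and c tie at 20 cM; contacts say a-c are adjacent
  lk <- data.table(scaffold1 = rep("a", 30), pos1 = 1000L,
                   scaffold2 = rep("c", 30), pos2 = 1000L)
  ord <- order_superscaffolds(anch, lk)
  expect_equal(ord[order(rank), unit], c("a", "c", "b"))
})

test_that("units without cM are inserted by contact gain", {
  anch <- rbind(rbindlist(Map(anchor_row, c("a", "b"), "1H", c(10, 20))),
                anchor_row("x", "1H", NA_real_))
  lk <- rbind(
    data.table(scaffold1 = rep("a", 20), pos1 = 1000L,
               scaffold2 = rep("x", 20), pos2 = 1000L),
    data.table(scaffold1 = rep("b", 20), pos1 = 1000L,
               scaffold2 = rep("x", 20), pos2 = 1000L))
  ord <- order_superscaffolds(anch, lk)
  expect_equal(ord[order(rank), unit], c("a", "x", "b"))
  ## a chromosome with no anchored units warns
  expect_warning(order_superscaffolds(anchor_row("z", NA_character_, NA)[0],
                                      lk), "no anchored")
})

test_that("Hi-C orientation follows contact decay towards neighbors", {
  ord <- data.table(chromosome = "1H", rank = 1:2, unit = c("u", "v"),
                    orientation = "+", cM = c(1, 2))
  ul <- c(u = 200000L, v = 200000L)
  ## u's high coordinates link to v: forward
  lk <- data.table(scaffold1 = rep("u", 20),
                   pos1 = as.integer(seq(150000, 199000, length.out = 20)),
                   scaffold2 = "v", pos2 = 1000L)
  o1 <- orient_by_hic(ord, lk, ul)
  expect_equal(o1[unit == "u", orientation], "+")
  ## mirrored evidence: reverse
  lk2 <- copy(lk)[, pos1 := 200000L - pos1]
  o2 <- orient_by_hic(ord, lk2, ul)
  expect_equal(o2[unit == "u", orientation], "-")
  ## no contacts: flag stays FALSE, orientation kept
  o3 <- orient_by_hic(ord, lk[0], ul)
  expect_equal(o3$orientation, c("+", "+"))
  expect_false(any(o3$informative))
})

test_that("genetic-map gradients orient single units", {
  ord <- data.table(chromosome = "1H", rank = 1L, unit = "u",
                    orientation = "+", cM = 1)
  mk <- data.table(marker = sprintf("m%d", 1:6), scaffold = "u",
                   position = as.integer(seq(1000, 60000, length.out = 6)),
                   aln_len = 500L, identity = 0.99)
  gm_fwd <- data.table(marker = mk$marker, chromosome = "1H", cM = 1:6)
  gm_rev <- data.table(marker = mk$marker, chromosome = "1H", cM = 6:1)
  expect_equal(orient_by_cm(ord, mk, gm_fwd)$orientation, "+")
  expect_equal(orient_by_cm(ord, mk, gm_rev)$orientation, "-")
})

test_that("curation edits are applied in order with a full audit", {
  ord <- data.table(chromosome = "1H", rank = 1:3,
                    unit = c("u1", "u2", "u3"), orientation = "+",
                    cM = c(1, 2, 3))
  ed <- data.table(action = c("invert", "invert", "move"),
                   target = c("u2", "u2", "u3"),
                   chromosome = NA_character_, rank = c(NA, NA, 1L),
                   position = NA_integer_)
  res <- apply_edits(ord, ed)
  ## double inversion is the identity
  expect_equal(res$chrom_order[unit == "u2", orientation], "+")
  expect_equal(res$chrom_order[order(rank), unit], c("u3", "u1", "u2"))
  expect_equal(nrow(res$audit), 3L)
  ## empty edit table is a no-op
  res0 <- apply_edits(ord, ed[0])
  expect_equal(as.data.frame(res0$chrom_order[order(rank)]),
               as.data.frame(ord))
  expect_error(apply_edits(ord, data.table(action = "invert",
                                           target = "nope",
                                           chromosome = NA_character_,
                                           rank = NA_integer_,
                                           position = NA_integer_)),
               "unknown target")
})

test_that("break edits split a placed singleton unit in place", {
  ord <- data.table(chromosome = "1H", rank = 1:2, unit = c("s1", "s2"),
                    orientation = "+", cM = c(1, 2))
  ss <- scaffold_set(c(s1 = 10000L, s2 = 5000L))
  ed <- data.table(action = "break", target = "s1",
                   chromosome = NA_character_, rank = NA_integer_,
                   position = 4000L)
  res <- apply_edits(ord, ed, ss)
  expect_equal(res$chrom_order[order(rank), unit],
               c("s1_p1", "s1_p2", "s2"))
  expect_equal(unname(scaffold_lengths(res$scaffolds)[c("s1_p1", "s1_p2")]),
               c(4000L, 6000L))
})

test_that("edits files round-trip through read_edits", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("action\ttarget\tchromosome\trank\tposition",
               "invert\tu1\t\t\t", "move\tu2\t1H\t3\t"), path)
  ed <- read_edits(path)
  expect_equal(ed$action, c("invert", "move"))
  expect_equal(ed$rank, c(NA_integer_, 3L))
})

test_that("pseudomolecule building concatenates, gaps and reverse-complements", {
  set.seed(91)
  s1 <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  ss <- scaffold_set(seq = c(m1 = s1, m2 = s2))
  ord <- data.table(chromosome = "1H", rank = 1:2, unit = c("m1", "m2"),
                    orientation = c("+", "-"), cM = c(1, 2))
  ssmap <- data.table(member = c("m1", "m2"), unit = c("m1", "m2"),
                      offset = 0L, orientation = "+",
                      member_length = c(10000L, 5000L))
  pm <- build_pseudomolecules(ord, ssmap, ss, gap = 100L,
                              chrun_min_len = 1000L)
  expect_equal(unname(pm$lengths["1H"]), 15100)
  chr <- as.character(pm$assembly$seq[["1H"]])
  expect_equal(substr(chr, 1, 10000), s1)
  expect_equal(substr(chr, 10001, 10100), strrep("N", 100))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s2)))
  expect_equal(substr(chr, 10101, 15100), rc)
  ## AGP agrees with FASTA lengths for every object
  agp_len <- pm$layout[, max(object_end), by = object]
  expect_equal(unname(scaffold_lengths(pm$assembly)[agp_len$object]),
               agp_len$V1)
  ## conservation: pseudomolecule bases minus gaps = placed scaffold bases
  gaps <- pm$layout[component_type == "U", sum(gap_length)]
  expect_equal(sum(pm$lengths) - gaps, sum(scaffold_lengths(ss)))
})

test_that("unplaced scaffolds go to chrUn above the length floor", {
  ss <- scaffold_set(c(a = 10000L, b = 3000L, c = 500L))
  ord <- data.table(chromosome = "1H", rank = 1L, unit = "a",
                    orientation = "+", cM = 1)
  ssmap <- data.table(member = "a", unit = "a", offset = 0L,
                      orientation = "+", member_length = 10000L)
  pm <- build_pseudomolecules(ord, ssmap, ss, gap = 100L,
                              chrun_min_len = 1000L)
  expect_equal(pm$layout[object == "chrUn", component], "b")
  expect_false("c" %in% pm$layout$component)  # below the chrUn floor
  expect_error(build_pseudomolecules(
    ord[, .(chromosome, rank, unit = "ghost", orientation, cM)],
    ssmap[0], ss), "missing")
})

test_that("random layouts keep AGP and FASTA consistent", {
  set.seed(92)
  for (rep in 1:3) {
    n <- sample(3:6, 1)
    lens <- sample(2000:8000, n)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("sc%d", seq_len(n))
    ss <- scaffold_set(seq = seqs)
    ord <- data.table(chromosome = "chrA", rank = seq_len(n),
                      unit = sample(names(seqs)),
                      orientation = sample(c("+", "-"), n, TRUE), cM = 1)
    ssmap <- data.table(member = names(seqs), unit = names(seqs),
                        offset = 0L, orientation = "+",
                        member_length = lens)
    pm <- build_pseudomolecules(ord, ssmap, ss, gap = 50L)
    expect_silent(validate <- write_agp(pm$layout, tempfile()))
    expect_equal(unname(pm$lengths["chrA"]),
                 sum(lens) + 50 * (n - 1))
    expect_equal(nchar(as.character(pm$assembly$seq[["chrA"]])),
                 unname(pm$lengths["chrA"]))
  }
})

test_that("collinearity statistics match hand-computed values", {
  ## assembly compared to itself: r = 1, concordance = 1
  self <- data.table(qname = sprintf("s1:%d", seq(0, 40000, by = 10000)),
                     strand = "+", tname = "s1",
                     tstart = seq(0, 40000, by = 10000), aln_len = 10000L)
  ev <- collinearity_eval(self, min_aligned = 10000L)
  expect_equal(ev$pairs$r, 1)
  expect_equal(ev$pairs$concordance, 1)
  ## reversed target: r = -1, concordance still 1 (uniformly minus)
  rev <- copy(self)[, `:=`(strand = "-", tstart = rev(tstart))]
  ev2 <- collinearity_eval(rev, min_aligned = 10000L)
  expect_equal(ev2$pairs$r, -1)
  expect_equal(ev2$pairs$concordance, 1)
  ## 5-fragment manual fixture with one off-diagonal fragment and mixed
  ## strands: weighted means computed by hand
  fix <- data.table(qname = sprintf("sA:%d", c(0, 10000, 20000, 30000, 40000)),
                    strand = c("+", "+", "+", "-", "+"), tname = "sB",
                    tstart = c(100, 10100, 20100, 39100, 40100),
                    aln_len = c(10000L, 10000L, 10000L, 5000L, 10000L))
  ev3 <- collinearity_eval(fix, min_aligned = 10000L)
  expect_equal(ev3$pairs$concordance, 40000 / 45000)
  expect_equal(ev3$pairs$r,
               cor(c(0, 10000, 20000, 30000, 40000),
                   c(100, 10100, 20100, 39100, 40100)))
  expect_equal(ev3$mean_r, ev3$pairs$r)
  ## pairs below the aligned-bp floor are skipped
  expect_equal(nrow(collinearity_eval(fix, min_aligned = 1e6)$pairs), 0L)
})

test_that("fragment_assembly tiles scaffolds without overlap", {
  ss <- scaffold_set(c(a = 25000L, b = 9999L))
  fr <- fragment_assembly(ss, fragment = 10000L)
  expect_equal(fr[scaffold == "a", start], c(0L, 10000L, 20000L))
  expect_equal(fr[scaffold == "a", end], c(10000L, 20000L, 25000L))
  expect_equal(fr[scaffold == "b", .N], 1L)
  expect_equal(fr$fragment[1], "a:0")
})
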