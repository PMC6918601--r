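## deterministic coverage profile builder: one scaffold, given raw counts
fake_profile <- function(raw, bin_size = 200L, expected = NULL) {
  n <- length(raw)
  prof <- data.table(scaffold = "s", bin = seq_len(n) - 1L,
                     start = (seq_len(n) - 1L) * bin_size,
                     end = seq_len(n) * bin_size,
                     dist_end = pmin(seq_len(n) - 1L, n - seq_len(n)),
                     raw = as.integer(raw))
  prof[, expected := if (is.null(expected)) mean(raw) else expected]
  prof[, ratio := log2((raw + 1) / (expected + 1))]
  setattr(prof, "bin_size", bin_size)
  prof
}

test_that("uniform coverage yields no breakpoints", {
  prof <- fake_profile(rep(30L, 600))  # 120 kb scaffold
  expect_equal(nrow(detect_breakpoints(prof, baseline_min_len = 0)), 0L)
  expect_equal(nrow(detect_breakpoints(fake_profile(integer(0))[0])), 0L)
})

test_that("a clean trough is localized to its zero bin", {
  raw <- rep(30L, 600)
  raw[300:302] <- 0L  # bins 299-301 (0-based), centre 300
  prof <- fake_profile(raw)
  bp <- detect_breakpoints(prof, baseline_min_len = 0)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$bin, 300L)
  expect_equal(bp$position, 300L * 200L + 100L)
  expect_equal(bp$evidence, "tenx")
})

test_that("breakpoints closer than the minimum separation keep the deepest", {
  raw <- rep(30L, 600)
  raw[200] <- 1L   # shallower trough
  raw[400] <- 0L   # deeper trough, 40 kb away
  prof <- fake_profile(raw)
  bp <- detect_breakpoints(prof, min_separation = 50000L,
                           baseline_min_len = 0)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$bin, 399L)
  ## with a smaller separation both survive
  bp2 <- detect_breakpoints(prof, min_separation = 10000L,
                            baseline_min_len = 0)
  expect_equal(nrow(bp2), 2L)
})

test_that("troughs without flank recovery are rejected", {
  ## long monotone ramp into the scaffold end, as at a telomere: bins fall
  ## below threshold well inside the trusted zone, but coverage never
  ## recovers on the distal side
  raw <- c(rep(30L, 400), as.integer(round(seq(30, 0, length.out = 700))))
  prof <- fake_profile(raw)
  expect_equal(nrow(detect_breakpoints(prof, baseline_min_len = 0)), 0L)
  ## the same depth of trough with recovering flanks IS called
  raw2 <- rep(30L, 1100)
  raw2[700:705] <- 0L
  expect_equal(nrow(detect_breakpoints(fake_profile(raw2),
                                       baseline_min_len = 0)), 1L)
})

test_that("breaking scaffolds splits sequence, lifts evidence, conserves bases", {
  sq <- paste(rep(c("A", "C", "G", "T"), each = 25), collapse = "")
  ss <- scaffold_set(seq = c(s1 = strrep(sq, 50), s2 = strrep("A", 3000)))
  expect_equal(unname(scaffold_lengths(ss)), c(5000L, 3000L))
  bp <- data.table(scaffold = "s1", position = 3320L)
  mols <- data.table(scaffold = c("s1", "s1", "s2"),
                     start = c(1000L, 3000L, 100L),
                     end = c(2000L, 4000L, 200L),
                     barcode = c("b1", "b2", "b3"), library = "L1",
                     n_pairs = c(10L, 10L, 2L))
  mk <- data.table(marker = c("m1", "m2"), scaffold = "s1",
                   position = c(3000L, 4000L), aln_len = 500L,
                   identity = 0.99)
  lk <- data.table(scaffold1 = "s1", pos1 = 3000L,
                   scaffold2 = "s1", pos2 = 4500L)
  br <- break_scaffolds(ss, bp, molecules = mols, markers = mk, links = lk)
  expect_equal(sort(scaffold_names(br$scaffolds)), c("s1_p1", "s1_p2", "s2"))
  expect_equal(unname(scaffold_lengths(br$scaffolds)[c("s1_p1", "s1_p2")]),
               c(3320L, 1680L))
  ## base conservation, sequence included
  expect_equal(sum(scaffold_lengths(br$scaffolds)), sum(scaffold_lengths(ss)))
  joined <- paste0(as.character(br$scaffolds$seq[["s1_p1"]]),
                   as.character(br$scaffolds$seq[["s1_p2"]]))
  expect_equal(joined, as.character(ss$seq[["s1"]]))
  ## molecule spanning the cut is split at it
  m2 <- br$molecules[barcode == "b2"]
  expect_equal(nrow(m2), 2L)
  expect_equal(m2[scaffold == "s1_p1", c(start, end)], c(3000L, 3320L))
  expect_equal(m2[scaffold == "s1_p2", c(start, end)], c(0L, 680L))
  ## markers become piece-local points; link sides reassigned independently
  expect_equal(br$markers[marker == "m2", .(scaffold, position)],
               data.table(scaffold = "s1_p2", position = 680L))
  expect_equal(br$links$scaffold1, "s1_p1")
  expect_equal(br$links$scaffold2, "s1_p2")
  expect_equal(br$links$pos2, 4500L - 3320L)
  ## no breakpoints: identity
  br0 <- break_scaffolds(ss, bp[0], molecules = mols)
  expect_equal(scaffold_lengths(br0$scaffolds), scaffold_lengths(ss))
  expect_equal(as.data.frame(br0$molecules), as.data.frame(mols))
  expect_error(break_scaffolds(ss, data.table(scaffold = "s1",
                                              position = 6000L)),
               "outside")
  expect_error(break_scaffolds(ss, data.table(scaffold = "zz",
                                              position = 10L)),
               "unknown")
})

test_that("random cuts lift every coordinate by plain arithmetic", {
  set.seed(41)
  ss <- scaffold_set(c(s = 100000L))
  cuts <- sort(sample(5000:95000, 3))
  bp <- data.table(scaffold = "s", position = cuts)
  mk <- data.table(marker = sprintf("m%d", 1:200), scaffold = "s",
                   position = as.integer(runif(200, 0, 100000)),
                   aln_len = 500L, identity = 0.99)
  br <- break_scaffolds(ss, bp, markers = mk)
  bounds <- c(0L, cuts, 100000L)
  for (i in seq_len(200)) {
    p <- mk$position[i]
    piece <- findInterval(p, bounds, rightmost.closed = FALSE)
    lifted <- br$markers[marker == sprintf("m%d", i)]
    expect_equal(lifted$scaffold, sprintf("s_p%d", piece))
    expect_equal(lifted$position, p - bounds[piece])
  }
})

test_that("a clean assembly reaches the fixpoint with zero cuts", {
  cfg <- sim_config(seed = 61, n_chromosomes = 2, chromosome_length = 2e6,
                    n_scaffolds = 15, n_chimeras = 0, with_sequence = FALSE)
  sim <- simulate_all(cfg)
  fix <- correct_to_fixpoint(sim$scaffolds, sim$pairs, markers = sim$markers)
  expect_equal(fix$rounds, 1L)
  expect_equal(nrow(fix$audit[action == "cut"]), 0L)
  expect_equal(scaffold_lengths(fix$scaffolds), scaffold_lengths(sim$scaffolds))
})

test_that("correction converges, conserves bases and is idempotent", {
  cfg <- sim_config(seed = 62, n_chromosomes = 2, chromosome_length = 2e6,
                    n_scaffolds = 15, n_chimeras = 2, with_sequence = FALSE)
  sim <- simulate_all(cfg)
  fix <- correct_to_fixpoint(sim$scaffolds, sim$pairs,
                             hic_pairs = sim$hic_pairs, markers = sim$markers)
  expect_equal(sum(scaffold_lengths(fix$scaffolds)),
               sum(scaffold_lengths(sim$scaffolds)))
  expect_gte(length(fix$scaffolds), length(sim$scaffolds))
  ev <- eval_breakpoints(fix$audit, sim$truth$junctions)
  expect_equal(ev$recall, 1)
  ## re-running on the corrected output is a no-op
  fix2 <- correct_to_fixpoint(fix$scaffolds, fix$pairs,
                              hic_pairs = fix$hic_pairs,
                              markers = fix$markers)
  expect_equal(fix2$rounds, 1L)
  expect_equal(nrow(fix2$audit[action == "cut"]), 0L)
  expect_equal(scaffold_lengths(fix2$scaffolds),
               scaffold_lengths(fix$scaffolds))
})

test_that("audit logs serialize as JSON lines", {
  audit <- data.table(round = 1L, scaffold = "s", position = 100L,
                      evidence = "tenx", trough = -3.2, action = "cut",
                      orig_scaffold = "s", orig_position = 100L)
  path <- tempfile(fileext = ".jsonl")
  write_audit_log(audit, path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(rec$scaffold, "s")
  expect_equal(rec$action, "cut")
})
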