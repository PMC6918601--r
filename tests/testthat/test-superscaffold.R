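## molecule table with controlled end-window support: each row one molecule
mol_row <- function(scaffold, start, end, barcode, library = "L1",
                    n_pairs = 5L)
  data.table(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), barcode = barcode, library = library,
             n_pairs = n_pairs)

test_that("edges need two libraries and compatible anchors", {
  ss <- scaffold_set(c(a = 200000L, b = 200000L))
  ## 5 linking barcodes, all from one library: no edge
  mols <- rbindlist(lapply(1:5, function(i) rbind(
    mol_row("a", 150000, 199000, sprintf("bc%d", i)),
    mol_row("b", 0, 50000, sprintf("bc%d", i)))))
  g1 <- build_link_graph(mols, ss)
  expect_equal(nrow(g1$edges), 0L)
  ## second library on some barcodes: edge appears
  mols2 <- copy(mols)[barcode %in% c("bc1", "bc2"), library := "L2"]
  g2 <- build_link_graph(mols2, ss)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$n_molecules, 5L)
  ## scaffolds anchored to different chromosomes: edge rejected
  anch <- data.table(scaffold = c("a", "b"), chromosome = c("2H", "5H"),
                     cM = c(50, 50), n_markers = 5L, n_concordant = 5L)
  g3 <- build_link_graph(mols2, ss, anch)
  expect_equal(nrow(g3$edges), 0L)
  ## same chromosome but > 5 cM apart: rejected; within 5 cM: kept
  anch[, chromosome := "2H"]
  anch[2, cM := 58]
  expect_equal(nrow(build_link_graph(mols2, ss, anch)$edges), 0L)
  anch[2, cM := 54]
  expect_equal(nrow(build_link_graph(mols2, ss, anch)$edges), 1L)
})

test_that("molecules support scaffolds only near ends and with enough pairs", {
  ss <- scaffold_set(c(a = 400000L, b = 400000L))
  mid_a <- mol_row("a", 180000, 220000, "bc1")      # interior: no support
  link1 <- rbind(mol_row("a", 350000, 399000, "bc2"),
                 mol_row("b", 0, 50000, "bc2"))
  link2 <- rbind(mol_row("a", 340000, 399000, "bc4", "L2"),
                 mol_row("b", 0, 40000, "bc4", "L2"))
  thin <- rbind(mol_row("a", 350000, 399000, "bc3", "L2", n_pairs = 1L),
                mol_row("b", 0, 50000, "bc3", "L2", n_pairs = 1L))
  g <- build_link_graph(rbind(mid_a, link1, link2, thin), ss,
                        min_molecules = 1L)
  expect_equal(g$edges$n_molecules, 2L)  # bc3 fails min_pairs = 2
  expect_equal(g$edges$n_lib, 2L)
  ## barcodes touching three scaffolds are ambiguous and discarded
  ss3 <- scaffold_set(c(a = 200000L, b = 200000L, c = 200000L))
  tri <- rbindlist(lapply(c("a", "b", "c"), function(s)
    mol_row(s, 0, 50000, "bcx")))
  g3 <- build_link_graph(tri, ss3, min_molecules = 1L)
  expect_equal(nrow(g3$edges), 0L)
})

test_that("edge weights equal brute-force barcode intersection counts", {
  cfg <- sim_config(seed = 71, n_chromosomes = 1, chromosome_length = 2e6,
                    n_scaffolds = 10, n_chimeras = 0, with_sequence = FALSE)
  sim <- simulate_all(cfg)
  mols <- call_molecules(sim$pairs)
  g <- build_link_graph(mols, sim$scaffolds, min_molecules = 1L)
  ## oracle: recompute supporting barcodes per scaffold by set operations
  lens <- scaffold_lengths(sim$scaffolds)
  sup <- mols[n_pairs >= 2L]
  sup <- sup[start < 1e5 | end > lens[scaffold] - 1e5]
  per_bc <- lapply(split(sup$scaffold, sup$barcode), unique)
  two <- per_bc[vapply(per_bc, length, integer(1)) == 2L]
  bc_pairs <- rbindlist(lapply(names(two), function(bc)
    data.table(barcode = bc,
               pair = paste(sort(two[[bc]]), collapse = "|"),
               library = sup[barcode == bc, library[1L]])))
  want <- bc_pairs[, .(n = .N, nl = uniqueN(library)), by = pair][nl >= 2L]
  got <- g$edges[, .(pair = paste(node1, node2, sep = "|"),
                     n = n_molecules)]
  setkey(want, pair); setkey(got, pair)
  expect_equal(got$pair, want$pair)
  expect_equal(got$n, want$n)
})

test_that("path components survive reduction unchanged", {
  edges <- data.table(node1 = c("a", "b", "c"), node2 = c("b", "c", "d"),
                      n_molecules = c(5L, 6L, 7L), n_lib = 2L,
                      weight = c(5L, 6L, 7L))
  g <- as_link_graph(edges, c(a = 5e4, b = 5e4, c = 5e4, d = 5e4))
  mem <- reduce_to_paths(g)
  expect_equal(uniqueN(mem$super_scaffold), 1L)
  expect_equal(mem[order(ord), member], c("a", "b", "c", "d"))
})

test_that("branch resolution keeps the heaviest edges of a star", {
  edges <- data.table(node1 = "hub", node2 = c("a", "b", "c"),
                      n_molecules = c(9L, 7L, 3L), n_lib = 2L,
                      weight = c(9L, 7L, 3L))
  g <- as_link_graph(edges, c(hub = 5e4, a = 5e4, b = 5e4, c = 5e4))
  mem <- reduce_to_paths(g)
  path <- mem[, .N, by = super_scaffold][N == 3L, super_scaffold]
  expect_equal(sort(mem[super_scaffold == path, member]),
               c("a", "b", "hub"))
  ## c becomes a singleton: partition property holds
  expect_equal(sort(unique(mem$member)), c("a", "b", "c", "hub"))
  expect_equal(nrow(mem), 4L)
  ## short tips are removed before edges are cut
  g2 <- as_link_graph(edges, c(hub = 5e4, a = 5e4, b = 5e4, c = 5000L))
  mem2 <- reduce_to_paths(g2, min_scaffold_len = 10000L)
  p2 <- mem2[, .N, by = super_scaffold][N == 3L, super_scaffold]
  expect_equal(sort(mem2[super_scaffold == p2, member]), c("a", "b", "hub"))
})

test_that("spanning-tree weight matches exhaustive enumeration", {
  for (s in 1:10) {
    gr <- random_connected_graph(sample(4:8, 1), seed = 600 + s)
    tree <- molscaf:::mst_edges(gr$edges, gr$vertices)
    w <- gr$edges[tree, on = c("node1", "node2"), sum(weight)]
    expect_equal(w, brute_force_mst_weight(gr$edges, gr$vertices))
  }
})

test_that("reduced graphs have degree at most two and no cycles", {
  set.seed(81)
  for (s in 1:5) {
    gr <- random_connected_graph(8, seed = 700 + s)
    lens <- setNames(sample(c(5000L, 50000L), 8, TRUE), gr$vertices)
    g <- as_link_graph(gr$edges[, .(node1, node2, n_molecules = weight,
                                    n_lib = 2L, weight)], lens)
    mem <- reduce_to_paths(g)
    ## partition: every vertex exactly once
    expect_equal(sort(mem$member), sort(gr$vertices))
    ## each path has consecutive ord values
    mem[, expect_equal(sort(ord), seq_len(.N)), by = super_scaffold]
  }
})

test_that("member orientation follows the stated link-position rule", {
  ss <- scaffold_set(c(a = 200000L, b = 200000L, c = 200000L))
  ## path a - b - c; b's links to a sit at its low coordinates and links
  ## to c at its high coordinates: b is forward
  mols <- rbindlist(list(
    mol_row("a", 150000, 199000, "bc1"), mol_row("b", 0, 40000, "bc1"),
    mol_row("a", 160000, 199000, "bc2", "L2"), mol_row("b", 0, 30000, "bc2", "L2"),
    mol_row("b", 170000, 199000, "bc3"), mol_row("c", 0, 40000, "bc3"),
    mol_row("b", 160000, 199000, "bc4", "L2"), mol_row("c", 0, 30000, "bc4", "L2")))
  g <- build_link_graph(mols, ss)
  mem <- reduce_to_paths(g)
  omem <- orient_members(mem, g)
  expect_equal(omem[member == "b", orientation], "+")
  ## mirror image: flip b's molecule positions
  mols2 <- copy(mols)
  mols2[scaffold == "b", `:=`(start = 200000L - end, end = 200000L - start)]
  g2 <- build_link_graph(mols2, ss)
  omem2 <- orient_members(reduce_to_paths(g2), g2)
  expect_equal(omem2[member == "b", orientation], "-")
})

test_that("a 1x1 sweep grid equals the direct pipeline run", {
  cfg <- sim_config(seed = 73, n_chromosomes = 1, chromosome_length = 2e6,
                    n_scaffolds = 15, n_chimeras = 0, with_sequence = FALSE)
  sim <- simulate_all(cfg)
  mols <- call_molecules(sim$pairs)
  sw <- sweep_and_select(mols, sim$scaffolds, min_pairs_grid = 3L,
                         min_molecules_grid = 4L)
  g <- build_link_graph(mols, sim$scaffolds, min_pairs = 3L,
                        min_molecules = 4L)
  direct <- orient_members(reduce_to_paths(g), g)
  expect_equal(as.data.frame(sw$membership), as.data.frame(direct))
  expect_equal(nrow(sw$report), 1L)
  ## full grid bookkeeping: one row per point, best is the max N50 with
  ## stringency tie-break
  sw2 <- sweep_and_select(mols, sim$scaffolds, min_pairs_grid = 2:4,
                          min_molecules_grid = 2:4)
  expect_equal(nrow(sw2$report), 9L)
  expect_equal(unname(sw2$best["n50"]), max(sw2$report$n50))
  top <- sw2$report[n50 == max(n50)][order(-min_pairs, -min_molecules)][1]
  expect_equal(unname(sw2$best["min_pairs"]), top$min_pairs)
  expect_equal(unname(sw2$best["min_molecules"]), top$min_molecules)
})

test_that("raising the molecule threshold never adds edges", {
  cfg <- sim_config(seed = 74, n_chromosomes = 1, chromosome_length = 2e6,
                    n_scaffolds = 15, n_chimeras = 0, with_sequence = FALSE)
  sim <- simulate_all(cfg)
  mols <- call_molecules(sim$pairs)
  n_edges <- vapply(2:8, function(mm)
    nrow(build_link_graph(mols, sim$scaffolds, min_molecules = mm)$edges),
    integer(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("the super-scaffold membership map lays members head to tail", {
  mem <- data.table(super_scaffold = "ss1", member = c("x", "y", "z"),
                    ord = 1:3, orientation = c("+", "-", "+"))
  ss <- scaffold_set(c(x = 1000L, y = 2000L, z = 500L))
  map <- superscaffold_map(mem, ss, gap = 100L)
  expect_equal(map$offset, c(0L, 1100L, 3200L))
  expect_equal(unique(map$unit_length), 1000L + 2000L + 500L + 200L)
  expect_equal(superscaffold_n50(mem, ss, gap = 100L), 3700L)
})
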