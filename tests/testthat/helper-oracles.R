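## Independent brute-force oracles and small fixture builders shared by
## the test files. These deliberately avoid the package's own algorithms.

library(data.table)

## write a FASTA file from a named character vector, return the path
write_tmp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

random_pair_table <- function(n, n_scaffolds = 3, scaffold_len = 5e6,
                              n_barcodes = 40, seed = 1) {
  set.seed(seed)
  start <- as.integer(runif(n, 0, scaffold_len - 400))
  dt <- data.table(
    scaffold = sprintf("s%02d", sample.int(n_scaffolds, n, replace = TRUE)),
    start = start, end = start + 300L,
    barcode = sprintf("BC%03d", sample.int(n_barcodes, n, replace = TRUE)),
    library = sample(c("L1", "L2"), n, replace = TRUE), mapq = 60L)
  setorder(dt, barcode, scaffold, start)
  dt
}

## O(n^2) single-linkage molecule clustering with the gap rule: two pairs
## of the same barcode and scaffold belong to one molecule if connected by
## a chain of start-to-start distances <= gap_max
brute_force_molecules <- function(pairs, gap_max = 500000,
                                  molecule_min_len = 1000, min_pairs = 2) {
  out <- list()
  for (key in split(pairs, by = c("barcode", "scaffold"))) {
    n <- nrow(key)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j && abs(key$start[i] - key$start[j]) <= gap_max) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
    cl <- vapply(seq_len(n), find, integer(1))
    for (g in unique(cl)) {
      m <- key[cl == g]
      out[[length(out) + 1L]] <- data.table(
        scaffold = m$scaffold[1], start = min(m$start), end = max(m$end),
        barcode = m$barcode[1], library = m$library[1], n_pairs = nrow(m))
    }
  }
  mols <- rbindlist(out)
  mols <- mols[(end - start) >= molecule_min_len & n_pairs >= min_pairs]
  setorder(mols, scaffold, start, end, barcode)
  mols
}

## exhaustive maximum-weight spanning tree over all edge subsets
brute_force_mst_weight <- function(edges, vertices) {
  n <- length(vertices)
  m <- nrow(edges)
  if (m < n - 1) return(NA_real_)
  best <- -Inf
  for (sel in utils::combn(m, n - 1, simplify = FALSE)) {
    sub <- edges[sel]
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    acyclic <- TRUE
    for (k in seq_len(nrow(sub))) {
      a <- find(match(sub$node1[k], vertices))
      b <- find(match(sub$node2[k], vertices))
      if (a == b) { acyclic <- FALSE; break }
      parent[a] <- b
    }
    if (acyclic && sum(sub$weight) > best) best <- sum(sub$weight)
  }
  best
}

## sparse enough that exhaustive spanning-tree enumeration stays feasible:
## choose(max_edges, n - 1) subsets at most
random_connected_graph <- function(n, seed, max_edges = n + 4L) {
  set.seed(seed)
  vertices <- sprintf("v%02d", seq_len(n))
  all_pairs <- t(utils::combn(vertices, 2))
  repeat {
    keep <- runif(nrow(all_pairs)) < 0.5
    if (sum(keep) < n - 1 || sum(keep) > max_edges) next
    edges <- data.table(node1 = all_pairs[keep, 1], node2 = all_pairs[keep, 2],
                        weight = sample.int(20L, sum(keep), replace = TRUE))
    g <- igraph::graph_from_data_frame(
      edges[, .(node1, node2)], directed = FALSE, vertices = vertices)
    if (igraph::is_connected(g)) return(list(edges = edges, vertices = vertices))
  }
}

## wrap an edge table as a link_graph for reduce_to_paths
as_link_graph <- function(edges, lengths) {
  nodes <- data.table(scaffold = names(lengths), length = as.integer(lengths),
                      chromosome = NA_character_, cM = NA_real_)
  structure(list(edges = as.data.table(edges), support = data.table(),
                 nodes = nodes,
                 params = list(end_window = 1e5, min_pairs = 2,
                               min_molecules = 2, max_cm_dist = 5)),
            class = "link_graph")
}

## directionality-track inversion signature: strong negative dip near the
## left edge and strong positive peak near the right edge of a block
inversion_signature <- function(bias, b1, b2, thr = 0.75, nb = 2L) {
  n <- length(bias)
  left <- bias[max(1, b1 - nb):min(n, b1 + nb)]
  right <- bias[max(1, b2 - nb):min(n, b2 + nb)]
  min(left) < -thr && max(right) > thr
}
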