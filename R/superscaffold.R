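#' Build the scaffold link graph from 10X molecules
#'
#' Nodes are scaffolds; an edge between two scaffolds is supported by
#' barcodes whose molecules touch both scaffold ends. A molecule supports a
#' scaffold if it has at least `min_pairs` read pairs on it and lies within
#' `end_window` of one of the scaffold's ends; a barcode supporting exactly
#' two scaffolds contributes one linking molecule to that pair (barcodes
#' touching three or more scaffolds are ambiguous and discarded). An edge
#' is kept only if it is supported by at least `min_molecules` linking
#' molecules drawn from at least two distinct libraries, and — when both
#' scaffolds are anchored — only if they sit on the same chromosome within
#' `max_cm_dist` cM of each other.
#'
#' @param molecules molecule table from [call_molecules()].
#' @param scaffolds a [scaffold_set].
#' @param anchors optional anchor table from [anchor_scaffolds()].
#' @param end_window distance from a scaffold end within which molecules
#'   count as end-supporting (default 100 kb).
#' @param min_pairs minimum read pairs for a molecule to support a scaffold.
#' @param min_molecules minimum linking molecules per edge.
#' @param max_cm_dist maximum genetic distance between anchored endpoints
#'   (default 5 cM).
#' @return A `link_graph` object: list with `edges` (`node1`, `node2`,
#'   `n_molecules`, `n_lib`, `weight`), `support` (per-barcode end support
#'   with molecule midpoints, used for orientation), `nodes`, and the
#'   parameters used.
#' @export
build_link_graph <- function(molecules, scaffolds, anchors = NULL,
                             end_window = 100000L, min_pairs = 2L,
                             min_molecules = 2L, max_cm_dist = 5) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  mols <- as.data.table(molecules)
  nodes <- scaffolds$info[, .(scaffold, length)]
  if (!is.null(anchors)) {
    nodes <- merge(nodes, as.data.table(anchors)[, .(scaffold, chromosome, cM)],
                   by = "scaffold", all.x = TRUE)
  } else {
    nodes[, `:=`(chromosome = NA_character_, cM = NA_real_)]
  }
  support <- support_table(mols, nodes, end_window, min_pairs)
  edges <- link_edges(support, nodes, min_molecules, max_cm_dist)
  structure(list(edges = edges, support = support, nodes = nodes,
                 params = list(end_window = end_window, min_pairs = min_pairs,
                               min_molecules = min_molecules,
                               max_cm_dist = max_cm_dist)),
            class = "link_graph")
}

## molecules that support a scaffold end, with their midpoints
support_table <- function(mols, nodes, end_window, min_pairs) {
  sup <- mols[n_pairs >= min_pairs]
  sup <- sup[nodes[, .(scaffold, len = length)], on = "scaffold", nomatch = NULL]
  sup <- sup[start < end_window | end > len - end_window]
  sup[, mid := (start + end) / 2]
  sup[, .(scaffold, start, end, mid, len, barcode, library)]
}

## aggregate barcode links into filtered edges
link_edges <- function(support, nodes, min_molecules, max_cm_dist) {
  empty <- data.table(node1 = character(), node2 = character(),
                      n_molecules = integer(), n_lib = integer(),
                      weight = integer())
  if (nrow(support) == 0L) return(empty)
  bc <- support[, .(n_scaf = uniqueN(scaffold)), by = .(barcode)]
  bc2 <- bc[n_scaf == 2L, barcode]
  if (length(bc2) == 0L) return(empty)
  sup2 <- support[barcode %in% bc2]
  prs <- sup2[, .(node1 = min(scaffold), node2 = max(scaffold),
                  library = library[1L]), by = .(barcode)]
  edges <- prs[, .(n_molecules = .N, n_lib = uniqueN(library)),
               by = .(node1, node2)]
  edges <- edges[n_molecules >= min_molecules & n_lib >= 2L]
  anc <- nodes[, .(scaffold, chromosome, cM)]
  edges[anc, `:=`(chr1 = i.chromosome, cm1 = i.cM), on = c(node1 = "scaffold")]
  edges[anc, `:=`(chr2 = i.chromosome, cm2 = i.cM), on = c(node2 = "scaffold")]
  both <- !is.na(edges$chr1) & !is.na(edges$chr2)
  ok <- !both | (edges$chr1 == edges$chr2 &
                 fifelse(is.na(edges$cm1) | is.na(edges$cm2), TRUE,
                         abs(edges$cm1 - edges$cm2) <= max_cm_dist))
  edges <- edges[ok]
  edges[, c("chr1", "cm1", "chr2", "cm2") := NULL]
  edges[, weight := n_molecules]
  setorder(edges, node1, node2)
  edges[]
}

#' @export
print.link_graph <- function(x, ...) {
  cat(sprintf("link_graph: %d nodes, %d edges (min_pairs=%d, min_molecules=%d)\n",
              nrow(x$nodes), nrow(x$edges), x$params$min_pairs,
              x$params$min_molecules))
  invisible(x)
}

#' Reduce a link graph to simple paths
#'
#' Computes, per connected component, a maximum-weight spanning tree
#' (molecule counts as weights; deterministic under fixed edge order), then
#' resolves branch nodes iteratively: at any node of degree three or more,
#' incident tip members (degree-one nodes) shorter than `min_scaffold_len`
#' are dropped first, then the lowest-weight incident edges are cut until
#' the degree is at most two. The remaining components are simple paths —
#' the initial super-scaffolds. Every scaffold of the assembly appears in
#' exactly one super-scaffold; scaffolds without retained edges (including
#' dropped tips) become singletons.
#'
#' @param graph a `link_graph` from [build_link_graph()].
#' @param min_scaffold_len tips shorter than this are dropped at branch
#'   points (default 10 kb).
#' @return A membership `data.table` with columns `super_scaffold`,
#'   `member`, `ord` (1-based position along the path).
#' @export
reduce_to_paths <- function(graph, min_scaffold_len = 10000L) {
  stopifnot(inherits(graph, "link_graph"))
  edges <- copy(graph$edges)
  nodes <- graph$nodes
  len <- setNames(nodes$length, nodes$scaffold)
  if (nrow(edges) > 0L) {
    tedges <- mst_edges(edges, nodes$scaffold)
    ## iterative branch resolution
    repeat {
      deg <- edge_degrees(tedges)
      branch <- sort(names(deg)[deg >= 3L])
      if (length(branch) == 0L) break
      changed <- FALSE
      for (b in branch) {
        inc <- tedges[node1 == b | node2 == b]
        if (nrow(inc) < 3L) next
        other <- fifelse(inc$node1 == b, inc$node2, inc$node1)
        ## (i) drop short tips first
        tip <- deg[other] == 1L & len[other] < min_scaffold_len
        if (any(tip)) {
          drop_nodes <- other[tip]
          tedges <- tedges[!(node1 %in% drop_nodes | node2 %in% drop_nodes)]
          changed <- TRUE
          next
        }
        ## (ii) cut lowest-weight incident edges down to degree 2
        o <- order(inc$weight, pmin(inc$node1, inc$node2),
                   pmax(inc$node1, inc$node2))
        cut <- inc[o][seq_len(nrow(inc) - 2L)]
        tedges <- tedges[!cut, on = c("node1", "node2")]
        changed <- TRUE
      }
      if (!changed) break
    }
    deg <- edge_degrees(tedges)
    if (length(deg) > 0L && max(deg) > 2L)
      stop("branch resolution failed to produce paths")
    paths <- trace_paths(tedges)
  } else {
    paths <- list()
  }
  placed <- unlist(paths, use.names = FALSE)
  singletons <- setdiff(nodes$scaffold, placed)
  all_units <- c(paths, as.list(singletons))
  ## deterministic unit order: by lexicographically smallest member
  first <- vapply(all_units, function(m) min(m), character(1))
  all_units <- all_units[order(first)]
  rbindlist(lapply(seq_along(all_units), function(i) {
    data.table(super_scaffold = sprintf("ss_%05d", i),
               member = all_units[[i]],
               ord = seq_along(all_units[[i]]))
  }))
}

## maximum-weight spanning forest: igraph MST on negated weights, edge
## order pre-sorted by (-weight, endpoints) for deterministic tie-breaks
mst_edges <- function(edges, vertices) {
  edges <- copy(as.data.table(edges))
  setorder(edges, -weight, node1, node2)
  g <- igraph::graph_from_data_frame(
    edges[, .(from = node1, to = node2, weight)], directed = FALSE,
    vertices = vertices)
  tree <- igraph::mst(g, weights = -igraph::E(g)$weight)
  tedges <- as.data.table(igraph::as_data_frame(tree, what = "edges"))
  setnames(tedges, c("from", "to"), c("node1", "node2"))
  tedges
}

edge_degrees <- function(edges) {
  if (nrow(edges) == 0L) return(integer(0))
  table(c(edges$node1, edges$node2))
}

## orient each path component from its lexicographically smaller endpoint
trace_paths <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    edges[, .(from = node1, to = node2)], directed = FALSE)
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(ci) {
    vs <- names(comp$membership)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vs)
    degs <- igraph::degree(sub)
    ends <- sort(names(degs)[degs == 1L])
    if (length(ends) == 0L) stop("cycle remaining after path reduction")
    path <- igraph::dfs(sub, root = ends[1L])$order
    names(path)
  })
}

#' Orient members within super-scaffolds
#'
#' For each member S of a path, molecules linking S to up to
#' `neighbor_span` members on its left (upstream) and right (downstream)
#' are collected, and the mean within-S positions of the two groups are
#' compared: if downstream links sit at higher coordinates than upstream
#' links, S is oriented forward (`+`), otherwise reverse (`-`). When only
#' one side is informative the mean is compared against the member
#' midpoint. Members with no informative links default to forward and are
#' flagged.
#'
#' @param membership membership table from [reduce_to_paths()].
#' @param graph the `link_graph` whose `support` table produced the paths.
#' @param neighbor_span number of neighboring members considered on each
#'   side (default 5).
#' @return The membership table with added columns `orientation` (`+`/`-`),
#'   `informative` (logical) and `n_links` (number of linking-molecule
#'   observations that informed the call).
#' @export
orient_members <- function(membership, graph, neighbor_span = 5L) {
  mem <- copy(as.data.table(membership))
  sup <- graph$support
  ## barcode-pair links with positions on each side
  sup2 <- sup[, if (uniqueN(scaffold) == 2L) .SD, by = .(barcode)]
  mem[, orientation := "+"]
  mem[, informative := FALSE]
  mem[, n_links := 0L]
  if (nrow(sup2) > 0L) {
    pl <- merge(sup2, sup2, by = "barcode", allow.cartesian = TRUE,
                suffixes = c("", ".o"))
    pl <- pl[scaffold != scaffold.o]
    pl <- pl[mem, on = c(scaffold = "member"), nomatch = NULL]
    setnames(pl, c("super_scaffold", "ord"), c("ss", "ord_s"))
    pl <- pl[mem[, .(member, super_scaffold, ord)],
             on = c("scaffold.o" = "member"), nomatch = NULL]
    pl <- pl[ss == super_scaffold & abs(ord - ord_s) <= neighbor_span]
    ori <- pl[, {
      up <- mid[ord < ord_s]
      down <- mid[ord > ord_s]
      half <- len[1L] / 2
      nl <- length(up) + length(down)
      if (length(up) > 0L && length(down) > 0L)
        .(orientation = if (mean(down) > mean(up)) "+" else "-",
          informative = TRUE, n_links = nl)
      else if (length(down) > 0L)
        .(orientation = if (mean(down) > half) "+" else "-",
          informative = TRUE, n_links = nl)
      else if (length(up) > 0L)
        .(orientation = if (mean(up) < half) "+" else "-",
          informative = TRUE, n_links = nl)
      else
        .(orientation = "+", informative = FALSE, n_links = 0L)
    }, by = .(ss, scaffold)]
    mem[ori, `:=`(orientation = i.orientation, informative = i.informative,
                  n_links = i.n_links),
        on = c(super_scaffold = "ss", member = "scaffold")]
  }
  mem[]
}

#' Super-scaffold N50 for a membership table
#'
#' @param membership membership table (`super_scaffold`, `member`).
#' @param scaffolds a [scaffold_set] supplying member lengths.
#' @param gap fixed inter-member gap in bp (default 100).
#' @return The N50 of the super-scaffold lengths.
#' @export
superscaffold_n50 <- function(membership, scaffolds, gap = 100L) {
  mem <- as.data.table(membership)
  mem[scaffolds$info, len := i.length, on = c(member = "scaffold")]
  ulen <- mem[, .(len = sum(len) + gap * (.N - 1L)), by = .(super_scaffold)]
  assembly_stats(ulen$len)$n50
}

#' Sweep molecule and edge thresholds and pick the best assembly
#'
#' Runs graph construction and path reduction over a grid of minimum read
#' pairs per supporting molecule and minimum linking molecules per edge,
#' scores each grid point by super-scaffold N50 (fixed inter-member gap),
#' and returns the highest-N50 assembly; N50 ties are resolved towards the
#' more stringent thresholds. Orientation is computed for the selected
#' assembly.
#'
#' @param molecules molecule table.
#' @param scaffolds a [scaffold_set].
#' @param anchors optional anchor table.
#' @param min_pairs_grid,min_molecules_grid integer grids (defaults 2..10).
#' @param end_window,max_cm_dist,min_scaffold_len,neighbor_span see
#'   [build_link_graph()], [reduce_to_paths()], [orient_members()].
#' @param gap inter-member gap used in the N50 score (default 100 bp).
#' @return A list with `membership` (oriented, for the best grid point),
#'   `graph`, `best` (named vector `min_pairs`, `min_molecules`, `n50`),
#'   and `report` (one row per grid point: thresholds, `n50`, `n_edges`,
#'   `n_paths`).
#' @export
sweep_and_select <- function(molecules, scaffolds, anchors = NULL,
                             min_pairs_grid = 2:10,
                             min_molecules_grid = 2:10,
                             end_window = 100000L, max_cm_dist = 5,
                             min_scaffold_len = 10000L, neighbor_span = 5L,
                             gap = 100L) {
  if (length(min_pairs_grid) == 0L || length(min_molecules_grid) == 0L)
    stop("empty sweep grid")
  report <- list()
  best <- NULL
  for (mp in sort(min_pairs_grid)) {
    g_mp <- build_link_graph(molecules, scaffolds, anchors,
                             end_window = end_window, min_pairs = mp,
                             min_molecules = min(min_molecules_grid),
                             max_cm_dist = max_cm_dist)
    for (mm in sort(min_molecules_grid)) {
      g <- g_mp
      g$edges <- g_mp$edges[n_molecules >= mm]
      g$params$min_molecules <- mm
      mem <- reduce_to_paths(g, min_scaffold_len = min_scaffold_len)
      n50 <- superscaffold_n50(mem, scaffolds, gap = gap)
      report[[length(report) + 1L]] <-
        data.table(min_pairs = mp, min_molecules = mm, n50 = n50,
                   n_edges = nrow(g$edges),
                   n_paths = uniqueN(mem$super_scaffold))
      ## ties favour stringency: larger (min_pairs, min_molecules) wins
      if (is.null(best) || n50 > best$n50 ||
          (n50 == best$n50 && (mp > best$min_pairs ||
            (mp == best$min_pairs && mm > best$min_molecules)))) {
        best <- list(min_pairs = mp, min_molecules = mm, n50 = n50,
                     graph = g, membership = mem)
      }
    }
  }
  membership <- orient_members(best$membership, best$graph,
                               neighbor_span = neighbor_span)
  list(membership = membership, graph = best$graph,
       best = c(min_pairs = best$min_pairs,
                min_molecules = best$min_molecules, n50 = best$n50),
       report = rbindlist(report))
}

#' Membership map of a super-scaffold set
#'
#' Converts an oriented membership table into a coordinate membership map
#' (see [lifting]) with fixed inter-member gaps, for lifting markers,
#' molecules and links onto super-scaffold coordinates.
#'
#' @param membership oriented membership table from [orient_members()].
#' @param scaffolds a [scaffold_set].
#' @param gap inter-member gap in bp (default 100).
#' @return A membership map `data.table` (`member`, `unit`, `offset`,
#'   `orientation`, `member_length`, `unit_length`).
#' @export
superscaffold_map <- function(membership, scaffolds, gap = 100L) {
  mem <- copy(as.data.table(membership))
  if (!"orientation" %in% names(mem)) mem[, orientation := "+"]
  mem[scaffolds$info, member_length := i.length, on = c(member = "scaffold")]
  setorder(mem, super_scaffold, ord)
  mem[, offset := cumsum(shift(member_length + gap, fill = 0L)),
      by = .(super_scaffold)]
  mem[, unit_length := sum(member_length) + gap * (.N - 1L),
      by = .(super_scaffold)]
  mem[, .(member, unit = super_scaffold, offset = as.integer(offset),
          orientation, member_length, unit_length)]
}
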