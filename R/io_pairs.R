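#' Read and filter a linked-read pair table
#'
#' Reads a BEDPE-like tab-separated table of aligned read pairs with header
#' columns `scaffold`, `start`, `end`, `barcode`, `library`, `mapq`
#' (coordinates 0-based, half-open; `start`/`end` span the outermost mapped
#' bases of the pair on one scaffold). Filtering follows the linked-read
#' alignment contract: pairs below the mapping-quality cutoff are dropped,
#' pairs whose span exceeds `insert_max` are dropped (long apparent inserts
#' are almost always mapping artefacts for short-insert Chromium libraries),
#' and duplicate records — identical `(scaffold, start, end, barcode)` — are
#' collapsed to one.
#'
#' @param path path to the pair table.
#' @param mapq_min minimum mapping quality to retain a pair (default 20).
#' @param insert_max maximum pair span in bp (default 800).
#' @return A `data.table` with the six input columns, sorted by
#'   `(barcode, scaffold, start)`. The number of rows rejected because
#'   `end <= start` is attached as attribute `n_rejected`.
#' @seealso [filter_pairs()] for applying the same rules to an in-memory
#'   table; [call_molecules()] for the downstream molecule reconstruction.
#' @export
read_pairs <- function(path, mapq_min = 20L, insert_max = 800L) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = c("scaffold", "barcode", "library")))
  req <- c("scaffold", "start", "end", "barcode", "library", "mapq")
  if (nrow(dt) == 0L && ncol(dt) == 0L)
    return(empty_pair_table())
  if (!all(req %in% names(dt)))
    stop("pair table must have columns: ", paste(req, collapse = ", "))
  dt <- dt[, req, with = FALSE]
  for (cc in c("start", "end", "mapq")) {
    v <- dt[[cc]]
    if (!is.numeric(v)) {
      vi <- suppressWarnings(as.integer(v))
      if (anyNA(vi))
        stop(sprintf("malformed %s field at line %d of %s", cc,
                     which(is.na(vi))[1L] + 1L, path))
      set(dt, j = cc, value = vi)
    } else set(dt, j = cc, value = as.integer(v))
  }
  filter_pairs(dt, mapq_min = mapq_min, insert_max = insert_max)
}

#' @rdname read_pairs
#' @param pairs an in-memory pair table (columns as above).
#' @export
filter_pairs <- function(pairs, mapq_min = 20L, insert_max = 800L) {
  pairs <- as.data.table(pairs)
  if (nrow(pairs) == 0L) return(empty_pair_table())
  bad <- pairs$end <= pairs$start
  n_rejected <- sum(bad)
  if (n_rejected > 0L)
    message(n_rejected, " pair record(s) with end <= start rejected")
  out <- pairs[!bad & mapq >= mapq_min & (end - start) <= insert_max]
  out <- unique(out, by = c("scaffold", "start", "end", "barcode"))
  setorder(out, barcode, scaffold, start, end)
  setattr(out, "n_rejected", n_rejected)
  out[]
}

empty_pair_table <- function() {
  data.table(scaffold = character(), start = integer(), end = integer(),
             barcode = character(), library = character(), mapq = integer())
}

#' Read a Hi-C pair table
#'
#' Reads a two-sided tab-separated link table with header columns
#' `scaffold1`, `pos1`, `scaffold2`, `pos2`, `mapq` (positions 0-based).
#' Each row is one read pair; the two sides may lie on different scaffolds.
#' No insert-size filter is applied: Hi-C pairs legitimately span arbitrary
#' distances.
#'
#' @param path path to the table.
#' @param mapq_min minimum mapping quality (default 20).
#' @return A `data.table` with columns `scaffold1`, `pos1`, `scaffold2`,
#'   `pos2`, stored so that `(scaffold1, pos1) <= (scaffold2, pos2)`.
#' @export
read_hic_pairs <- function(path, mapq_min = 20L) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = c("scaffold1", "scaffold2")))
  if (nrow(dt) == 0L)
    return(data.table(scaffold1 = character(), pos1 = integer(),
                      scaffold2 = character(), pos2 = integer()))
  if ("mapq" %in% names(dt)) dt <- dt[mapq >= mapq_min]
  canonical_link_sides(dt[, .(scaffold1, pos1 = as.integer(pos1),
                              scaffold2, pos2 = as.integer(pos2))])
}

## enforce (scaffold1,pos1) <= (scaffold2,pos2) lexicographically
canonical_link_sides <- function(dt) {
  flip <- dt$scaffold2 < dt$scaffold1 |
    (dt$scaffold2 == dt$scaffold1 & dt$pos2 < dt$pos1)
  if (any(flip)) {
    s1 <- dt$scaffold1[flip]; p1 <- dt$pos1[flip]
    dt[flip, `:=`(scaffold1 = scaffold2, pos1 = pos2)]
    dt[flip, `:=`(scaffold2 = s1, pos2 = p1)]
  }
  dt[]
}

#' Write evidence tables as TSV
#'
#' Thin wrappers over [data.table::fwrite()] used by the command-line
#' interface; provided so round-trips preserve column order and types.
#'
#' @param x a data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}
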