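#' Read genetic-marker alignments from PAF
#'
#' Parses a PAF file of marker-sequence alignments against the assembly and
#' keeps the single best alignment per marker: highest alignment block
#' length, ties broken by higher identity, then by lexicographically smallest
#' target scaffold (for determinism).
#'
#' @param path path to a PAF file (columns 1-12; extra tags ignored).
#' @return A `data.table` with columns `marker`, `scaffold`, `position`
#'   (target start, 0-based), `aln_len`, `identity`, one row per marker.
#' @export
read_marker_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              select = 1:12,
              col.names = c("qname", "qlen", "qstart", "qend", "strand",
                            "tname", "tlen", "tstart", "tend", "nmatch",
                            "aln_len", "mapq"))
  if (nrow(dt) == 0L)
    return(data.table(marker = character(), scaffold = character(),
                      position = integer(), aln_len = integer(),
                      identity = numeric()))
  num_cols <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
                "nmatch", "aln_len", "mapq")
  for (cc in num_cols) {
    v <- suppressWarnings(as.integer(dt[[cc]]))
    if (anyNA(v))
      stop(sprintf("non-numeric %s field at line %d of %s", cc,
                   which(is.na(v))[1L], path))
    set(dt, j = cc, value = v)
  }
  aln <- dt[, .(marker = qname, scaffold = tname,
                position = tstart, aln_len,
                identity = ifelse(aln_len > 0, nmatch / aln_len, 0))]
  best_marker_alignment(aln)
}

## best hit per marker: max aln_len, then max identity, then smallest scaffold
best_marker_alignment <- function(aln) {
  setorder(aln, marker, -aln_len, -identity, scaffold, position)
  unique(aln, by = "marker")[]
}

#' Read a genetic map table
#'
#' @param path tab-separated table with header columns `marker`,
#'   `chromosome`, `cM`. Each marker must map to exactly one position.
#' @return A keyed `data.table` with one row per marker.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gm <- fread(path, header = TRUE, sep = "\t",
              colClasses = list(character = c("marker", "chromosome")))
  if (!all(c("marker", "chromosome", "cM") %in% names(gm)))
    stop("genetic map must have columns marker, chromosome, cM")
  gm <- gm[, .(marker, chromosome, cM = as.numeric(cM))]
  if (anyDuplicated(gm$marker))
    stop("genetic map assigns some markers more than once")
  setkey(gm, marker)
  gm[]
}
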