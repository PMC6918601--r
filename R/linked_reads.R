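#' Preprocess raw linked-read FASTQ pairs
#'
#' Applies the Chromium read-structure contract before alignment: the 10X
#' barcode is the first 16 nt of read 1; the first 23 nt of read 1 (barcode
#' plus spacer) are removed; the instrument field of the read identifier is
#' replaced by the barcode so that it travels through alignment; both reads
#' are 3'-trimmed at the first exact occurrence of the sequencing adapter;
#' pairs in which either read ends up shorter than `min_len` are dropped.
#' Pairs whose read 1 is too short to contain the barcode structure are
#' dropped and counted.
#'
#' @param fastq1,fastq2 paths to read-1 and read-2 FASTQ files.
#' @param out1,out2 output FASTQ paths.
#' @param barcode_len barcode length at the start of read 1 (default 16).
#' @param clip1 number of leading bases removed from read 1 (default 23).
#' @param adapter adapter sequence removed from read 3' ends.
#' @param min_len minimum read length after trimming (default 30).
#' @return Invisibly, a list with counts: `n_in`, `n_out`, `n_short_r1`
#'   (read 1 too short for the barcode structure), `n_trimmed_short`
#'   (dropped after adapter trimming).
#' @export
preprocess_linked_reads <- function(fastq1, fastq2, out1, out2,
                                    barcode_len = 16L, clip1 = 23L,
                                    adapter = "AGATCGGAAGAGC",
                                    min_len = 30L) {
  r1 <- read_fastq(fastq1)
  r2 <- read_fastq(fastq2)
  if (nrow(r1) != nrow(r2)) stop("read 1 and read 2 files differ in length")
  n_in <- nrow(r1)
  ok <- nchar(r1$seq) > clip1
  n_short_r1 <- sum(!ok)
  r1 <- r1[ok]; r2 <- r2[ok]
  barcode <- substr(r1$seq, 1L, barcode_len)
  r1[, `:=`(seq = substring(seq, clip1 + 1L), qual = substring(qual, clip1 + 1L))]
  ## replace the instrument field (first ':'-separated token) by the barcode
  r1[, id := sub("^@[^:]*", paste0("@", barcode), id)]
  r2[, id := sub("^@[^:]*", paste0("@", barcode), id)]
  trim <- function(dt) {
    hit <- regexpr(adapter, dt$seq, fixed = TRUE)
    cut <- ifelse(hit > 0L, hit - 1L, nchar(dt$seq))
    dt[, `:=`(seq = substr(seq, 1L, cut), qual = substr(qual, 1L, cut))]
  }
  trim(r1); trim(r2)
  keep <- nchar(r1$seq) >= min_len & nchar(r2$seq) >= min_len
  n_trimmed_short <- sum(!keep)
  write_fastq(r1[keep], out1)
  write_fastq(r2[keep], out2)
  invisible(list(n_in = n_in, n_out = sum(keep),
                 n_short_r1 = n_short_r1, n_trimmed_short = n_trimmed_short))
}

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  data.table(id = lines[c(TRUE, FALSE, FALSE, FALSE)],
             seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
             qual = lines[c(FALSE, FALSE, FALSE, TRUE)])
}

write_fastq <- function(dt, path) {
  if (nrow(dt) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(4L * nrow(dt))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- dt$id
  out[c(FALSE, TRUE, FALSE, FALSE)] <- dt$seq
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- dt$qual
  writeLines(out, path)
  invisible(path)
}

#' Reconstruct 10X molecules from a filtered pair table
#'
#' Read pairs sharing a barcode and mapping to the same scaffold within
#' `gap_max` of each other are assigned to the same molecule: within each
#' `(barcode, scaffold)` group sorted by start, a pair extends the current
#' molecule if its start is at most `gap_max` beyond the previous pair's
#' start, and opens a new molecule otherwise. A molecule spans from the
#' minimum start to the maximum end of its member pairs. Molecules shorter
#' than `molecule_min_len` or supported by fewer than `min_pairs` pairs are
#' discarded.
#'
#' @param pairs pair table as returned by [read_pairs()], sorted by
#'   `(barcode, scaffold, start)`; unsorted input is an error.
#' @param gap_max maximum start-to-start gap within a molecule (default
#'   500 kb).
#' @param molecule_min_len minimum molecule span (default 1 kb).
#' @param min_pairs minimum supporting pairs per molecule (default 2).
#' @return A `data.table` with columns `scaffold`, `start`, `end`,
#'   `barcode`, `library`, `n_pairs`.
#' @examples
#' p <- data.table::data.table(
#'   scaffold = "s", start = c(0L, 490000L), end = c(300L, 490300L),
#'   barcode = "AC", library = "L1", mapq = 60L)
#' call_molecules(p, min_pairs = 1)
#' @export
call_molecules <- function(pairs, gap_max = 500000L, molecule_min_len = 1000L,
                           min_pairs = 2L) {
  pairs <- as.data.table(pairs)
  if (nrow(pairs) == 0L)
    return(data.table(scaffold = character(), start = integer(),
                      end = integer(), barcode = character(),
                      library = character(), n_pairs = integer()))
  if (is.unsorted_pairs(pairs))
    stop("pair table must be sorted by (barcode, scaffold, start)")
  ## single pass: a new molecule starts at every barcode/scaffold change
  ## or start-to-start gap beyond gap_max
  n <- nrow(pairs)
  b <- pairs$barcode; s <- pairs$scaffold; st <- pairs$start
  new_mol <- c(TRUE, b[-1L] != b[-n] | s[-1L] != s[-n] |
                 (st[-1L] - st[-n]) > gap_max)
  pairs <- copy(pairs)[, grp := cumsum(new_mol)]
  mols <- pairs[, .(barcode = barcode[1L], scaffold = scaffold[1L],
                    start = min(start), end = max(end), n_pairs = .N,
                    library = library[1L]), by = .(grp)]
  mols <- mols[(end - start) >= molecule_min_len & n_pairs >= min_pairs]
  mols[, grp := NULL]
  setcolorder(mols, c("scaffold", "start", "end", "barcode", "library", "n_pairs"))
  setorder(mols, scaffold, start, end, barcode)
  mols[]
}

is.unsorted_pairs <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  b <- pairs$barcode; s <- pairs$scaffold; st <- pairs$start
  i <- 2:n
  ok <- b[i - 1L] < b[i] |
    (b[i - 1L] == b[i] & (s[i - 1L] < s[i] |
                          (s[i - 1L] == s[i] & st[i - 1L] <= st[i])))
  !all(ok)
}
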