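#' Scaffold sets
#'
#' A `scaffold_set` holds the current assembly state: one record per scaffold
#' with a unique name and a positive length, and optionally the nucleotide
#' sequences themselves (a [Biostrings::DNAStringSet]). Sequence-free sets are
#' sufficient for every coordinate-level operation; sequences are only needed
#' for in silico digestion and FASTA output.
#'
#' @param lengths named integer vector of scaffold lengths, or a data.frame /
#'   data.table with columns `scaffold` and `length`.
#' @param seq optional `DNAStringSet` (or named character vector) of scaffold
#'   sequences. When given, lengths are checked against (or derived from) it.
#' @return An object of class `scaffold_set`: a list with elements `info`
#'   (a `data.table` with columns `scaffold`, `length`) and `seq` (a
#'   `DNAStringSet` or `NULL`).
#' @examples
#' ss <- scaffold_set(c(s1 = 1000L, s2 = 500L))
#' scaffold_lengths(ss)
#' @export
scaffold_set <- function(lengths = NULL, seq = NULL) {
  if (!is.null(seq) && !methods::is(seq, "DNAStringSet"))
    seq <- Biostrings::DNAStringSet(seq)
  if (is.null(lengths)) {
    if (is.null(seq)) {
      info <- data.table(scaffold = character(), length = integer())
    } else {
      info <- data.table(scaffold = names(seq), length = Biostrings::width(seq))
    }
  } else if (is.data.frame(lengths)) {
    info <- as.data.table(lengths)[, .(scaffold = as.character(scaffold),
                                       length = as.integer(length))]
  } else {
    info <- data.table(scaffold = names(lengths), length = as.integer(lengths))
  }
  if (anyNA(info$length) || any(info$length < 1L))
    stop("scaffold lengths must be positive integers")
  if (anyDuplicated(info$scaffold))
    stop("duplicate scaffold names: ",
         paste(unique(info$scaffold[duplicated(info$scaffold)]), collapse = ", "))
  if (!is.null(seq)) {
    if (!setequal(names(seq), info$scaffold))
      stop("sequence names do not match scaffold names")
    seq <- seq[info$scaffold]
    if (!all(Biostrings::width(seq) == info$length))
      stop("sequence lengths disagree with the length field")
  }
  structure(list(info = info, seq = seq), class = "scaffold_set")
}

#' @rdname scaffold_set
#' @param x a `scaffold_set`.
#' @export
scaffold_lengths <- function(x) {
  stopifnot(inherits(x, "scaffold_set"))
  setNames(x$info$length, x$info$scaffold)
}

#' @rdname scaffold_set
#' @export
scaffold_names <- function(x) {
  stopifnot(inherits(x, "scaffold_set"))
  x$info$scaffold
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat(sprintf("scaffold_set: %d scaffolds, %s bp%s\n",
              nrow(x$info), format(sum(as.numeric(x$info$length)),
                                   big.mark = ",", scientific = FALSE),
              if (is.null(x$seq)) " (lengths only)" else " (with sequence)"))
  invisible(x)
}

#' @export
length.scaffold_set <- function(x) nrow(x$info)

#' Load an assembly from FASTA or a name/length table
#'
#' Reads either a (possibly gzipped) FASTA file or a two-column tab-separated
#' table of scaffold name and length. FASTA is detected by a leading `>`.
#'
#' @param path path to a FASTA file or a two-column name/length TSV.
#' @return A [scaffold_set].
#' @export
load_scaffolds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) {
    warning("empty assembly file: ", path)
    return(scaffold_set())
  }
  if (startsWith(first, ">")) {
    seq <- Biostrings::readDNAStringSet(path)
    names(seq) <- sub("\\s.*", "", names(seq))
    if (any(Biostrings::width(seq) == 0L))
      stop("zero-length sequence record in ", path)
    scaffold_set(seq = seq)
  } else {
    tab <- fread(path, header = FALSE, col.names = c("scaffold", "length"))
    scaffold_set(tab[, .(scaffold, length)])
  }
}

#' Write a scaffold set to FASTA
#'
#' @param x a [scaffold_set] carrying sequence.
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  stopifnot(inherits(x, "scaffold_set"))
  if (is.null(x$seq)) stop("scaffold set carries no sequence")
  Biostrings::writeXStringSet(x$seq, path, width = width)
  invisible(path)
}

#' Assembly contiguity statistics
#'
#' Computes standard assembly summary statistics. N50 is the largest scaffold
#' length L such that scaffolds of length >= L together cover at least half of
#' the total assembly span; N90 is defined analogously at 90%.
#'
#' @param x a [scaffold_set], or a numeric vector of lengths.
#' @return A list with `total_bp`, `count`, `n50`, `n90`, and counts and
#'   summed lengths of scaffolds at least 1 kb and 1 Mb long.
#' @examples
#' assembly_stats(scaffold_set(c(a = 10L, b = 10L, c = 10L)))$n50
#' @export
assembly_stats <- function(x) {
  len <- if (inherits(x, "scaffold_set")) x$info$length else as.integer(x)
  if (length(len) == 0L) stop("empty scaffold set")
  len <- sort(len, decreasing = TRUE)
  total <- sum(as.numeric(len))
  csum <- cumsum(as.numeric(len))
  list(
    total_bp = total,
    count = length(len),
    n50 = len[which(csum >= 0.5 * total)[1L]],
    n90 = len[which(csum >= 0.9 * total)[1L]],
    count_1kb = sum(len >= 1e3), bp_1kb = sum(as.numeric(len[len >= 1e3])),
    count_1mb = sum(len >= 1e6), bp_1mb = sum(as.numeric(len[len >= 1e6]))
  )
}
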