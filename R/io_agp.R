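#' AGP 2.1 layouts
#'
#' A pseudomolecule layout is a `data.table` in AGP semantics: one row per
#' component (`component_type == "W"`, a placed scaffold) or gap
#' (`component_type == "U"`). Internal package coordinates are 0-based
#' half-open; AGP rows are 1-based inclusive, converted at the file boundary.
#'
#' Columns: `object`, `object_start`, `object_end` (1-based inclusive),
#' `part_number`, `component_type`, `component` (scaffold name, `NA` for
#' gaps), `component_start`, `component_end` (1-based within the component,
#' `NA` for gaps), `orientation` (`+`, `-` or `?`; `NA` for gaps),
#' `gap_length` (`NA` for components).
#'
#' @param layout a layout `data.table` as described above.
#' @param path file path.
#' @return `write_agp()` returns `path` invisibly; `read_agp()` returns the
#'   layout `data.table`.
#' @name agp
NULL

validate_layout <- function(layout) {
  need <- c("object", "object_start", "object_end", "part_number",
            "component_type")
  if (!all(need %in% names(layout)))
    stop("layout lacks columns: ", paste(setdiff(need, names(layout)), collapse = ", "))
  lay <- as.data.table(layout)
  setorder(lay, object, part_number)
  lay[, {
    if (!identical(part_number, seq_len(.N)))
      stop("part numbers of object ", .BY[[1]], " are not consecutive from 1")
    if (object_start[1L] != 1L)
      stop("object ", .BY[[1]], " does not start at 1")
    if (.N > 1L && any(object_start[-1L] != object_end[-.N] + 1L))
      stop("coverage gap or overlap in object ", .BY[[1]])
    if (any(object_end < object_start))
      stop("negative-length row in object ", .BY[[1]])
    NULL
  }, by = object]
  invisible(lay)
}

#' @rdname agp
#' @export
write_agp <- function(layout, path) {
  lay <- validate_layout(layout)
  is_gap <- lay$component_type == "U"
  lines <- character(nrow(lay))
  lines[!is_gap] <- lay[!is_gap, sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s",
    object, object_start, object_end, part_number, component,
    component_start, component_end, orientation)]
  lines[is_gap] <- lay[is_gap, sprintf("%s\t%d\t%d\t%d\tU\t%d\tscaffold\tyes\tmap",
    object, object_start, object_end, part_number, gap_length)]
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' @rdname agp
#' @export
read_agp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  if (length(txt) == 0L) stop("AGP file has no data rows: ", path)
  raw <- fread(text = txt, header = FALSE, sep = "\t", colClasses = "character")
  ## fifelse evaluates both branches, so the type-mixed columns (gap rows
  ## hold text where component rows hold numbers) are coerced quietly
  lay <- suppressWarnings(raw[, .(
    object = V1,
    object_start = as.integer(V2),
    object_end = as.integer(V3),
    part_number = as.integer(V4),
    component_type = V5,
    component = fifelse(V5 == "U", NA_character_, V6),
    component_start = fifelse(V5 == "U", NA_integer_, as.integer(V7)),
    component_end = fifelse(V5 == "U", NA_integer_, as.integer(V8)),
    orientation = fifelse(V5 == "U", NA_character_, V9),
    gap_length = fifelse(V5 == "U", as.integer(V6), NA_integer_))])
  validate_layout(lay)
  lay[]
}
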