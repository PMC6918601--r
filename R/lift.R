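#' Membership maps and coordinate lifting
#'
#' A membership map describes how old coordinate units (scaffolds) are
#' placed inside new units (pieces of a broken scaffold, super-scaffolds,
#' or pseudomolecules). It is a `data.table` with columns:
#' `member` (old unit), `unit` (new unit), `offset` (0-based start of the
#' member inside the new unit), `orientation` (`"+"` or `"-"`), and
#' `member_length`.
#'
#' Points at position `p` on a member lift to `offset + p` on a forward
#' member and to `offset + (member_length - p)` on a reverse one. Intervals
#' `[start, end)` lift to `[offset + start, offset + end)` forward and
#' `[offset + member_length - end, offset + member_length - start)` reverse.
#'
#' @param map a membership map.
#' @name lifting
NULL

check_membership <- function(map) {
  need <- c("member", "unit", "offset", "orientation", "member_length")
  if (!all(need %in% names(map)))
    stop("membership map lacks columns: ",
         paste(setdiff(need, names(map)), collapse = ", "))
  if (!all(map$orientation %in% c("+", "-")))
    stop("membership orientation must be '+' or '-'")
  as.data.table(map)
}

## identity membership for a scaffold set
identity_membership <- function(scaffolds) {
  scaffolds$info[, .(member = scaffold, unit = scaffold, offset = 0L,
                     orientation = "+", member_length = length)]
}

#' Lift point positions through a membership map
#'
#' @param dt table holding member names and positions.
#' @param map membership map (see [lifting]).
#' @param scaffold_col,pos_col names of the member and position columns.
#' @return A copy of `dt` with the member column replaced by the new unit
#'   name and the position column lifted. Rows whose member is absent from
#'   the map are an error.
#' @rdname lifting
#' @export
lift_points <- function(dt, map, scaffold_col = "scaffold", pos_col = "position") {
  map <- check_membership(map)
  dt <- as.data.table(dt)
  if (nrow(dt) == 0L) return(dt)
  m <- map[match(dt[[scaffold_col]], map$member)]
  if (anyNA(m$unit))
    stop("member(s) missing from membership map: ",
         paste(unique(dt[[scaffold_col]][is.na(m$unit)]), collapse = ", "))
  p <- dt[[pos_col]]
  newp <- fifelse(m$orientation == "+", m$offset + p,
                  m$offset + (m$member_length - p))
  out <- copy(dt)
  set(out, j = scaffold_col, value = m$unit)
  set(out, j = pos_col, value = as.integer(newp))
  out
}

#' @param start_col,end_col interval column names for [lift_intervals()].
#' @rdname lifting
#' @export
lift_intervals <- function(dt, map, scaffold_col = "scaffold",
                           start_col = "start", end_col = "end") {
  map <- check_membership(map)
  dt <- as.data.table(dt)
  if (nrow(dt) == 0L) return(dt)
  m <- map[match(dt[[scaffold_col]], map$member)]
  if (anyNA(m$unit))
    stop("member(s) missing from membership map: ",
         paste(unique(dt[[scaffold_col]][is.na(m$unit)]), collapse = ", "))
  s <- dt[[start_col]]; e <- dt[[end_col]]
  ns <- fifelse(m$orientation == "+", m$offset + s,
                m$offset + (m$member_length - e))
  ne <- fifelse(m$orientation == "+", m$offset + e,
                m$offset + (m$member_length - s))
  out <- copy(dt)
  set(out, j = scaffold_col, value = m$unit)
  set(out, j = start_col, value = as.integer(ns))
  set(out, j = end_col, value = as.integer(ne))
  out
}

#' @describeIn lifting Lift both sides of a two-sided link/pair table;
#'   sides are re-canonicalized afterwards.
#' @param links a two-sided link table (`scaffold1`, `pos1`, `scaffold2`,
#'   `pos2`).
#' @export
lift_link_sides <- function(links, map) {
  lk <- lift_points(links, map, "scaffold1", "pos1")
  lk <- lift_points(lk, map, "scaffold2", "pos2")
  canonical_link_sides(lk)
}
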