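## Lineage-table text format: comma-separated, header row, NA for missing
## optional fields. Required columns first, optional columns kept if present.
.lineage_required <- c("cell_id", "parent_id", "birth_time", "division_time",
                       "birth_area", "division_area")
.lineage_optional <- c("g1s_time", "g1s_area", "zone", "g", "d")

#' Write a lineage table as delimited text
#'
#' Comma-separated with a header row; missing optional values are written as
#' `NA`. The schema is the one shared by the population simulator, the
#' synthetic generator and the analysis functions: required columns
#' `cell_id`, `parent_id`, `birth_time`, `division_time`, `birth_area`,
#' `division_area`; optional `g1s_time`, `g1s_area`, `zone`, `g`, `d`.
#'
#' @param table Lineage table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(table, path) {
  miss <- setdiff(.lineage_required, names(table))
  if (length(miss))
    stop("lineage table is missing required columns: ",
         paste(miss, collapse = ", "))
  keep <- c(.lineage_required,
            intersect(.lineage_optional, names(table)))
  utils::write.csv(table[keep], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate lineage-table invariants
#'
#' Checks the structural invariants of a lineage table: positive areas,
#' division after birth, daughters born when their parent divides, and
#' daughter birth areas summing to the parent division area. Measured data
#' carry measurement noise, so the area-conservation check takes a
#' tolerance.
#'
#' @param table Lineage table data frame.
#' @param area_tol Absolute tolerance (um^2) on daughter-area conservation
#'   and on the parent-division/daughter-birth time match (default 1e-6,
#'   appropriate for simulated tables; use ~3x the measurement noise s.d.
#'   for measured ones).
#' @return A data frame of violations (`row`, `rule`, `detail`); zero rows
#'   when the table is clean.
#' @export
validate_lineage_table <- function(table, area_tol = 1e-6) {
  v <- list()
  bad <- function(rows, rule, detail) {
    if (length(rows))
      v[[length(v) + 1L]] <<- data.frame(row = rows, rule = rule,
                                         detail = detail,
                                         stringsAsFactors = FALSE)
  }
  bad(which(!is.finite(table$birth_area) | table$birth_area <= 0),
      "positive_area", "birth_area must be > 0")
  bad(which(!is.na(table$division_area) & table$division_area <= 0),
      "positive_area", "division_area must be > 0")
  bad(which(!is.na(table$division_time) &
              table$division_time <= table$birth_time),
      "time_order", "division_time must exceed birth_time")
  idx <- match(table$parent_id, table$cell_id)
  linked <- which(!is.na(idx))
  if (length(linked)) {
    pd <- table$division_time[idx[linked]]
    off <- abs(table$birth_time[linked] - pd) > area_tol
    bad(linked[off], "birth_at_parent_division",
        "daughter birth_time must equal parent division_time")
    for (pid in unique(table$parent_id[linked])) {
      kids <- which(!is.na(table$parent_id) & table$parent_id == pid)
      if (length(kids) == 2L) {
        parent_row <- match(pid, table$cell_id)
        tot <- sum(table$birth_area[kids])
        if (abs(tot - table$division_area[parent_row]) > area_tol)
          bad(kids, "area_conservation",
              sprintf("daughter areas sum to %.6g, parent divided at %.6g",
                      tot, table$division_area[parent_row]))
      }
    }
  }
  if (!length(v))
    return(data.frame(row = integer(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

#' Read a lineage table from delimited text
#'
#' Reads the schema written by [write_lineage_table()] and validates its
#' invariants. In strict mode any violation aborts with the offending row
#' numbers; in lenient mode violations are attached as the `"violations"`
#' attribute and reported as a warning.
#'
#' @param path CSV file path.
#' @param strict Abort on invariant violations (default `TRUE`).
#' @param area_tol Passed to [validate_lineage_table()].
#' @return The lineage table data frame.
#' @export
read_lineage_table <- function(path, strict = TRUE, area_tol = 1e-6) {
  if (!file.exists(path)) stop("no such file: ", path)
  table <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.lineage_required, names(table))
  if (length(miss))
    stop("malformed lineage table ", path, ": missing columns ",
         paste(miss, collapse = ", "))
  for (col in c("birth_time", "division_time", "birth_area", "division_area",
                intersect(c("g1s_time", "g1s_area", "g", "d"), names(table)))) {
    if (!is.numeric(table[[col]])) {
      coerced <- suppressWarnings(as.numeric(table[[col]]))
      if (any(is.na(coerced) & !is.na(table[[col]]) & table[[col]] != "NA"))
        stop("malformed lineage table ", path, ": non-numeric values in ",
             col)
      table[[col]] <- coerced
    }
  }
  viol <- validate_lineage_table(table, area_tol = area_tol)
  if (nrow(viol)) {
    if (strict)
      stop("lineage table ", path, " violates invariants at rows ",
           paste(utils::head(unique(viol$row), 10L), collapse = ", "),
           " (", viol$rule[1L], ": ", viol$detail[1L], ")")
    warning(nrow(viol), " invariant violations flagged (see attr ",
            "'violations')")
    attr(table, "violations") <- viol
  }
  table
}
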