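# Table schemas and validated CSV I/O. All downstream modules consume tables
# that have passed validate_table(), so malformed input stops here.

.SCHEMAS <- list(
  transfer = list(
    columns = c("lineage_id", "culture_type", "antibiotic", "transfer",
                "od600", "concentration", "alive"),
    types = c("character", "character", "character", "integer",
              "numeric", "numeric", "logical")
  ),
  growth = list(
    columns = c("replicate_id", "strain", "time_h", "cfu_per_ml"),
    types = c("character", "character", "numeric", "numeric")
  ),
  mic = list(
    columns = c("replicate_id", "concentration", "od600", "supplemented",
                "culture_type"),
    types = c("character", "numeric", "numeric", "logical", "character")
  ),
  colony = list(
    columns = c("population_id", "colony_id", "mmab", "mmab_trp",
                "mmab_tyr", "lb"),
    types = c("character", "character", "logical", "logical", "logical",
              "logical")
  )
)

#' Table schemas
#'
#' The four table kinds the package exchanges as CSV:
#' \describe{
#'   \item{`"transfer"`}{per-lineage OD600 and antibiotic concentration at
#'     each serial transfer (`lineage_id`, `culture_type`, `antibiotic`,
#'     `transfer`, `od600`, `concentration`, `alive`).}
#'   \item{`"growth"`}{CFU counts on the fixed time grid (`replicate_id`,
#'     `strain`, `time_h`, `cfu_per_ml`).}
#'   \item{`"mic"`}{dose--response OD over a concentration grid
#'     (`replicate_id`, `concentration`, `od600`, `supplemented`,
#'     `culture_type`).}
#'   \item{`"colony"`}{growth flags of screened colonies on the four
#'     selective media (`population_id`, `colony_id`, `mmab`, `mmab_trp`,
#'     `mmab_tyr`, `lb`).}
#' }
#'
#' @return Character vector of schema names.
#' @export
table_schemas <- function() names(.SCHEMAS)

.coerce_column <- function(x, type, col) {
  out <- switch(type,
    character = as.character(x),
    integer = {
      v <- suppressWarnings(as.numeric(x))
      if (any(!is.na(v) & v != round(v))) {
        stop(sprintf("column '%s': non-integer value in row %d", col,
                     which(v != round(v))[1]), call. = FALSE)
      }
      as.integer(v)
    },
    numeric = suppressWarnings(as.numeric(x)),
    logical = {
      if (is.logical(x)) x else {
        v <- toupper(trimws(as.character(x)))
        out <- rep(NA, length(v))
        out[v %in% c("TRUE", "T", "1")] <- TRUE
        out[v %in% c("FALSE", "F", "0")] <- FALSE
        out
      }
    }
  )
  bad <- which(is.na(out) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    stop(sprintf("column '%s': cannot parse value '%s' in row %d as %s",
                 col, x[bad[1]], bad[1], type), call. = FALSE)
  }
  out
}

.fail_row <- function(schema, col, row, what) {
  stop(sprintf("%s table: %s (column '%s', row %d)", schema, what, col, row),
       call. = FALSE)
}

#' Validate a table against its schema
#'
#' Checks column presence, types, enumerations and the schema's invariants:
#' non-negative ODs and CFU counts, contiguous transfer indices from 0 per
#' lineage, a dead lineage never coming back alive, strictly increasing MIC
#' concentration grids per replicate, growth-curve times drawn from
#' [TIME_GRID_H], and viable (LB-positive) colonies.
#'
#' @param x data.frame.
#' @param schema one of [table_schemas()].
#' @return The validated (type-coerced) data.frame, columns in schema order.
#' @export
validate_table <- function(x, schema = c("transfer", "growth", "mic", "colony")) {
  schema <- match.arg(schema)
  sc <- .SCHEMAS[[schema]]
  missing <- setdiff(sc$columns, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s table: missing column(s): %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- x[sc$columns]
  for (i in seq_along(sc$columns)) {
    x[[i]] <- .coerce_column(x[[i]], sc$types[i], sc$columns[i])
  }
  for (col in sc$columns) {
    bad <- which(is.na(x[[col]]))
    if (length(bad) > 0) .fail_row(schema, col, bad[1], "missing value")
  }

  if (schema == "transfer") {
    bad <- which(!x$culture_type %in% CULTURE_TYPES)
    if (length(bad)) .fail_row(schema, "culture_type", bad[1], "unknown culture type")
    bad <- which(!x$antibiotic %in% ANTIBIOTICS)
    if (length(bad)) .fail_row(schema, "antibiotic", bad[1], "unknown antibiotic")
    bad <- which(x$od600 < 0)
    if (length(bad)) .fail_row(schema, "od600", bad[1], "negative OD600")
    bad <- which(x$concentration < 0)
    if (length(bad)) .fail_row(schema, "concentration", bad[1], "negative concentration")
    for (id in unique(x$lineage_id)) {
      rows <- which(x$lineage_id == id)
      tr <- x$transfer[rows]
      o <- order(tr)
      if (!identical(tr[o], seq(0L, length.out = length(tr)))) {
        .fail_row(schema, "transfer", rows[1],
                  sprintf("transfers of lineage '%s' not contiguous from 0", id))
      }
      al <- x$alive[rows][o]
      if (any(diff(al) > 0)) {
        .fail_row(schema, "alive", rows[1],
                  sprintf("lineage '%s' revives after death", id))
      }
    }
  } else if (schema == "growth") {
    bad <- which(!x$strain %in% STRAINS)
    if (length(bad)) .fail_row(schema, "strain", bad[1], "unknown strain")
    bad <- which(!x$time_h %in% TIME_GRID_H)
    if (length(bad)) .fail_row(schema, "time_h", bad[1], "time not on the sampling grid")
    bad <- which(x$cfu_per_ml < 0)
    if (length(bad)) .fail_row(schema, "cfu_per_ml", bad[1], "negative CFU")
  } else if (schema == "mic") {
    bad <- which(x$od600 < 0)
    if (length(bad)) .fail_row(schema, "od600", bad[1], "negative OD600")
    bad <- which(x$concentration < 0)
    if (length(bad)) .fail_row(schema, "concentration", bad[1], "negative concentration")
    for (id in unique(x$replicate_id)) {
      conc <- x$concentration[x$replicate_id == id]
      if (length(conc) < 2) {
        .fail_row(schema, "concentration", which(x$replicate_id == id)[1],
                  sprintf("replicate '%s' has fewer than 2 concentrations", id))
      }
      if (any(diff(conc) <= 0)) {
        .fail_row(schema, "concentration", which(x$replicate_id == id)[1],
                  sprintf("concentration grid of replicate '%s' not strictly increasing", id))
      }
    }
  } else if (schema == "colony") {
    bad <- which(!x$lb)
    if (length(bad)) .fail_row(schema, "lb", bad[1], "nonviable colony (no LB growth)")
  }
  rownames(x) <- NULL
  x
}

#' Read a validated table from CSV
#'
#' Reads a UTF-8 CSV with a header row and dot decimal separator (plate-reader
#' export convention) and validates it with [validate_table()]. Row order is
#' preserved.
#'
#' @param path CSV file path.
#' @param schema one of [table_schemas()].
#' @return Validated data.frame.
#' @seealso [write_table()]
#' @export
read_table <- function(path, schema = c("transfer", "growth", "mic", "colony")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", fileEncoding = "UTF-8")
  validate_table(x, schema)
}

#' Write a table to CSV
#'
#' Validates, orders columns canonically and writes a header-row CSV that
#' [read_table()] round-trips exactly.
#'
#' @param x data.frame conforming to `schema`.
#' @param path output file path.
#' @param schema one of [table_schemas()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema = c("transfer", "growth", "mic", "colony")) {
  schema <- match.arg(schema)
  if (nrow(x) > 0) x <- validate_table(x, schema)
  else x <- x[.SCHEMAS[[schema]]$columns]
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
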