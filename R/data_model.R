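#' Attach a schema to a data frame of patient records
#'
#' Validates `data` against `schema`, assigns stable 0-based row identifiers
#' in a `.row_id` column (unless one is already present), and returns a
#' tibble carrying the schema as an attribute. Row ids survive subsampling,
#' so cleaning reports and fold plans can refer to original rows.
#'
#' @param data A data frame whose columns are the schema's attributes plus
#'   the target column (a `.row_id` column is allowed and preserved).
#' @param schema A [pca_schema()].
#' @return A tibble of class `patient_tbl` with a `.row_id` column.
#' @export
patient_table <- function(data, schema) {
  data <- tibble::as_tibble(data)
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "pcatree_unknown_column")
  }
  extra <- setdiff(names(data), c(cols, ".row_id"))
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown column(s): ", paste(extra, collapse = ", ")),
      class = "pcatree_unknown_column")
  }
  if (!".row_id" %in% names(data)) {
    data$.row_id <- seq_len(nrow(data)) - 1L
  }
  data <- data[, c(".row_id", cols)]
  rep <- validate_table(data, schema)
  if (!rep$ok) {
    v <- rep$violations
    rlang::abort(
      sprintf("invalid table: %d violation(s); first: row %s, column '%s': %s",
        nrow(v), v$row_id[1], v$attribute[1], v$reason[1]),
      class = "pcatree_invalid_table")
  }
  attr(data, "pca_schema") <- schema
  class(data) <- c("patient_tbl", class(data))
  data
}

#' Retrieve the schema attached to a patient table
#'
#' @param data A `patient_tbl`.
#' @return The [pca_schema()] carried by `data`.
#' @export
table_schema <- function(data) {
  sch <- attr(data, "pca_schema", exact = TRUE)
  if (is.null(sch)) {
    rlang::abort("no schema attached; use patient_table() or pass `schema`",
      class = "pcatree_schema_error")
  }
  sch
}

# schema if present, else the explicit argument
resolve_schema <- function(data, schema = NULL) {
  if (!is.null(schema)) schema else table_schema(data)
}

#' Validate a table against its schema
#'
#' Enumerates every violation (wrong type, value outside a nominal domain or
#' numeric range, missing value, target outside declared labels) rather than
#' stopping at the first. Violations are reported, not raised.
#'
#' @param data A data frame with the schema's columns (and optionally `.row_id`).
#' @param schema A [pca_schema()]; defaults to the one attached to `data`.
#' @return A list of class `pcat_validation` with elements `ok` (logical) and
#'   `violations` (a tibble with columns `row_id`, `attribute`, `reason`).
#' @export
validate_table <- function(data, schema = NULL) {
  schema <- resolve_schema(data, schema)
  row_id <- if (".row_id" %in% names(data)) data$.row_id else seq_len(nrow(data)) - 1L
  viol <- list()
  add <- function(rows, attribute, reason) {
    if (length(rows) > 0) {
      viol[[length(viol) + 1L]] <<- tibble::tibble(
        row_id = row_id[rows], attribute = attribute, reason = reason)
    }
  }
  check_col <- function(values, name, kind, domain) {
    if (kind == "numeric") {
      if (!is.numeric(values)) {
        add(seq_along(values), name, "column is not numeric")
        return()
      }
      add(which(is.na(values)), name, "missing value")
      bad <- which(!is.na(values) & (values < domain[1] | values > domain[2]))
      add(bad, name, sprintf("value outside range [%g, %g]", domain[1], domain[2]))
    } else {
      values <- as.character(values)
      add(which(is.na(values)), name, "missing value")
      bad <- which(!is.na(values) & !(values %in% domain))
      add(bad, name, "nominal value outside declared domain")
    }
  }
  for (i in seq_len(nrow(schema$attributes))) {
    nm <- schema$attributes$name[i]
    check_col(data[[nm]], nm, schema$attributes$kind[i], schema$attributes$domain[[i]])
  }
  tgt <- schema$target
  if (tgt$kind == "nominal") {
    check_col(data[[tgt$name]], tgt$name, "nominal", tgt$labels)
  } else {
    check_col(data[[tgt$name]], tgt$name, "numeric", tgt$range)
  }
  violations <- if (length(viol) > 0) {
    dplyr::bind_rows(viol)
  } else {
    tibble::tibble(row_id = integer(), attribute = character(), reason = character())
  }
  structure(list(ok = nrow(violations) == 0, violations = violations),
    class = "pcat_validation")
}

#' @export
print.pcat_validation <- function(x, ...) {
  if (x$ok) {
    cat("<pcat_validation> ok\n")
  } else {
    cat(sprintf("<pcat_validation> %d violation(s)\n", nrow(x$violations)))
    print(x$violations, ...)
  }
  invisible(x)
}

#' Load a patient table from CSV plus a JSON schema sidecar
#'
#' The CSV must have a header row matching the schema's attribute names plus
#' the target name (in any order; a `.row_id` column written by
#' [write_patient_table()] is honoured). Every cell is type-checked; blank
#' cells are rejected with the offending row and column named, mirroring the
#' discard-incomplete-records preprocessing rule. Distinct failures raise
#' distinct condition classes: `pcatree_unknown_column`,
#' `pcatree_unparseable_numeric`, `pcatree_invalid_table`.
#'
#' @param csv_path Path to an RFC 4180 CSV file with a header row.
#' @param schema Path to a schema JSON file, or a [pca_schema()].
#' @return A `patient_tbl`.
#' @export
read_patient_table <- function(csv_path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  raw <- utils::read.csv(csv_path, colClasses = "character", check.names = FALSE,
    na.strings = NULL, fileEncoding = "UTF-8")
  cols <- schema_columns(schema)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("CSV is missing column(s): ",
      paste(missing_cols, collapse = ", ")), class = "pcatree_unknown_column")
  }
  extra <- setdiff(names(raw), c(cols, ".row_id"))
  if (length(extra) > 0) {
    rlang::abort(paste0("CSV has column(s) not in schema: ",
      paste(extra, collapse = ", ")), class = "pcatree_unknown_column")
  }
  kinds <- stats::setNames(schema$attributes$kind, schema$attributes$name)
  kinds[schema$target$name] <- schema$target$kind
  out <- raw
  for (nm in cols) {
    v <- raw[[nm]]
    blank <- which(v == "")
    if (length(blank) > 0) {
      rlang::abort(sprintf("missing cell at row %d, column '%s'", blank[1], nm),
        class = "pcatree_invalid_table")
    }
    if (kinds[[nm]] == "numeric") {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed))
      if (length(bad) > 0) {
        rlang::abort(sprintf("unparseable numeric cell at row %d, column '%s' ('%s')",
          bad[1], nm, v[bad[1]]), class = "pcatree_unparseable_numeric")
      }
      out[[nm]] <- parsed
    }
  }
  if (".row_id" %in% names(out)) {
    out$.row_id <- as.integer(out$.row_id)
  }
  patient_table(out, schema)
}

#' Write a patient table to CSV plus a JSON schema sidecar
#'
#' Numeric cells are serialised with 17 significant digits so that a
#' write-then-load round trip reproduces the table bit-for-bit.
#'
#' @param data A `patient_tbl` (or data frame plus explicit `schema`).
#' @param csv_path Output CSV path.
#' @param schema_path Optional output path for the schema JSON.
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return `csv_path`, invisibly.
#' @export
write_patient_table <- function(data, csv_path, schema_path = NULL, schema = NULL) {
  schema <- resolve_schema(data, schema)
  cols <- schema_columns(schema)
  out <- as.data.frame(data[, c(".row_id", cols)], check.names = FALSE)
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && nm != ".row_id") {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, csv_path, row.names = FALSE, quote = TRUE,
    fileEncoding = "UTF-8")
  if (!is.null(schema_path)) write_schema(schema, schema_path)
  invisible(csv_path)
}

#' @method tidy pcat_validation
#' @export
tidy.pcat_validation <- function(x, ...) x$violations

# Target labels in schema order for a nominal target.
target_labels <- function(schema) {
  if (schema$target$kind != "nominal") {
    rlang::abort("target is numeric; discretize it first",
      class = "pcatree_schema_error")
  }
  schema$target$labels
}
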