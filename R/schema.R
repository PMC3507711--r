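#' Declare an attribute schema for patient tables
#'
#' A schema names every descriptive attribute, declares it `nominal` (with a
#' legal value set) or `numeric` (with a finite range), and declares the
#' target attribute. Attribute order is significant: split-selection
#' tie-breaks, vote tie-breaks and serialisation all follow schema order.
#'
#' @param attributes A data frame with columns `name` (character), `kind`
#'   (`"nominal"` or `"numeric"`) and `domain` (a list column: a character
#'   vector of legal values for nominal attributes, a length-2 numeric range
#'   for numeric attributes).
#' @param target A list with elements `name`, `kind` (`"nominal"` for
#'   classification targets, `"numeric"` for a continuous dose target that is
#'   discretized downstream) and either `labels` (ordered class labels) or
#'   `range` (length-2 numeric).
#'
#' @return An object of class `pca_schema`.
#' @export
#' @examples
#' sch <- pca_schema(
#'   tibble::tibble(
#'     name = c("age", "gender"),
#'     kind = c("numeric", "nominal"),
#'     domain = list(c(18, 90), c("F", "M"))
#'   ),
#'   target = list(name = "outcome", kind = "nominal", labels = c("no", "yes"))
#' )
pca_schema <- function(attributes, target) {
  attributes <- tibble::as_tibble(attributes)
  stopifnot(all(c("name", "kind", "domain") %in% names(attributes)))
  if (anyDuplicated(attributes$name)) {
    rlang::abort("attribute names must be unique", class = "pcatree_schema_error")
  }
  if (!all(attributes$kind %in% c("nominal", "numeric"))) {
    rlang::abort("attribute kind must be 'nominal' or 'numeric'",
      class = "pcatree_schema_error")
  }
  for (i in seq_len(nrow(attributes))) {
    d <- attributes$domain[[i]]
    if (attributes$kind[i] == "nominal") {
      if (length(d) < 1 || anyDuplicated(d)) {
        rlang::abort(sprintf("nominal domain for '%s' must be a non-empty set",
          attributes$name[i]), class = "pcatree_schema_error")
      }
      attributes$domain[[i]] <- as.character(d)
    } else {
      if (length(d) != 2 || !is.numeric(d) || !all(is.finite(d)) || d[1] > d[2]) {
        rlang::abort(sprintf("numeric range for '%s' must be finite c(lo, hi)",
          attributes$name[i]), class = "pcatree_schema_error")
      }
      attributes$domain[[i]] <- as.numeric(d)
    }
  }
  target$kind <- target$kind %||% "nominal"
  if (!target$kind %in% c("nominal", "numeric")) {
    rlang::abort("target kind must be 'nominal' or 'numeric'",
      class = "pcatree_schema_error")
  }
  if (target$kind == "nominal") {
    if (length(target$labels) < 2 || anyDuplicated(target$labels)) {
      rlang::abort("target must declare >= 2 distinct labels",
        class = "pcatree_schema_error")
    }
    target$labels <- as.character(target$labels)
  } else {
    target$range <- as.numeric(target$range %||% c(-Inf, Inf))
  }
  if (target$name %in% attributes$name) {
    rlang::abort("target name collides with an attribute name",
      class = "pcatree_schema_error")
  }
  structure(list(attributes = attributes, target = target),
    class = "pca_schema")
}

#' @export
print.pca_schema <- function(x, ...) {
  cat(sprintf("<pca_schema> %d attributes (%d nominal, %d numeric)\n",
    nrow(x$attributes),
    sum(x$attributes$kind == "nominal"),
    sum(x$attributes$kind == "numeric")))
  if (x$target$kind == "nominal") {
    cat(sprintf("target: %s {%s}\n", x$target$name,
      paste(x$target$labels, collapse = ", ")))
  } else {
    cat(sprintf("target: %s (numeric)\n", x$target$name))
  }
  invisible(x)
}

schema_attr_names <- function(schema) schema$attributes$name

schema_columns <- function(schema) c(schema$attributes$name, schema$target$name)

#' Write a schema to a JSON sidecar file
#'
#' @param schema A [pca_schema()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  attrs <- lapply(seq_len(nrow(schema$attributes)), function(i) {
    list(
      name = schema$attributes$name[i],
      kind = schema$attributes$kind[i],
      domain = schema$attributes$domain[[i]]
    )
  })
  tgt <- list(name = schema$target$name, kind = schema$target$kind)
  if (schema$target$kind == "nominal") {
    tgt$labels <- schema$target$labels
  } else {
    tgt$range <- schema$target$range
  }
  jsonlite::write_json(list(attributes = attrs, target = tgt), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a schema from a JSON sidecar file
#'
#' @param path Path to a schema JSON file written by [write_schema()].
#' @return A [pca_schema()].
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path)
  attributes <- tibble::tibble(
    name = vapply(raw$attributes, function(a) a$name, character(1)),
    kind = vapply(raw$attributes, function(a) a$kind, character(1)),
    domain = lapply(raw$attributes, function(a) {
      d <- unlist(a$domain, use.names = FALSE)
      if (a$kind == "numeric") as.numeric(d) else as.character(d)
    })
  )
  tgt <- raw$target
  target <- list(name = tgt$name, kind = tgt$kind %||% "nominal")
  if (target$kind == "nominal") {
    target$labels <- unlist(tgt$labels, use.names = FALSE)
  } else {
    target$range <- as.numeric(unlist(tgt$range, use.names = FALSE))
  }
  pca_schema(attributes, target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
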