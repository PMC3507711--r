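# Internal: encode a patient table into the matrix form the C++ core uses.
#
# Numeric attributes become columns of a double matrix, nominal attributes
# 1-based level codes (schema domain order) in an integer matrix; attr_type /
# attr_col map schema order onto the two matrices.

encode_table <- function(data, schema, with_target = TRUE) {
  attrs <- schema$attributes
  is_num <- attrs$kind == "numeric"
  num_names <- attrs$name[is_num]
  nom_names <- attrs$name[!is_num]
  n <- nrow(data)

  Xnum <- matrix(0, n, length(num_names))
  for (j in seq_along(num_names)) Xnum[, j] <- as.numeric(data[[num_names[j]]])
  Xnom <- matrix(0L, n, length(nom_names))
  nom_levels <- integer(length(nom_names))
  nom_idx <- which(!is_num)
  for (j in seq_along(nom_names)) {
    dom <- attrs$domain[[nom_idx[j]]]
    Xnom[, j] <- match(as.character(data[[nom_names[j]]]), dom)
    nom_levels[j] <- length(dom)
  }

  # rank-encode numeric columns once per table: 0-based code over the sorted
  # distinct values, plus the value table (thresholds are midpoints between
  # adjacent distinct values); all trees grown from this encoding share it
  num_codes <- matrix(0L, n, length(num_names))
  num_values <- vector("list", length(num_names))
  for (j in seq_along(num_names)) {
    v <- Xnum[, j]
    uv <- sort(unique(v))
    num_values[[j]] <- uv
    num_codes[, j] <- match(v, uv) - 1L
  }

  attr_type <- ifelse(is_num, 1L, 0L)
  attr_col <- integer(nrow(attrs))
  attr_col[is_num] <- seq_along(num_names) - 1L
  attr_col[!is_num] <- seq_along(nom_names) - 1L

  y <- NULL
  if (with_target && schema$target$kind == "nominal") {
    y <- match(as.character(data[[schema$target$name]]), schema$target$labels)
  }
  list(Xnum = Xnum, Xnom = Xnom, y = y,
    num_codes = num_codes, num_values = num_values,
    attr_type = attr_type, attr_col = attr_col, nom_levels = nom_levels,
    num_names = num_names, nom_names = nom_names)
}

# Numeric ranges (max - min) per numeric attribute, for HEOM.
numeric_ranges <- function(data, schema) {
  attrs <- schema$attributes
  num_names <- attrs$name[attrs$kind == "numeric"]
  vapply(num_names, function(nm) {
    v <- as.numeric(data[[nm]])
    diff(range(v))
  }, numeric(1))
}
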