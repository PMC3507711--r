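#' Rank attributes by occurrence frequency and tree level
#'
#' Attributes appearing often, and near the root, across the members of a
#' bagged tree ensemble are the informative ones. Each internal-node
#' occurrence of an attribute contributes `1 / (1 + depth)` (root depth 0)
#' to its score; attributes never used score 0 and rank last, ties broken
#' by schema order.
#'
#' @param ensemble A `pcat_ensemble` (a single `pcat_tree` is also
#'   accepted).
#' @return A tibble ordered by descending score: `attribute`, `occurrences`,
#'   `mean_level`, `score`.
#' @export
rank_attributes <- function(ensemble) {
  members <- if (inherits(ensemble, "pcat_tree")) list(ensemble) else
    ensemble$members
  if (length(members) == 0) {
    rlang::abort("empty ensemble", class = "pcatree_tree_error")
  }
  schema <- members[[1]]$schema
  nm <- schema_attr_names(schema)
  occ <- stats::setNames(numeric(length(nm)), nm)
  lev <- stats::setNames(numeric(length(nm)), nm)
  sco <- stats::setNames(numeric(length(nm)), nm)
  for (tree in members) {
    internal <- which(tree$nodes$type != 0L)
    if (length(internal) == 0) next
    a <- tree$nodes$attr[internal]
    d <- tree$nodes$depth[internal]
    for (j in seq_along(internal)) {
      occ[a[j]] <- occ[a[j]] + 1
      lev[a[j]] <- lev[a[j]] + d[j]
      sco[a[j]] <- sco[a[j]] + 1 / (1 + d[j])
    }
  }
  out <- tibble::tibble(
    attribute = nm,
    occurrences = as.integer(occ),
    mean_level = unname(ifelse(occ > 0, lev / pmax(occ, 1), NA_real_)),
    score = unname(sco)
  )
  out[order(-out$score, seq_len(nrow(out))), ]
}

#' Association between one attribute and a nominal target
#'
#' One-way ANOVA (F-test) for numeric attributes grouped by class; Pearson's
#' chi-square test (uncorrected) for nominal attributes. Degenerate
#' groupings (a constant attribute, or fewer than two classes present)
#' return `p = 1` with the flag set.
#'
#' @param data A `patient_tbl` (or data frame plus `schema`).
#' @param attribute Attribute name.
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return A one-row tibble: `attribute`, `method`, `statistic`, `p_value`,
#'   `degenerate`.
#' @export
association_test <- function(data, attribute, schema = NULL) {
  schema <- resolve_schema(data, schema)
  if (!attribute %in% schema$attributes$name) {
    rlang::abort(sprintf("unknown attribute '%s'", attribute),
      class = "pcatree_unknown_attribute")
  }
  y <- factor(as.character(data[[schema$target$name]]),
    levels = target_labels(schema))
  kind <- schema$attributes$kind[schema$attributes$name == attribute]
  x <- data[[attribute]]
  degenerate_row <- function(method) {
    tibble::tibble(attribute = attribute, method = method,
      statistic = NA_real_, p_value = 1, degenerate = TRUE)
  }
  if (kind == "numeric") {
    x <- as.numeric(x)
    groups <- droplevels(y)
    if (nlevels(groups) < 2 || stats::sd(x) == 0 ||
        any(tapply(x, groups, length) < 2)) {
      return(degenerate_row("anova"))
    }
    fit <- stats::aov(x ~ groups)
    tab <- summary(fit)[[1]]
    tibble::tibble(attribute = attribute, method = "anova",
      statistic = tab$`F value`[1], p_value = tab$`Pr(>F)`[1],
      degenerate = FALSE)
  } else {
    tab <- table(droplevels(factor(as.character(x))), droplevels(y))
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(degenerate_row("chi_square"))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(attribute = attribute, method = "chi_square",
      statistic = unname(ct$statistic), p_value = ct$p.value,
      degenerate = FALSE)
  }
}

#' Association tests for many attributes at once
#'
#' @param data A `patient_tbl`.
#' @param attributes Attribute names (default: all).
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return A tibble with one row per attribute, ordered as given, with
#'   `neg_log10_p` appended (`Inf` when p underflows to 0).
#' @export
association_table <- function(data, attributes = NULL, schema = NULL) {
  schema <- resolve_schema(data, schema)
  attributes <- attributes %||% schema_attr_names(schema)
  out <- dplyr::bind_rows(lapply(attributes, function(a) {
    association_test(data, a, schema)
  }))
  out$neg_log10_p <- -log10(out$p_value)
  out
}

#' Monte-Carlo baseline for attribute informativeness
#'
#' Repeats `n_rand` times: draw `length(attribute_group)` attributes
#' uniformly at random from the candidate pool, run [association_test()] on
#' each, and average `-log10(p)`. The grand mean over repetitions is the
#' chance baseline against which the informative set's mean `-log10(p)` is
#' compared. By default the pool is the attributes belonging to the same
#' hourly-series families as the group (e.g. all 24 `pcadose_*hr` columns
#' for a group of PCA-dose attributes).
#'
#' @param data A `patient_tbl`.
#' @param attribute_group Character vector of informative attribute names.
#' @param n_rand Number of random draws.
#' @param seed Integer seed.
#' @param pool Candidate attribute names; `NULL` derives the hourly-family
#'   pool (falling back to all attributes when the group is not hourly).
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return A list with `baseline` (grand mean of `-log10(p)` over random
#'   draws), `informative` (the group's own mean), `draws` (a tibble with
#'   one row per repetition).
#' @export
mc_baseline <- function(data, attribute_group, n_rand = 20L, seed = 1L,
                        pool = NULL, schema = NULL) {
  schema <- resolve_schema(data, schema)
  stopifnot(length(attribute_group) >= 1, n_rand >= 1)
  if (is.null(pool)) {
    fam <- unique(sub("_[0-9]+hr$", "", attribute_group))
    hourly <- grepl("_[0-9]+hr$", attribute_group)
    pool <- if (all(hourly)) {
      unlist(lapply(fam, hourly_names))
    } else {
      schema_attr_names(schema)
    }
    pool <- intersect(pool, schema_attr_names(schema))
  }
  if (length(pool) < length(attribute_group)) {
    rlang::abort("candidate pool smaller than the attribute group",
      class = "pcatree_analysis_error")
  }
  mean_nlp <- function(attrs) {
    mean(association_table(data, attrs, schema)$neg_log10_p)
  }
  set.seed(seed)
  draws <- dplyr::bind_rows(lapply(seq_len(n_rand), function(i) {
    drawn <- sample(pool, length(attribute_group))
    tibble::tibble(draw = i, attributes = paste(drawn, collapse = ","),
      mean_neg_log10_p = mean_nlp(drawn))
  }))
  list(
    baseline = mean(draws$mean_neg_log10_p),
    informative = mean_nlp(attribute_group),
    draws = draws
  )
}
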