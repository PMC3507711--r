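#' Heterogeneous Euclidean-Overlap (HEOM) distance between two rows
#'
#' Per-attribute contribution: 0/1 overlap for nominal attributes,
#' `|a - b| / range` for numeric attributes with the range taken from a
#' training table (a zero range contributes 0). The distance is the square
#' root of the summed squared contributions; it is symmetric and zero iff
#' the rows agree on every attribute with positive range.
#'
#' @param row_a,row_b One-row data frames (or lists) with the schema's
#'   attribute columns.
#' @param schema A [pca_schema()].
#' @param ranges Named numeric vector of per-attribute ranges for the numeric
#'   attributes (as produced from a training table); defaults to the numeric
#'   domains declared in the schema.
#' @return A non-negative scalar.
#' @export
heom_distance <- function(row_a, row_b, schema, ranges = NULL) {
  attrs <- schema$attributes
  if (is.null(ranges)) {
    num <- attrs$kind == "numeric"
    ranges <- stats::setNames(
      vapply(attrs$domain[num], function(d) d[2] - d[1], numeric(1)),
      attrs$name[num])
  }
  s <- 0
  for (i in seq_len(nrow(attrs))) {
    nm <- attrs$name[i]
    if (attrs$kind[i] == "nominal") {
      s <- s + as.numeric(as.character(row_a[[nm]]) != as.character(row_b[[nm]]))
    } else {
      r <- ranges[[nm]]
      if (r > 0) {
        s <- s + ((as.numeric(row_a[[nm]]) - as.numeric(row_b[[nm]])) / r)^2
      }
    }
  }
  sqrt(s)
}

#' Identify "dirty" majority examples near the minority class
#'
#' For every minority-class row, the k nearest other rows (under HEOM, with
#' numeric ranges taken from `data`) are located; ties at the k-th distance
#' are all included. Any majority-class row appearing in any minority row's
#' neighbour list is marked dirty. The scan is single-pass: the dirty set is
#' computed once over the table as given, not iterated to a fixpoint.
#'
#' @param data A `patient_tbl` (or data frame plus `schema`) with a nominal
#'   target and both classes present.
#' @param minority_label The minority class label. `NULL` selects the rarest
#'   class.
#' @param k Number of nearest neighbours (`1 <= k <= n - 1`).
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return An object of class `pcat_cleaning`: a list with `minority_label`,
#'   `neighbor_lists` (a tibble with `minority_row_id`, `neighbor_row_id`,
#'   `distance`, `neighbor_class`), `dirty_ids` (original `.row_id`s of the
#'   removed majority rows), `k`, `ratio_before` and `ratio_after` (each
#'   `c(majority, minority)` counts).
#' @export
find_dirty <- function(data, minority_label = NULL, k = 3L, schema = NULL) {
  scan <- knn_scan(data, minority_label, k, schema)
  report_from_scan(scan, k)
}

# One HEOM k-NN pass at `k`; reports for any smaller k can be derived from
# it without re-scanning (used by select_k over a candidate grid).
knn_scan <- function(data, minority_label = NULL, k = 3L, schema = NULL) {
  schema <- resolve_schema(data, schema)
  y <- as.character(data[[schema$target$name]])
  if (length(unique(y)) < 2) {
    rlang::abort("both classes must be present", class = "pcatree_imbalance_error")
  }
  if (is.null(minority_label)) {
    minority_label <- names(which.min(table(y)))
  }
  minority_label <- as.character(minority_label)
  if (!minority_label %in% y) {
    rlang::abort(sprintf("minority label '%s' not present in the target",
      minority_label), class = "pcatree_imbalance_error")
  }
  n <- nrow(data)
  stopifnot(k >= 1, k <= n - 1)
  row_id <- data$.row_id %||% (seq_len(n) - 1L)
  is_min <- y == minority_label
  enc <- encode_table(data, schema, with_target = FALSE)
  ranges <- apply(enc$Xnum, 2, function(v) diff(range(v)))
  if (ncol(enc$Xnum) == 0) ranges <- numeric(0)
  res <- knn_dirty_cpp(enc$Xnum, enc$Xnom, as.numeric(ranges), is_min,
    as.integer(k), 1e-12)
  list(res = res, y = y, row_id = row_id, k_scan = as.integer(k),
    minority_label = minority_label,
    n_min = sum(is_min), n_maj = n - sum(is_min))
}

# Build a CleaningReport at neighbour count k <= scan$k_scan.
report_from_scan <- function(scan, k) {
  k <- as.integer(k)
  stopifnot(k >= 1, k <= scan$k_scan)
  res <- scan$res
  y <- scan$y
  row_id <- scan$row_id
  is_min_lab <- function(pos) y[pos] == scan$minority_label
  pieces <- lapply(seq_along(res$minority_pos), function(i) {
    pos <- res$neighbor_idx[[i]]
    dist <- res$neighbor_dist[[i]]
    if (k < scan$k_scan && length(pos) > k) {
      # lists are distance-sorted; keep rank <= k plus ties at the k-th
      keep <- dist <= dist[k] + 1e-12
      pos <- pos[keep]
      dist <- dist[keep]
    }
    tibble::tibble(
      minority_row_id = row_id[res$minority_pos[i]],
      neighbor_row_id = row_id[pos],
      distance = dist,
      neighbor_class = y[pos])
  })
  nbr <- dplyr::bind_rows(pieces)
  dirty_ids <- sort(unique(
    nbr$neighbor_row_id[nbr$neighbor_class != scan$minority_label]))
  structure(list(
    minority_label = scan$minority_label,
    neighbor_lists = nbr,
    dirty_ids = dirty_ids,
    k = k,
    ratio_before = c(majority = scan$n_maj, minority = scan$n_min),
    ratio_after = c(majority = scan$n_maj - length(dirty_ids),
      minority = scan$n_min)
  ), class = "pcat_cleaning")
}

#' @export
print.pcat_cleaning <- function(x, ...) {
  cat(sprintf(
    "<pcat_cleaning> k = %d, minority '%s'; removed %d dirty majority rows\n",
    x$k, x$minority_label, length(x$dirty_ids)))
  cat(sprintf("  majority:minority  %d:%d -> %d:%d\n",
    x$ratio_before[1], x$ratio_before[2], x$ratio_after[1], x$ratio_after[2]))
  invisible(x)
}

#' @method tidy pcat_cleaning
#' @export
tidy.pcat_cleaning <- function(x, ...) x$neighbor_lists

#' @method glance pcat_cleaning
#' @export
glance.pcat_cleaning <- function(x, ...) {
  tibble::tibble(k = x$k, minority_label = x$minority_label,
    n_dirty = length(x$dirty_ids),
    majority_before = x$ratio_before[["majority"]],
    minority_before = x$ratio_before[["minority"]],
    majority_after = x$ratio_after[["majority"]],
    minority_after = x$ratio_after[["minority"]])
}

#' Remove dirty majority examples from a training table
#'
#' Runs [find_dirty()] and drops the dirty rows, preserving original row
#' order and every minority row. On data emulating the readjustment task's
#' sparse 81:19 geometry this moves the class ratio toward the mid-60s:30s;
#' the exact value is data-dependent.
#'
#' @inheritParams find_dirty
#' @return A list with elements `table` (the cleaned `patient_tbl`) and
#'   `report` (the `pcat_cleaning`).
#' @export
clean_training_set <- function(data, minority_label = NULL, k = 3L,
                               schema = NULL) {
  schema <- resolve_schema(data, schema)
  report <- find_dirty(data, minority_label, k, schema)
  row_id <- data$.row_id %||% (seq_len(nrow(data)) - 1L)
  keep <- !(row_id %in% report$dirty_ids)
  cleaned <- data[keep, , drop = FALSE]
  attr(cleaned, "pca_schema") <- schema
  if (!inherits(cleaned, "patient_tbl")) {
    class(cleaned) <- c("patient_tbl", class(cleaned))
  }
  list(table = cleaned, report = report)
}

#' Serialise a cleaning report to JSON
#'
#' @param report A `pcat_cleaning`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(list(
    minority_label = report$minority_label,
    k = report$k,
    dirty_ids = report$dirty_ids,
    ratio_before = as.list(report$ratio_before),
    ratio_after = as.list(report$ratio_after),
    neighbor_lists = report$neighbor_lists
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Select k for dirty-example cleaning by validation
#'
#' For each candidate k and each of `validation_repeats` stratified random
#' splits of the training data, the first subset is cleaned at that k and
#' used to train a classifier, which is scored on the second (never cleaned)
#' subset by minority F-score. The candidate with the highest mean score
#' wins; ties go to the smallest k.
#'
#' @param data A `patient_tbl` with a nominal target.
#' @param k_candidates Integer vector of candidate neighbour counts.
#' @param minority_label Minority class label (`NULL`: rarest class).
#' @param validation_fraction Fraction of rows in the training subset.
#' @param validation_repeats Number of random splits per candidate.
#' @param learner A learner spec: `list(fit = function(data, schema) model)`
#'   where `predict(model, newdata)` yields labels. Defaults to a single
#'   pruned tree.
#' @param seed Integer seed for the splits.
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return A list with `k` (the selected value) and `scores` (a tibble with
#'   one row per candidate x repeat).
#' @export
select_k <- function(data, k_candidates = c(1L, 3L, 5L, 7L, 9L),
                     minority_label = NULL, validation_fraction = 2 / 3,
                     validation_repeats = 5L, learner = NULL, seed = 1L,
                     schema = NULL) {
  schema <- resolve_schema(data, schema)
  stopifnot(length(k_candidates) >= 1)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (length(k_candidates) == 1) {
    return(list(k = k_candidates, scores = tibble::tibble(
      k = k_candidates, repeat_id = NA_integer_, f_score = NA_real_)))
  }
  y <- as.character(data[[schema$target$name]])
  if (is.null(minority_label)) minority_label <- names(which.min(table(y)))
  labels <- target_labels(schema)
  if (is.null(learner)) {
    learner <- list(fit = function(d, s) prune_tree(grow_tree(d, schema = s)))
  }
  n <- nrow(data)
  splits <- lapply(seq_len(validation_repeats), function(r) {
    set.seed(seed + r)
    for (try in 1:25) {
      train_idx <- sort(unlist(lapply(split(seq_len(n), y), function(ix) {
        sample(ix, max(1, round(length(ix) * validation_fraction)))
      }), use.names = FALSE))
      val_idx <- setdiff(seq_len(n), train_idx)
      if (length(unique(y[train_idx])) >= 2 && length(unique(y[val_idx])) >= 2) {
        return(list(train = train_idx, val = val_idx))
      }
    }
    rlang::abort("could not build a split with both classes in each subset",
      class = "pcatree_imbalance_error")
  })
  # one neighbour scan per split at the largest candidate serves every k
  scores <- dplyr::bind_rows(lapply(seq_len(validation_repeats), function(r) {
    sp <- splits[[r]]
    train <- data[sp$train, , drop = FALSE]
    attr(train, "pca_schema") <- schema
    val <- data[sp$val, , drop = FALSE]
    scan <- knn_scan(train, minority_label, max(k_candidates), schema)
    dplyr::bind_rows(lapply(k_candidates, function(kk) {
      report <- report_from_scan(scan, kk)
      keep <- !(train$.row_id %in% report$dirty_ids)
      cleaned <- train[keep, , drop = FALSE]
      attr(cleaned, "pca_schema") <- schema
      model <- learner$fit(cleaned, schema)
      pred <- predict(model, val)
      cm <- confusion_matrix(y[sp$val], pred, labels)
      tibble::tibble(k = kk, repeat_id = r,
        f_score = minority_f_score(cm, minority_label))
    }))
  }))
  means <- scores |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_f = mean(.data$f_score), .groups = "drop")
  best <- means$k[which(means$mean_f == max(means$mean_f))]
  list(k = min(best), scores = scores)
}

# F-score of one class treated as the positive class, from a K x K matrix
# (rows = predicted, columns = real).
minority_f_score <- function(cm, positive) {
  bm <- binary_metrics(collapse_to_binary(cm, positive), positive = "pos")
  bm$f_score
}

# Collapse a K x K confusion matrix to 2 x 2 (pos = `positive`, neg = rest).
collapse_to_binary <- function(cm, positive) {
  labels <- colnames(cm)
  pos <- labels == positive
  m <- matrix(c(sum(cm[pos, pos]), sum(cm[pos, !pos]),
                sum(cm[!pos, pos]), sum(cm[!pos, !pos])),
    2, 2, byrow = TRUE,
    dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m
}

#' Random under-sampling of the majority class
#'
#' Majority rows are sampled without replacement until each class matches
#' the size of the smallest class; minority rows are untouched. Row order is
#' preserved.
#'
#' @param data A `patient_tbl` with a nominal target and >= 2 classes.
#' @param seed Integer seed.
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return A `patient_tbl` with exactly balanced classes.
#' @export
undersample <- function(data, seed = 1L, schema = NULL) {
  schema <- resolve_schema(data, schema)
  y <- as.character(data[[schema$target$name]])
  tab <- table(y)
  if (length(tab) < 2) {
    rlang::abort("both classes must be present", class = "pcatree_imbalance_error")
  }
  n_min <- min(tab)
  set.seed(seed)
  keep <- sort(unlist(lapply(split(seq_len(nrow(data)), y), function(ix) {
    if (length(ix) > n_min) sample(ix, n_min) else ix
  }), use.names = FALSE))
  out <- data[keep, , drop = FALSE]
  attr(out, "pca_schema") <- schema
  out
}

#' Random over-sampling of the minority class with replications
#'
#' Minority rows are replicated by sampling with replacement until each
#' class matches the largest class. Replicates are value-identical copies of
#' original minority rows, appended after the originals with fresh row ids.
#'
#' @inheritParams undersample
#' @return A `patient_tbl` with exactly balanced classes.
#' @export
oversample <- function(data, seed = 1L, schema = NULL) {
  schema <- resolve_schema(data, schema)
  y <- as.character(data[[schema$target$name]])
  tab <- table(y)
  if (length(tab) < 2) {
    rlang::abort("both classes must be present", class = "pcatree_imbalance_error")
  }
  n_maj <- max(tab)
  set.seed(seed)
  extra_idx <- unlist(lapply(split(seq_len(nrow(data)), y), function(ix) {
    need <- n_maj - length(ix)
    if (need > 0) sample(ix, need, replace = TRUE) else integer(0)
  }), use.names = FALSE)
  if (length(extra_idx) == 0) return(data)
  extra <- data[extra_idx, , drop = FALSE]
  next_id <- max(data$.row_id %||% (seq_len(nrow(data)) - 1L)) + 1L
  extra$.row_id <- seq.int(next_id, length.out = nrow(extra))
  out <- dplyr::bind_rows(data, extra)
  attr(out, "pca_schema") <- schema
  if (!inherits(out, "patient_tbl")) class(out) <- c("patient_tbl", class(out))
  out
}
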