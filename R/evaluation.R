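#' Confusion matrix with rows = predicted, columns = real
#'
#' @param real,predicted Class label vectors of equal length.
#' @param labels Ordered class labels (defaults to the sorted union).
#' @return A K x K integer matrix; rows are predicted classes, columns real
#'   classes.
#' @export
confusion_matrix <- function(real, predicted, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(real, predicted)))
  pred_f <- factor(as.character(predicted), levels = labels)
  real_f <- factor(as.character(real), levels = labels)
  m <- table(pred_f, real_f)
  out <- matrix(as.integer(m), nrow = length(labels),
    dimnames = list(predicted = labels, real = labels))
  out
}

#' Per-class sensitivity and precision plus overall accuracy
#'
#' For class c (with rows of the matrix predicted, columns real):
#' sensitivity = correct c / real c (a column sum), precision = correct c /
#' predicted c (a row sum), accuracy = trace / total. A zero denominator
#' yields 0 with its flag set.
#'
#' @param matrix A K x K confusion matrix from [confusion_matrix()].
#' @return A list of class `pcat_multiclass_metrics`: `per_class` (a tibble
#'   with `class`, `sensitivity`, `precision`, `sensitivity_undefined`,
#'   `precision_undefined`) and `accuracy`.
#' @export
multiclass_metrics <- function(matrix) {
  stopifnot(nrow(matrix) == ncol(matrix))
  labels <- colnames(matrix) %||% as.character(seq_len(ncol(matrix)))
  safe_div <- function(num, den) {
    list(value = ifelse(den == 0, 0, num / den), undefined = den == 0)
  }
  sens <- safe_div(diag(matrix), colSums(matrix))
  prec <- safe_div(diag(matrix), rowSums(matrix))
  total <- sum(matrix)
  structure(list(
    per_class = tibble::tibble(
      class = labels,
      sensitivity = as.numeric(sens$value),
      precision = as.numeric(prec$value),
      sensitivity_undefined = sens$undefined,
      precision_undefined = prec$undefined
    ),
    accuracy = if (total == 0) 0 else sum(diag(matrix)) / total
  ), class = "pcat_multiclass_metrics")
}

#' @method tidy pcat_multiclass_metrics
#' @export
tidy.pcat_multiclass_metrics <- function(x, ...) x$per_class

#' @method glance pcat_multiclass_metrics
#' @export
glance.pcat_multiclass_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy)
}

#' Binary metrics: TPR, FPR, precision, F-score
#'
#' TPR = TP/(TP+FN), FPR = FP/(FP+TN), precision = TP/(TP+FP), F-score =
#' 2*TPR*precision/(TPR+precision). Any ratio with a zero denominator is
#' reported as 0 with its flag set.
#'
#' @param matrix A 2 x 2 confusion matrix (rows predicted, columns real).
#' @param positive The positive-class label (defaults to the first row
#'   name).
#' @return A one-row tibble with `TP`, `FP`, `TN`, `FN`, `TPR`, `FPR`,
#'   `precision`, `f_score` and `*_undefined` flags.
#' @export
binary_metrics <- function(matrix, positive = NULL) {
  stopifnot(nrow(matrix) == 2, ncol(matrix) == 2)
  labels <- colnames(matrix) %||% c("pos", "neg")
  if (is.null(positive)) positive <- labels[1]
  p <- which(labels == positive)
  n <- which(labels != positive)
  TP <- matrix[p, p]; FP <- matrix[p, n]
  FN <- matrix[n, p]; TN <- matrix[n, n]
  safe <- function(num, den) if (den == 0) c(0, 1) else c(num / den, 0)
  tpr <- safe(TP, TP + FN)
  fpr <- safe(FP, FP + TN)
  prec <- safe(TP, TP + FP)
  f <- safe(2 * tpr[1] * prec[1], tpr[1] + prec[1])
  tibble::tibble(
    TP = as.integer(TP), FP = as.integer(FP),
    TN = as.integer(TN), FN = as.integer(FN),
    TPR = tpr[1], FPR = fpr[1], precision = prec[1], f_score = f[1],
    TPR_undefined = tpr[2] == 1, FPR_undefined = fpr[2] == 1,
    precision_undefined = prec[2] == 1, f_score_undefined = f[2] == 1
  )
}

#' Build a stratified repeated cross-validation plan
#'
#' Within each repeat, each class's rows are shuffled and dealt round-robin
#' across folds (with a rotating starting fold so fold sizes stay within one
#' row of each other), so per-fold class counts are within +/- 1 row of the
#' full-table proportions.
#'
#' @param data A `patient_tbl`.
#' @param n_folds Number of folds (every class must have at least this many
#'   rows).
#' @param repeats Number of independent repetitions.
#' @param seed Integer seed.
#' @param class Optional class vector used for stratification (defaults to
#'   the nominal target column; supply provisional labels when the target is
#'   continuous).
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return A `pcat_cvplan`: a tibble with columns `repeat_id`, `.row_id`,
#'   `fold`, carrying `n_folds`, `repeats` and `seed` attributes.
#' @export
make_stratified_folds <- function(data, n_folds = 10L, repeats = 1L,
                                  seed = 1L, class = NULL, schema = NULL) {
  schema <- resolve_schema(data, schema)
  if (is.null(class)) {
    class <- as.character(data[[schema$target$name]])
  }
  stopifnot(length(class) == nrow(data))
  tab <- table(class)
  if (any(tab < n_folds)) {
    rlang::abort(sprintf(
      "class '%s' has %d rows, fewer than n_folds = %d",
      names(tab)[which.min(tab)], min(tab), n_folds),
      class = "pcatree_cv_error")
  }
  row_id <- data$.row_id %||% (seq_len(nrow(data)) - 1L)
  plans <- lapply(seq_len(repeats), function(r) {
    set.seed(seed + 131 * r)
    offset <- 0L
    assign <- integer(nrow(data))
    for (cl in names(tab)) {
      ix <- which(class == cl)
      ix <- ix[sample.int(length(ix))]
      assign[ix] <- ((offset + seq_along(ix) - 1L) %% n_folds) + 1L
      offset <- (offset + length(ix)) %% n_folds
    }
    tibble::tibble(repeat_id = r, .row_id = row_id, fold = assign)
  })
  out <- dplyr::bind_rows(plans)
  attr(out, "n_folds") <- as.integer(n_folds)
  attr(out, "repeats") <- as.integer(repeats)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "stratified") <- TRUE
  class(out) <- c("pcat_cvplan", class(out))
  out
}

#' Learner specifications for [run_cv()]
#'
#' Each factory returns a `list(fit, name)` where
#' `fit(data, schema, seed)` yields a fitted model answering
#' `predict(model, newdata)`.
#'
#' @param params A [tree_params()].
#' @param prune Prune trees after growing.
#' @param M Ensemble size.
#' @param bootstrap Passed to [bagging_fit()].
#' @return A learner spec list.
#' @export
learner_tree <- function(params = tree_params(), prune = TRUE) {
  list(name = "tree", fit = function(data, schema, seed = 1L) {
    set.seed(seed)
    tr <- grow_tree(data, params, schema)
    if (prune) prune_tree(tr) else tr
  })
}

#' @rdname learner_tree
#' @export
learner_bagging <- function(M = 200L, params = tree_params(), prune = TRUE,
                            bootstrap = TRUE) {
  list(name = "bagging", fit = function(data, schema, seed = 1L) {
    bagging_fit(data, M, params, seed = seed, schema = schema,
      bootstrap = bootstrap, prune = prune)
  })
}

#' @rdname learner_tree
#' @export
learner_adaboost <- function(M = 200L, params = tree_params(), prune = TRUE) {
  list(name = "adaboost", fit = function(data, schema, seed = 1L) {
    adaboost_fit(data, M, params, seed = seed, schema = schema, prune = prune)
  })
}

#' Run a prediction pipeline under a cross-validation plan
#'
#' For each repeat x fold, the training folds pass through the configured
#' stages in order — target discretization (fitted on training rows only),
#' dirty-example cleaning (fixed `k` or validation-selected from `k_grid`),
#' under/over-sampling — and the learner is fitted; the test fold is never
#' altered and keeps the original class distribution. Per-fold confusion
#' matrices are returned along with the pooled matrix.
#'
#' @param data A `patient_tbl`.
#' @param pipeline A list with elements:
#'   * `discretize`: `NULL` or `list(K, labels)` for a continuous target;
#'   * `cleaning`: `NULL` or `list(k = ...)` / `list(k_grid = c(...),
#'     validation_repeats = 5)`, optionally `minority_label`;
#'   * `sampling`: `"none"`, `"under"` or `"over"`;
#'   * `learner`: a spec from [learner_tree()], [learner_bagging()] or
#'     [learner_adaboost()].
#' @param plan A `pcat_cvplan` built on `data`.
#' @param seed Integer base seed for per-fold learner fits and sampling.
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return An object of class `pcat_cv`: `folds` (a tibble with `repeat_id`,
#'   `fold`, `n_test`, `confusion` list column, `selected_k`, `train_ids`
#'   and `test_ids` list columns, cleaning `ratio_after` bookkeeping),
#'   `pooled` (summed confusion matrix), `labels`.
#' @export
run_cv <- function(data, pipeline, plan, seed = 1L, schema = NULL) {
  schema <- resolve_schema(data, schema)
  if (is.null(pipeline$learner)) {
    rlang::abort("pipeline$learner is required", class = "pcatree_cv_error")
  }
  sampling <- pipeline$sampling %||% "none"
  stopifnot(sampling %in% c("none", "under", "over"))
  if (is.null(pipeline$discretize) && schema$target$kind != "nominal") {
    rlang::abort("continuous target requires pipeline$discretize",
      class = "pcatree_cv_error")
  }
  target <- schema$target$name
  row_id <- data$.row_id
  n_folds <- attr(plan, "n_folds")
  repeats <- attr(plan, "repeats")

  cls_schema <- if (is.null(pipeline$discretize)) schema else {
    labels <- pipeline$discretize$labels %||%
      (if ((pipeline$discretize$K %||% 3L) == 3) c("low", "medium", "high")
       else paste0("c", seq_len(pipeline$discretize$K)))
    pca_schema(schema$attributes,
      list(name = target, kind = "nominal", labels = labels))
  }
  labels <- target_labels(cls_schema)

  results <- list()
  for (r in seq_len(repeats)) {
    fold_of <- plan[plan$repeat_id == r, ]
    for (f in seq_len(n_folds)) {
      test_ids <- fold_of$.row_id[fold_of$fold == f]
      in_test <- row_id %in% test_ids
      train <- data[!in_test, , drop = FALSE]
      test <- data[in_test, , drop = FALSE]
      attr(train, "pca_schema") <- schema
      fold_seed <- seed + 977L * r + 13L * f

      if (!is.null(pipeline$discretize)) {
        dz <- fit_equal_deviation_intervals(train[[target]],
          K = pipeline$discretize$K %||% 3L, labels = labels)
        train[[target]] <- apply_discretization(dz, train[[target]])
        test_real <- apply_discretization(dz, test[[target]])
      } else {
        test_real <- as.character(test[[target]])
      }
      attr(train, "pca_schema") <- cls_schema

      selected_k <- NA_integer_
      ratio_after <- NULL
      if (!is.null(pipeline$cleaning)) {
        cl <- pipeline$cleaning
        kk <- cl$k
        if (!is.null(cl$k_grid)) {
          sk <- select_k(train, k_candidates = cl$k_grid,
            minority_label = cl$minority_label,
            validation_repeats = cl$validation_repeats %||% 5L,
            learner = cl$selection_learner, seed = fold_seed,
            schema = cls_schema)
          kk <- sk$k
        }
        selected_k <- as.integer(kk)
        cleaned <- clean_training_set(train, cl$minority_label, kk, cls_schema)
        train <- cleaned$table
        ratio_after <- cleaned$report$ratio_after
      }
      if (sampling == "under") {
        train <- undersample(train, seed = fold_seed, schema = cls_schema)
      } else if (sampling == "over") {
        train <- oversample(train, seed = fold_seed, schema = cls_schema)
      }

      model <- pipeline$learner$fit(train, cls_schema, fold_seed)
      pred <- predict(model, test)
      cm <- confusion_matrix(test_real, pred, labels)
      results[[length(results) + 1L]] <- tibble::tibble(
        repeat_id = r, fold = f, n_test = nrow(test),
        confusion = list(cm),
        selected_k = selected_k,
        majority_after = if (is.null(ratio_after)) NA_real_ else
          ratio_after[["majority"]],
        minority_after = if (is.null(ratio_after)) NA_real_ else
          ratio_after[["minority"]],
        train_ids = list(sort(train$.row_id)),
        test_ids = list(sort(test$.row_id))
      )
    }
  }
  folds <- dplyr::bind_rows(results)
  pooled <- Reduce(`+`, folds$confusion)
  structure(list(folds = folds, pooled = pooled, labels = labels,
    learner = pipeline$learner$name %||% "custom"),
    class = "pcat_cv")
}

#' @export
print.pcat_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pcat_cv> %s: %d folds, mean accuracy %.3f (pooled %.3f)\n",
    x$learner, nrow(x$folds), g$mean_accuracy, g$pooled_accuracy))
  invisible(x)
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x A `pcat_cv`.
#' @param positive Optional positive-class label; when given (or when the
#'   task is binary, defaulting to the last label) binary metrics are
#'   appended per fold.
#' @param ... Unused.
#' @return A tibble with one row per repeat x fold: `accuracy`, per-class
#'   sensitivities/precisions (wide, `sens_<class>` / `prec_<class>`), and
#'   for binary tasks `TPR`, `FPR`, `precision`, `f_score`.
#' @method tidy pcat_cv
#' @export
tidy.pcat_cv <- function(x, positive = NULL, ...) {
  if (is.null(positive) && length(x$labels) == 2) {
    positive <- x$labels[2]
  }
  dplyr::bind_cols(
    x$folds[, c("repeat_id", "fold", "n_test", "selected_k")],
    dplyr::bind_rows(lapply(x$folds$confusion, function(cm) {
      mm <- multiclass_metrics(cm)
      wide <- tibble::tibble(accuracy = mm$accuracy)
      for (i in seq_len(nrow(mm$per_class))) {
        wide[[paste0("sens_", mm$per_class$class[i])]] <- mm$per_class$sensitivity[i]
        wide[[paste0("prec_", mm$per_class$class[i])]] <- mm$per_class$precision[i]
      }
      if (!is.null(positive)) {
        bm <- binary_metrics(collapse_to_binary(cm, positive), positive = "pos")
        wide <- dplyr::bind_cols(wide,
          bm[, c("TPR", "FPR", "precision", "f_score")])
      }
      wide
    }))
  )
}

#' @method glance pcat_cv
#' @export
glance.pcat_cv <- function(x, ...) {
  per_fold <- tidy(x)
  out <- tibble::tibble(
    n_folds = nrow(x$folds),
    mean_accuracy = mean(per_fold$accuracy),
    pooled_accuracy = multiclass_metrics(x$pooled)$accuracy
  )
  if ("f_score" %in% names(per_fold)) {
    out$mean_f_score <- mean(per_fold$f_score)
    out$mean_TPR <- mean(per_fold$TPR)
  }
  out
}

#' Paired t-tests against a baseline, Bonferroni-corrected
#'
#' Two-sided paired t-test of the baseline's scores against each
#' competitor's, with the adjusted p-value `min(1, p * n_comparisons)`.
#' Zero-variance differences yield `t = 0, p = 1` when the mean difference
#' is 0, and are reported as a degenerate exact win (`p = 0`) otherwise.
#'
#' @param scores_baseline Numeric vector (one score per CV iteration).
#' @param scores_others A list of equal-length numeric vectors.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return A tibble with one row per comparison: `comparison`, `t`,
#'   `df`, `p_value`, `p_adjusted`, `significant`, `mean_difference`.
#' @export
paired_t_bonferroni <- function(scores_baseline, scores_others, alpha = 0.05) {
  if (!is.list(scores_others)) scores_others <- list(scores_others)
  m <- length(scores_others)
  nm <- names(scores_others) %||% paste0("comparison_", seq_len(m))
  rows <- lapply(seq_len(m), function(i) {
    other <- scores_others[[i]]
    stopifnot(length(other) == length(scores_baseline))
    d <- scores_baseline - other
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        tibble::tibble(comparison = nm[i], t = 0, df = length(d) - 1,
          p_value = 1, mean_difference = 0)
      } else {
        tibble::tibble(comparison = nm[i], t = sign(mean(d)) * Inf,
          df = length(d) - 1, p_value = 0, mean_difference = mean(d))
      }
    } else {
      tt <- stats::t.test(scores_baseline, other, paired = TRUE)
      tibble::tibble(comparison = nm[i], t = unname(tt$statistic),
        df = unname(tt$parameter), p_value = tt$p.value,
        mean_difference = unname(tt$estimate))
    }
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * m)
  out$significant <- out$p_adjusted < alpha
  out[, c("comparison", "t", "df", "p_value", "p_adjusted", "significant",
    "mean_difference")]
}
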