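#' Run a full, reproducible PCA prediction experiment
#'
#' Composes the whole control flow end to end: obtain data (from CSV+schema
#' files or the synthetic generator), build a stratified CV plan, run the
#' configured pipeline (discretization for the consumption task, optional
#' cleaning/sampling for the readjustment task, tree or ensemble learner),
#' and write a result bundle: per-fold metrics CSV, a JSON summary, cleaning
#' bookkeeping, an attribute ranking, and a plain-text log recording every
#' parameter and seed. Identical configs produce identical metric files.
#'
#' @param config A list (e.g. parsed from YAML/JSON) with elements:
#'   * `task`: `"consumption"` or `"readjustment"`;
#'   * `data`: either `list(csv = , schema = )` or a generator spec
#'     `list(n_patients = , proportions = , readjust_rate = , seed = )`;
#'   * `discretizer`: `list(K = 3, labels = c("low","medium","high"))`
#'     (consumption task);
#'   * `imbalance`: `NULL`, or `list(k = 3)` / `list(k_grid = c(1,3,5,7,9))`,
#'     plus optional `sampling` in `"none"/"under"/"over"`;
#'   * `learner`: `list(method = "bagging"|"adaboost"|"tree", M = 200,
#'     min_leaf = 2, pruning_cf = 0.25)`;
#'   * `cv`: `list(n_folds = 10, repeats = 10)`;
#'   * `seed`: mandatory integer;
#'   * `output_dir`: where the bundle is written.
#' @return Invisibly, a list with the `pcat_cv` result, the attribute
#'   ranking, and the output paths.
#' @export
run_experiment <- function(config) {
  cfg <- config
  if (is.null(cfg$seed)) {
    rlang::abort("config$seed is mandatory", class = "pcatree_config_error")
  }
  task <- match.arg(cfg$task, c("consumption", "readjustment"))
  out_dir <- cfg$output_dir %||% "pcatree_results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(fmt, ...) {
    writeLines(sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      sprintf(fmt, ...)), log_con)
  }
  logline("task=%s seed=%d", task, cfg$seed)

  # ---- data ----------------------------------------------------------------
  stage <- "data"
  result <- tryCatch({
    if (!is.null(cfg$data$csv)) {
      data <- read_patient_table(cfg$data$csv, cfg$data$schema)
      logline("loaded %d rows from %s", nrow(data), cfg$data$csv)
    } else {
      gseed <- cfg$data$seed %||% cfg$seed
      data <- gen_pca_cohort(
        n_patients = cfg$data$n_patients %||% 1099L,
        consumption_class_proportions = cfg$data$proportions %||%
          c(0.363, 0.501, 0.136),
        seed = gseed)
      if (task == "readjustment") {
        data <- gen_readjust_labels(data,
          readjust_positive_rate = cfg$data$readjust_rate %||% 0.19,
          seed = gseed + 1L)
      }
      logline("generated synthetic cohort: %d rows, generator seed %d",
        nrow(data), gseed)
    }
    schema <- table_schema(data)

    # ---- pipeline ----------------------------------------------------------
    stage <- "pipeline"
    lp <- cfg$learner %||% list()
    params <- tree_params(
      min_leaf = lp$min_leaf %||% 2L,
      max_depth = lp$max_depth %||% Inf,
      pruning_cf = lp$pruning_cf %||% 0.25,
      attribute_subsample = lp$attribute_subsample %||% "all")
    learner <- switch(lp$method %||% "bagging",
      bagging = learner_bagging(M = lp$M %||% 200L, params = params),
      adaboost = learner_adaboost(M = lp$M %||% 200L, params = params),
      tree = learner_tree(params = params),
      rlang::abort(sprintf("unknown learner method '%s'", lp$method),
        class = "pcatree_config_error"))
    pipeline <- list(learner = learner,
      sampling = cfg$imbalance$sampling %||% "none")
    if (task == "consumption" && schema$target$kind == "numeric") {
      pipeline$discretize <- list(K = cfg$discretizer$K %||% 3L,
        labels = cfg$discretizer$labels %||% c("low", "medium", "high"))
    }
    if (!is.null(cfg$imbalance) &&
        (!is.null(cfg$imbalance$k) || !is.null(cfg$imbalance$k_grid))) {
      pipeline$cleaning <- list(k = cfg$imbalance$k,
        k_grid = cfg$imbalance$k_grid,
        minority_label = cfg$imbalance$minority_label,
        validation_repeats = cfg$imbalance$validation_repeats %||% 5L)
    }

    # ---- folds -------------------------------------------------------------
    stage <- "cv_plan"
    n_folds <- cfg$cv$n_folds %||% 10L
    repeats <- cfg$cv$repeats %||% 10L
    strat_class <- if (!is.null(pipeline$discretize)) {
      # provisional whole-table labels, used only to balance folds
      dz0 <- fit_equal_deviation_intervals(data[[schema$target$name]],
        K = pipeline$discretize$K, labels = pipeline$discretize$labels)
      apply_discretization(dz0, data[[schema$target$name]])
    } else {
      NULL
    }
    plan <- make_stratified_folds(data, n_folds = n_folds, repeats = repeats,
      seed = cfg$seed, class = strat_class)
    logline("plan: %d folds x %d repeats", n_folds, repeats)

    # ---- run ---------------------------------------------------------------
    stage <- "cv_run"
    cv <- run_cv(data, pipeline, plan, seed = cfg$seed)
    per_fold <- tidy(cv)
    overall <- glance(cv)
    logline("mean accuracy %.4f", overall$mean_accuracy)

    # ---- attribute ranking on a full-data fit ------------------------------
    stage <- "ranking"
    rank_data <- data
    rank_schema <- schema
    if (!is.null(pipeline$discretize)) {
      dz0 <- fit_equal_deviation_intervals(data[[schema$target$name]],
        K = pipeline$discretize$K, labels = pipeline$discretize$labels)
      rank_data[[schema$target$name]] <-
        apply_discretization(dz0, data[[schema$target$name]])
      rank_schema <- pca_schema(schema$attributes,
        list(name = schema$target$name, kind = "nominal",
          labels = pipeline$discretize$labels))
      attr(rank_data, "pca_schema") <- rank_schema
    }
    rank_M <- min(lp$M %||% 200L, cfg$ranking_M %||% 25L)
    ens <- bagging_fit(rank_data, M = rank_M, params = params,
      seed = cfg$seed, schema = rank_schema)
    ranking <- rank_attributes(ens)

    # ---- bundle ------------------------------------------------------------
    stage <- "write"
    utils::write.csv(as.data.frame(per_fold),
      file.path(out_dir, "metrics_per_fold.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(ranking),
      file.path(out_dir, "attribute_ranking.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      task = task, seed = cfg$seed,
      n_folds = n_folds, repeats = repeats,
      learner = lp$method %||% "bagging",
      M = lp$M %||% 200L,
      summary = as.list(overall),
      pooled_confusion = cv$pooled,
      labels = cv$labels
    ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    logline("bundle written to %s", out_dir)
    list(cv = cv, ranking = ranking, per_fold = per_fold, overall = overall,
      output_dir = out_dir)
  }, error = function(e) {
    logline("ERROR at stage %s: %s", stage, conditionMessage(e))
    rlang::abort(sprintf("experiment failed at stage '%s': %s", stage,
      conditionMessage(e)), class = "pcatree_experiment_error", parent = e)
  })
  invisible(result)
}
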