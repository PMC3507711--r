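# ggplot2 views of the main result types.

#' Plot a 2-D scenario or cleaning result
#'
#' Scatter of the two attributes coloured by class; when a cleaning report
#' is supplied the removed dirty majority rows are crossed out, mirroring
#' the geometric intuition behind the method.
#'
#' @param data A 2-attribute `patient_tbl` (e.g. from [gen_scenario2d()]).
#' @param report Optional `pcat_cleaning` computed on `data`.
#' @return A ggplot object.
#' @export
plot_scenario2d <- function(data, report = NULL) {
  schema <- table_schema(data)
  nm <- schema_attr_names(schema)
  stopifnot(length(nm) == 2)
  df <- tibble::tibble(
    x = as.numeric(data[[nm[1]]]),
    y = as.numeric(data[[nm[2]]]),
    class = as.character(data[[schema$target$name]]),
    dirty = FALSE
  )
  if (!is.null(report)) {
    df$dirty <- data$.row_id %in% report$dirty_ids
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = nm[1], y = nm[2], colour = "class") +
    ggplot2::theme_minimal()
  if (any(df$dirty)) {
    p <- p + ggplot2::geom_point(data = df[df$dirty, ], shape = 4, size = 3,
      colour = "red", stroke = 1.1)
  }
  p
}

#' @method autoplot pcat_cleaning
#' @export
autoplot.pcat_cleaning <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    rlang::abort("pass the table the report was computed on via `data`",
      class = "pcatree_plot_error")
  }
  plot_scenario2d(data, object)
}

#' @method autoplot pcat_cv
#' @export
autoplot.pcat_cv <- function(object, ...) {
  per_fold <- tidy(object)
  metrics <- intersect(c("accuracy", "TPR", "precision", "f_score"),
    names(per_fold))
  long <- tidyr::pivot_longer(per_fold, dplyr::all_of(metrics),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-fold value") +
    ggplot2::theme_minimal()
}

#' @method autoplot pcat_discretization
#' @export
autoplot.pcat_discretization <- function(object, values = NULL, ...) {
  td <- tidy(object)
  p <- ggplot2::ggplot(td)
  if (!is.null(values)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(v = as.numeric(values)),
      ggplot2::aes(x = .data$v), bins = 60, fill = "grey70")
  }
  p + ggplot2::geom_vline(xintercept = object$cut_points,
      linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "dose", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot an attribute ranking
#'
#' @param ranking A tibble from [rank_attributes()].
#' @param top_n How many attributes to show.
#' @return A ggplot object.
#' @export
plot_attribute_ranking <- function(ranking, top_n = 10L) {
  df <- utils::head(ranking, top_n)
  df$attribute <- factor(df$attribute, levels = rev(df$attribute))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$attribute)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "informativeness score", y = NULL) +
    ggplot2::theme_minimal()
}
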