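#' Fit equal-deviation intervals for a continuous dose target
#'
#' Divides the observed dose values into `K` ordered intervals such that the
#' dose deviations within the intervals are as close to equal as possible:
#' the fitted cut points minimise the variance, across intervals, of the
#' within-interval standard deviation of the dose. Cut points are restricted
#' to midpoints between consecutive distinct sorted values, so every
#' interval is non-empty. When the candidate space is small enough the
#' optimum is found by exact enumeration; otherwise deterministic coordinate
#' descent from an equal-frequency start is used.
#'
#' @param values Numeric dose values with at least `K` distinct values.
#' @param K Number of intervals (>= 2).
#' @param labels Ordered class names, length `K`. Defaults to
#'   `c("low", "medium", "high")` for `K = 3`.
#' @param exact_limit Maximum number of cut-point combinations enumerated
#'   exactly before falling back to coordinate descent.
#' @return An object of class `pcat_discretization` with fields
#'   `cut_points` (ascending, length `K - 1`), `labels`,
#'   `per_interval_deviation`, `per_interval_count` and `objective_value`.
#' @export
#' @examples
#' fit_equal_deviation_intervals(1:9, K = 3) # cuts at 3.5 and 6.5
fit_equal_deviation_intervals <- function(values, K = 3L,
                                          labels = NULL,
                                          exact_limit = 2e5) {
  K <- as.integer(K)
  stopifnot(K >= 2)
  if (is.null(labels)) {
    labels <- if (K == 3) c("low", "medium", "high") else
      paste0("c", seq_len(K))
  }
  stopifnot(length(labels) == K, !anyDuplicated(labels))
  x <- sort(as.numeric(values))
  n <- length(x)
  d <- length(unique(x))
  if (d < K) {
    rlang::abort(sprintf("need >= %d distinct values, got %d", K, d),
      class = "pcatree_discretizer_error")
  }
  # boundary positions: index p means a cut between x[p] and x[p+1]
  bpos <- which(diff(x) > 0)
  S1 <- cumsum(x)
  S2 <- cumsum(x^2)
  # sd of the sorted slice (l..r]; l = 0 means from the start; vectorised
  slice_sd <- function(l, r) {
    m <- r - l
    s <- S1[r] - ifelse(l > 0, S1[pmax(l, 1)], 0)
    q <- S2[r] - ifelse(l > 0, S2[pmax(l, 1)], 0)
    out <- sqrt(pmax((q - s^2 / m) / pmax(m - 1, 1), 0))
    out[m < 2] <- 0
    out
  }
  obj_of <- function(pos) {  # pos: ascending boundary positions, length K-1
    bounds <- c(0L, pos, n)
    sds <- slice_sd(bounds[-length(bounds)], bounds[-1])
    stats::var(sds)
  }

  n_comb <- choose(length(bpos), K - 1)
  if (K == 3 && n_comb <= exact_limit * 10) {
    # exact search, vectorised over the second cut
    best_obj <- Inf
    best_pos <- NULL
    nb <- length(bpos)
    for (i in seq_len(nb - 1)) {
      p <- bpos[i]
      qs <- bpos[(i + 1):nb]
      a <- slice_sd(0L, p)
      b <- slice_sd(rep(p, length(qs)), qs)
      c3 <- slice_sd(qs, rep(n, length(qs)))
      m <- (a + b + c3) / 3
      obj <- ((a - m)^2 + (b - m)^2 + (c3 - m)^2) / 2
      j <- which.min(obj)
      if (obj[j] < best_obj - 1e-15) {
        best_obj <- obj[j]
        best_pos <- c(p, qs[j])
      }
    }
    pos <- best_pos
  } else if (n_comb <= exact_limit) {
    combs <- utils::combn(bpos, K - 1)
    objs <- apply(combs, 2, obj_of)
    pos <- combs[, which.min(objs)]
  } else {
    # deterministic coordinate descent from equal-frequency cuts
    target_pos <- round(seq_len(K - 1) * n / K)
    pos <- vapply(target_pos, function(tp) bpos[which.min(abs(bpos - tp))],
      numeric(1))
    pos <- sort(unique(pos))
    while (length(pos) < K - 1) {  # degenerate init: pad with free boundaries
      pos <- sort(c(pos, setdiff(bpos, pos)[1]))
    }
    repeat {
      changed <- FALSE
      for (j in seq_len(K - 1)) {
        lo <- if (j == 1) 0L else pos[j - 1]
        hi <- if (j == K - 1) n else pos[j + 1]
        cand <- bpos[bpos > lo & bpos < hi]
        vals <- vapply(cand, function(p) {
          trial <- pos
          trial[j] <- p
          obj_of(trial)
        }, numeric(1))
        p_new <- cand[which.min(vals)]
        if (p_new != pos[j] && min(vals) < obj_of(pos) - 1e-15) {
          pos[j] <- p_new
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }

  new_discretization(x, pos, labels)
}

new_discretization <- function(x_sorted, pos, labels) {
  n <- length(x_sorted)
  cuts <- (x_sorted[pos] + x_sorted[pos + 1]) / 2
  bounds <- c(0L, pos, n)
  sds <- vapply(seq_along(labels), function(i) {
    seg <- x_sorted[(bounds[i] + 1):bounds[i + 1]]
    if (length(seg) < 2) 0 else stats::sd(seg)
  }, numeric(1))
  counts <- diff(bounds)
  structure(list(
    cut_points = cuts,
    labels = labels,
    per_interval_deviation = sds,
    per_interval_count = as.integer(counts),
    objective_value = stats::var(sds)
  ), class = "pcat_discretization")
}

#' @export
print.pcat_discretization <- function(x, ...) {
  cat(sprintf("<pcat_discretization> %d intervals, objective %.6g\n",
    length(x$labels), x$objective_value))
  cat("  cuts:", paste(format(x$cut_points), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy pcat_discretization
#' @export
tidy.pcat_discretization <- function(x, ...) {
  K <- length(x$labels)
  tibble::tibble(
    label = x$labels,
    lower = c(-Inf, x$cut_points),
    upper = c(x$cut_points, Inf),
    n = x$per_interval_count,
    deviation = x$per_interval_deviation
  )
}

#' @method glance pcat_discretization
#' @export
glance.pcat_discretization <- function(x, ...) {
  tibble::tibble(K = length(x$labels), objective_value = x$objective_value)
}

#' Exhaustive-search discretization oracle
#'
#' Enumerates every `(K-1)`-subset of the candidate cut points (midpoints of
#' consecutive distinct sorted values) and returns the global optimum of the
#' equal-deviation objective. Interval deviations are recomputed directly
#' with [stats::sd()], independently of the fitting path, so this serves as
#' a test oracle for [fit_equal_deviation_intervals()].
#'
#' @inheritParams fit_equal_deviation_intervals
#' @param max_comb Refuse instances with more than this many combinations.
#' @return A `pcat_discretization`.
#' @export
optimal_intervals_bruteforce <- function(values, K = 3L, labels = NULL,
                                         max_comb = 2e6) {
  K <- as.integer(K)
  if (is.null(labels)) {
    labels <- if (K == 3) c("low", "medium", "high") else
      paste0("c", seq_len(K))
  }
  x <- sort(as.numeric(values))
  n <- length(x)
  bpos <- which(diff(x) > 0)
  if (length(bpos) < K - 1) {
    rlang::abort("too few distinct values", class = "pcatree_discretizer_error")
  }
  if (choose(length(bpos), K - 1) > max_comb) {
    rlang::abort("instance too large for brute force",
      class = "pcatree_discretizer_error")
  }
  combs <- utils::combn(bpos, K - 1)
  best_obj <- Inf
  best <- NULL
  for (j in seq_len(ncol(combs))) {
    pos <- combs[, j]
    bounds <- c(0L, pos, n)
    sds <- vapply(seq_len(K), function(i) {
      seg <- x[(bounds[i] + 1):bounds[i + 1]]
      if (length(seg) < 2) 0 else stats::sd(seg)
    }, numeric(1))
    obj <- stats::var(sds)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- pos
    }
  }
  new_discretization(x, best, labels)
}

#' Map continuous values to interval labels
#'
#' Intervals are left-open, right-closed: value `v` maps to interval `i`
#' when `cut[i-1] < v <= cut[i]`, with the extremes unbounded. A value
#' exactly at a cut point goes to the lower interval.
#'
#' @param spec A `pcat_discretization`.
#' @param values Numeric values.
#' @return A character vector of labels (one per value).
#' @export
apply_discretization <- function(spec, values) {
  idx <- findInterval(as.numeric(values), spec$cut_points, left.open = TRUE) + 1L
  spec$labels[idx]
}

#' Serialise a discretization spec to JSON
#'
#' @param spec A `pcat_discretization`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discretization <- function(spec, path) {
  jsonlite::write_json(list(
    cut_points = spec$cut_points,
    labels = spec$labels,
    per_interval_deviation = spec$per_interval_deviation,
    per_interval_count = spec$per_interval_count,
    objective_value = spec$objective_value
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a discretization spec from JSON
#'
#' @param path Path written by [write_discretization()].
#' @return A `pcat_discretization`.
#' @export
read_discretization <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    cut_points = as.numeric(raw$cut_points),
    labels = as.character(raw$labels),
    per_interval_deviation = as.numeric(raw$per_interval_deviation),
    per_interval_count = as.integer(raw$per_interval_count),
    objective_value = as.numeric(raw$objective_value)
  ), class = "pcat_discretization")
}
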