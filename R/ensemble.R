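#' Bagged decision trees
#'
#' Grows `M` trees, each on a bootstrap sample of size n drawn uniformly with
#' replacement from the training table, and predicts by majority vote.
#' Member `i` is reproducible on its own from `seed + i`.
#'
#' @param data A `patient_tbl` (or data frame plus `schema`) with a nominal
#'   target.
#' @param M Ensemble size (the consumption experiments use 200).
#' @param params A [tree_params()] shared by all members.
#' @param seed Integer seed; member `i` draws its bootstrap (and any
#'   attribute subsampling) under `seed + i`.
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @param bootstrap Set `FALSE` to train every member on the identity sample
#'   (no resampling); with `M = 1` this reduces the ensemble to a single
#'   [grow_tree()] fit.
#' @param prune Prune each member at `params$pruning_cf` after growing.
#' @return An object of class `pcat_ensemble`.
#' @export
bagging_fit <- function(data, M = 200L, params = tree_params(), seed = 1L,
                        schema = NULL, bootstrap = TRUE, prune = TRUE) {
  schema <- resolve_schema(data, schema)
  stopifnot(M >= 1)
  if (nrow(data) == 0) {
    rlang::abort("cannot bag an empty table", class = "pcatree_tree_error")
  }
  n <- nrow(data)
  enc <- encode_table(data, schema)  # encode once; members share it
  members <- vector("list", M)
  for (i in seq_len(M)) {
    set.seed(seed + i)
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    tr <- grow_tree_encoded(enc, schema, params, idx - 1L)
    members[[i]] <- if (prune) prune_tree(tr) else tr
  }
  new_pcat_ensemble(members, rep(1, M), "bagging", seed, schema, params)
}

new_pcat_ensemble <- function(members, weights, method, seed, schema, params) {
  structure(list(members = members, weights = weights, method = method,
    seed = seed, schema = schema, params = params),
    class = "pcat_ensemble")
}

#' @export
print.pcat_ensemble <- function(x, ...) {
  cat(sprintf("<pcat_ensemble> %s, %d members\n", x$method, length(x$members)))
  invisible(x)
}

#' AdaBoost.M1 tree ensemble
#'
#' Boosting by weighted resampling: round 1 fits the training table directly
#' (uniform weights), and each later round draws a bootstrap sample with
#' probabilities proportional to the current example weights, fits a tree,
#' computes its weighted training error `eps_t` on the full table, assigns
#' the member the vote weight `log((1 - eps_t) / eps_t)`, and down-weights
#' correctly classified examples by `eps_t / (1 - eps_t)`. The loop stops
#' early when `eps_t >= 0.5` (member discarded unless it is the first, which
#' then triggers a warning and a single-member ensemble) or `eps_t = 0`
#' (perfect member kept with a large finite vote weight).
#'
#' @inheritParams bagging_fit
#' @param base_fit Optional base learner hook: a
#'   `function(data, weights, round)` returning an object whose
#'   `predict(object, newdata)` method yields labels. Defaults to resampled
#'   pruned trees; the hook exists so deterministic members can be injected
#'   when auditing the weight recursion.
#' @return A `pcat_ensemble` with method `"adaboost"`.
#' @export
adaboost_fit <- function(data, M = 200L, params = tree_params(), seed = 1L,
                         schema = NULL, prune = TRUE, base_fit = NULL) {
  schema <- resolve_schema(data, schema)
  stopifnot(M >= 1)
  n <- nrow(data)
  if (n == 0) {
    rlang::abort("cannot boost an empty table", class = "pcatree_tree_error")
  }
  w <- rep(1 / n, n)
  y <- as.character(data[[schema$target$name]])
  enc <- encode_table(data, schema)
  labels <- target_labels(schema)
  members <- list()
  alphas <- numeric(0)
  for (t in seq_len(M)) {
    member <- if (is.null(base_fit)) {
      # round 1 has uniform weights, where the weighted fit is exactly the
      # plain fit; later rounds approximate weighted fitting by resampling
      set.seed(seed + t)
      idx <- if (t == 1) seq_len(n) else sample.int(n, n, replace = TRUE, prob = w)
      tr <- grow_tree_encoded(enc, schema, params, idx - 1L)
      if (prune) prune_tree(tr) else tr
    } else {
      base_fit(data, w, t)
    }
    pred <- if (inherits(member, "pcat_tree")) {
      labels[predict_tree_encoded(member, enc)]
    } else {
      predict(member, data)
    }
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 0.5) {
      if (length(members) == 0) {
        rlang::warn("base learner cannot beat chance on round 1; returning a single-member ensemble")
        members <- list(member)
        alphas <- 1
      }
      break
    }
    eps_f <- max(eps, 1e-10)  # eps = 0: perfect member, large finite weight
    members[[length(members) + 1L]] <- member
    alphas <- c(alphas, log((1 - eps_f) / eps_f))
    if (eps == 0) break
    beta <- eps / (1 - eps)
    w[!miss] <- w[!miss] * beta
    w <- w / sum(w)
  }
  new_pcat_ensemble(members, alphas, "adaboost", seed, schema, params)
}

#' Predict by (weighted) majority vote
#'
#' Each member votes for one label with its weight; the label with the
#' largest total wins, ties going to the label earliest in schema label
#' order.
#'
#' @param ensemble A `pcat_ensemble`.
#' @param newdata A data frame conforming to the schema.
#' @return A character vector of predicted labels.
#' @export
ensemble_predict <- function(ensemble, newdata) {
  if (length(ensemble$members) == 0) {
    rlang::abort("empty ensemble", class = "pcatree_tree_error")
  }
  labels <- target_labels(ensemble$schema)
  votes <- ensemble_votes(ensemble, newdata)
  labels[max.col(votes, ties.method = "first")]
}

# n x K matrix of weighted vote totals; the table is encoded once and
# members traverse the shared encoding
ensemble_votes <- function(ensemble, newdata) {
  labels <- target_labels(ensemble$schema)
  votes <- matrix(0, nrow(newdata), length(labels))
  enc <- encode_table(newdata, ensemble$schema, with_target = FALSE)
  rows <- seq_len(nrow(newdata))
  for (i in seq_along(ensemble$members)) {
    j <- predict_tree_encoded(ensemble$members[[i]], enc)
    votes[cbind(rows, j)] <- votes[cbind(rows, j)] + ensemble$weights[i]
  }
  votes
}

#' @export
predict.pcat_ensemble <- function(object, newdata, ...) {
  ensemble_predict(object, newdata)
}

#' Member-level ensemble summary
#'
#' @param x A `pcat_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per member: `member`, `weight`,
#'   `node_count`, `n_leaves`, `depth`.
#' @method tidy pcat_ensemble
#' @export
tidy.pcat_ensemble <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(member = seq_along(x$members), weight = x$weights),
    dplyr::bind_rows(lapply(x$members, function(m) {
      glance(m)[, c("node_count", "n_leaves", "depth")]
    }))
  )
}

#' @method glance pcat_ensemble
#' @export
glance.pcat_ensemble <- function(x, ...) {
  tibble::tibble(method = x$method, n_members = length(x$members),
    mean_nodes = mean(vapply(x$members, n_nodes, numeric(1))),
    seed = x$seed)
}

#' Serialise an ensemble to a directory of JSON files
#'
#' Writes a `manifest.json` (method, weights, seed) and one
#' `member_<i>.json` per tree.
#'
#' @param ensemble A `pcat_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(method = ensemble$method, weights = ensemble$weights,
      seed = ensemble$seed, n_members = length(ensemble$members)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  for (i in seq_along(ensemble$members)) {
    write_tree(ensemble$members[[i]], file.path(dir, sprintf("member_%03d.json", i)))
  }
  invisible(dir)
}
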