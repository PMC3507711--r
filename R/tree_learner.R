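#' Shannon entropy of class counts, in bits
#'
#' @param class_counts Non-negative integer counts per class (not all zero).
#' @return Entropy in bits, with `0 log 0 := 0`.
#' @export
#' @examples
#' entropy(c(9, 5)) # 0.9403 bits
entropy <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    rlang::abort("class counts must be non-negative and not all zero",
      class = "pcatree_entropy_error")
  }
  p <- class_counts[class_counts > 0] / sum(class_counts)
  -sum(p * log2(p))
}

#' Gain ratio of splitting on one attribute
#'
#' C4.5's split criterion: information gain divided by split information,
#' both in bits. Nominal attributes are scored by their multiway partition
#' over observed values; numeric attributes by the best binary split at a
#' midpoint between consecutive distinct sorted values. When the split
#' information is zero (a constant attribute) the score is 0.
#'
#' @param data A data frame holding the attribute and target columns.
#' @param attribute Attribute name.
#' @param schema A [pca_schema()]; defaults to the one attached to `data`.
#' @return A list with `score` (gain ratio), `gain`, `split_info`, and for
#'   numeric attributes `threshold` (else `NULL`).
#' @export
gain_ratio <- function(data, attribute, schema = NULL) {
  schema <- resolve_schema(data, schema)
  if (!attribute %in% schema$attributes$name) {
    rlang::abort(sprintf("unknown attribute '%s'", attribute),
      class = "pcatree_unknown_attribute")
  }
  if (nrow(data) < 2) {
    rlang::abort("need at least 2 rows", class = "pcatree_tree_error")
  }
  y <- factor(as.character(data[[schema$target$name]]),
    levels = target_labels(schema))
  h_node <- entropy(as.integer(table(y)))
  kind <- schema$attributes$kind[schema$attributes$name == attribute]
  x <- data[[attribute]]
  n <- length(y)

  if (kind == "nominal") {
    tab <- table(factor(as.character(x)), y)
    sizes <- rowSums(tab)
    w <- sizes / n
    cond <- sum(w * apply(tab, 1, function(cnt) {
      if (sum(cnt) == 0) 0 else entropy(cnt)
    }))
    gain <- h_node - cond
    si <- entropy(sizes)
    score <- if (si <= 1e-12 || gain <= 1e-12) 0 else gain / si
    list(score = score, gain = gain, split_info = si, threshold = NULL)
  } else {
    xs <- sort(unique(as.numeric(x)))
    best <- list(score = 0, gain = 0, split_info = 0, threshold = NULL)
    if (length(xs) >= 2) {
      cuts <- (xs[-length(xs)] + xs[-1]) / 2
      for (thr in cuts) {
        left <- y[x <= thr]
        right <- y[x > thr]
        w <- c(length(left), length(right)) / n
        cond <- w[1] * entropy(as.integer(table(left))) +
          w[2] * entropy(as.integer(table(right)))
        gain <- h_node - cond
        si <- entropy(c(length(left), length(right)))
        if (gain > 1e-12 && si > 1e-12) {
          score <- gain / si
          if (score > best$score) {
            best <- list(score = score, gain = gain, split_info = si,
              threshold = thr)
          }
        }
      }
    }
    best
  }
}

#' Tree induction parameters
#'
#' @param min_leaf Minimum rows per admissible branch (a node with fewer than
#'   `2 * min_leaf` rows becomes a leaf).
#' @param max_depth Depth limit (`Inf` for unlimited; the root has depth 0).
#' @param pruning_cf Confidence factor in (0, 1] for pessimistic pruning;
#'   smaller is more aggressive. C4.5's conventional default is 0.25.
#' @param attribute_subsample Number of candidate attributes drawn afresh at
#'   each node, or `"all"` (plain C4.5). Values below the attribute count
#'   give Random-Forest-style randomised trees.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(min_leaf = 2L, max_depth = Inf, pruning_cf = 0.25,
                        attribute_subsample = "all") {
  stopifnot(min_leaf >= 1, pruning_cf > 0, pruning_cf <= 1)
  structure(list(min_leaf = as.integer(min_leaf), max_depth = max_depth,
    pruning_cf = pruning_cf, attribute_subsample = attribute_subsample),
    class = "tree_params")
}

#' Grow a C4.5-style decision tree
#'
#' Top-down recursive greedy induction: at each node the candidate attribute
#' with the largest gain ratio is selected (ties go to the attribute earliest
#' in schema order); nominal attributes split multiway with one branch per
#' declared legal value, numeric attributes split at the best midpoint
#' threshold. Recursion stops at purity, `min_leaf`, `max_depth`, or when no
#' split has positive gain; empty nominal branches become leaves carrying the
#' parent majority label. A nominal attribute is tested at most once per
#' path.
#'
#' @param data A non-empty `patient_tbl` (or data frame plus `schema`) with a
#'   nominal target.
#' @param params A [tree_params()].
#' @param schema A [pca_schema()]; defaults to the attached one.
#' @return An object of class `pcat_tree`.
#' @export
grow_tree <- function(data, params = tree_params(), schema = NULL) {
  schema <- resolve_schema(data, schema)
  if (nrow(data) == 0) {
    rlang::abort("cannot grow a tree from an empty table",
      class = "pcatree_tree_error")
  }
  enc <- encode_table(data, schema)
  grow_tree_encoded(enc, schema, params, seq_len(nrow(data)) - 1L)
}

# Grow from a pre-encoded table; `rows0` is a 0-based index multiset
# (bootstrap samples pass duplicated indices).
grow_tree_encoded <- function(enc, schema, params, rows0) {
  m <- nrow(schema$attributes)
  msub <- if (identical(params$attribute_subsample, "all")) m else
    min(as.integer(params$attribute_subsample), m)
  max_depth <- if (is.finite(params$max_depth)) as.integer(params$max_depth) else
    .Machine$integer.max
  flat <- grow_tree_cpp(enc$num_codes, enc$num_values, enc$Xnom, enc$y,
    length(target_labels(schema)),
    enc$attr_type, enc$attr_col, enc$nom_levels,
    params$min_leaf, max_depth, msub, as.integer(rows0))
  new_pcat_tree(flat, schema, params)
}

new_pcat_tree <- function(flat, schema, params) {
  structure(list(nodes = flat, schema = schema, params = params),
    class = "pcat_tree")
}

#' @export
print.pcat_tree <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pcat_tree> %d nodes (%d leaves), depth %d\n",
    g$node_count, g$n_leaves, g$depth))
  invisible(x)
}

n_nodes <- function(tree) length(tree$nodes$attr)

#' Tree summary statistics
#'
#' @param x A `pcat_tree`.
#' @param ... Unused.
#' @return A one-row tibble with `node_count`, `n_leaves`, `depth`, `n_train`.
#' @method glance pcat_tree
#' @export
glance.pcat_tree <- function(x, ...) {
  tibble::tibble(
    node_count = n_nodes(x),
    n_leaves = sum(x$nodes$type == 0L),
    depth = max(x$nodes$depth),
    n_train = x$nodes$n[1]
  )
}

#' Predict class labels with a decision tree
#'
#' Deterministic root-to-leaf traversal by attribute value. A nominal value
#' outside the domain declared at a node falls back to that node's majority
#' label.
#'
#' @param tree A `pcat_tree`.
#' @param newdata A data frame conforming to the tree's schema (target column
#'   not required).
#' @return A character vector of predicted class labels.
#' @export
predict_tree <- function(tree, newdata) {
  enc <- encode_table(newdata, tree$schema, with_target = FALSE)
  target_labels(tree$schema)[predict_tree_encoded(tree, enc)]
}

# 1-based label indices from a pre-encoded table
predict_tree_encoded <- function(tree, enc) {
  predict_tree_cpp(tree$nodes$attr, tree$nodes$type,
    tree$nodes$threshold, tree$nodes$label, tree$nodes$kids,
    enc$attr_type, enc$attr_col, enc$Xnum, enc$Xnom)
}

#' @export
predict.pcat_tree <- function(object, newdata, ...) predict_tree(object, newdata)

#' Pessimistic error pruning
#'
#' Bottom-up subtree replacement: a subtree collapses to a leaf when the
#' leaf's upper-confidence-bound error estimate (exact binomial upper bound
#' at one-sided level `1 - cf`, evaluated on the training counts stored in
#' the nodes) is strictly smaller than the sum over the subtree's leaves.
#' Node count never increases. As `cf` approaches 1 the bound approaches
#' zero pessimism and the tree is left unchanged.
#'
#' @param tree A `pcat_tree` grown with [grow_tree()].
#' @param pruning_cf Confidence factor in (0, 1]; defaults to the growing
#'   parameters' value.
#' @return A pruned `pcat_tree`.
#' @export
prune_tree <- function(tree, pruning_cf = tree$params$pruning_cf) {
  nodes <- tree$nodes
  ucb_errors <- function(cnt) {
    n <- sum(cnt)
    if (n == 0) return(0)
    e <- n - max(cnt)
    if (e >= n) return(n)
    n * stats::qbeta(1 - pruning_cf, e + 1, n - e)
  }
  keep_internal <- rep(TRUE, length(nodes$attr))
  # returns estimated subtree errors after pruning decisions below `id`
  walk <- function(id) {
    if (nodes$type[id] == 0L) return(ucb_errors(nodes$counts[id, ]))
    sub <- sum(vapply(nodes$kids[[id]], walk, numeric(1)))
    leaf <- ucb_errors(nodes$counts[id, ])
    if (leaf < sub) {
      keep_internal[id] <<- FALSE
      leaf
    } else {
      sub
    }
  }
  walk(1L)
  # compact: drop descendants of collapsed nodes, renumber survivors
  collapsed <- function(id) nodes$type[id] != 0L && !keep_internal[id]
  new_ids <- integer(length(nodes$attr))
  order_keep <- integer(0)
  visit <- function(id) {
    order_keep[length(order_keep) + 1L] <<- id
    new_ids[id] <<- length(order_keep)
    if (nodes$type[id] != 0L && keep_internal[id]) {
      for (k in nodes$kids[[id]]) visit(k)
    }
  }
  visit(1L)
  flat <- list(
    attr = ifelse(vapply(order_keep, collapsed, logical(1)), 0L,
      nodes$attr[order_keep]),
    type = ifelse(vapply(order_keep, collapsed, logical(1)), 0L,
      nodes$type[order_keep]),
    threshold = ifelse(vapply(order_keep, collapsed, logical(1)), NA_real_,
      nodes$threshold[order_keep]),
    label = nodes$label[order_keep],
    kids = lapply(order_keep, function(id) {
      if (nodes$type[id] != 0L && keep_internal[id]) {
        as.integer(new_ids[nodes$kids[[id]]])
      } else {
        integer(0)
      }
    }),
    counts = nodes$counts[order_keep, , drop = FALSE],
    depth = nodes$depth[order_keep],
    n = nodes$n[order_keep]
  )
  new_pcat_tree(flat, tree$schema, tree$params)
}

#' Translate a decision tree into if-then rules
#'
#' One rule per leaf: the conjunction of attribute tests along the
#' root-to-leaf path. Rules are mutually exclusive and exhaustive over the
#' input space.
#'
#' @param tree A `pcat_tree`.
#' @return A tibble with columns `rule_id`, `conditions` (a list column of
#'   condition tibbles with `attribute`, `op`, `value`), `text` (the rendered
#'   rule), `class` and `n` (training rows at the leaf).
#' @export
tree_to_rules <- function(tree) {
  nodes <- tree$nodes
  schema <- tree$schema
  labels <- target_labels(schema)
  rules <- list()
  descend <- function(id, conds) {
    if (nodes$type[id] == 0L) {
      rules[[length(rules) + 1L]] <<- list(conds = conds,
        class = labels[nodes$label[id]], n = nodes$n[id])
      return(invisible(NULL))
    }
    a <- nodes$attr[id]
    nm <- schema$attributes$name[a]
    if (nodes$type[id] == 1L) {
      dom <- schema$attributes$domain[[a]]
      for (b in seq_along(dom)) {
        descend(nodes$kids[[id]][b], c(conds, list(
          tibble::tibble(attribute = nm, op = "is", value = dom[b]))))
      }
    } else {
      thr <- nodes$threshold[id]
      descend(nodes$kids[[id]][1], c(conds, list(
        tibble::tibble(attribute = nm, op = "<=", value = format(thr)))))
      descend(nodes$kids[[id]][2], c(conds, list(
        tibble::tibble(attribute = nm, op = ">", value = format(thr)))))
    }
  }
  descend(1L, list())
  tibble::tibble(
    rule_id = seq_along(rules),
    conditions = lapply(rules, function(r) {
      if (length(r$conds) == 0) {
        tibble::tibble(attribute = character(), op = character(),
          value = character())
      } else {
        dplyr::bind_rows(r$conds)
      }
    }),
    text = vapply(rules, function(r) {
      if (length(r$conds) == 0) {
        sprintf("target is %s", r$class)
      } else {
        cc <- dplyr::bind_rows(r$conds)
        sprintf("If %s, then target is %s",
          paste(sprintf("%s %s %s", cc$attribute, cc$op, cc$value),
            collapse = ", "),
          r$class)
      }
    }, character(1)),
    class = vapply(rules, function(r) r$class, character(1)),
    n = vapply(rules, function(r) as.integer(r$n), integer(1))
  )
}

#' @method tidy pcat_tree
#' @export
tidy.pcat_tree <- function(x, ...) tree_to_rules(x)

# Evaluate the rule list (not the tree) on new data; used as the dual
# representation in tests and kept independent of predict_tree().
predict_rules <- function(rules, newdata, tree) {
  labels <- rep(NA_character_, nrow(newdata))
  for (i in seq_len(nrow(rules))) {
    cc <- rules$conditions[[i]]
    hit <- rep(TRUE, nrow(newdata))
    for (j in seq_len(nrow(cc))) {
      v <- newdata[[cc$attribute[j]]]
      hit <- hit & switch(cc$op[j],
        "is" = as.character(v) == cc$value[j],
        "<=" = as.numeric(v) <= as.numeric(cc$value[j]),
        ">" = as.numeric(v) > as.numeric(cc$value[j]))
    }
    labels[hit & is.na(labels)] <- rules$class[i]
  }
  labels
}

#' Serialise a decision tree to JSON
#'
#' Nested node objects: internal nodes carry `attribute`, `type`, optional
#' `threshold` and a `children` array; leaves carry `class` and
#' `distribution`.
#'
#' @param tree A `pcat_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  nodes <- tree$nodes
  schema <- tree$schema
  labels <- target_labels(schema)
  nest <- function(id) {
    base <- list(
      class = labels[nodes$label[id]],
      n = nodes$n[id],
      distribution = stats::setNames(as.list(nodes$counts[id, ]), labels)
    )
    if (nodes$type[id] == 0L) return(base)
    a <- nodes$attr[id]
    base$attribute <- schema$attributes$name[a]
    base$split <- if (nodes$type[id] == 1L) "nominal" else "numeric"
    if (nodes$type[id] == 2L) base$threshold <- nodes$threshold[id]
    base$children <- lapply(nodes$kids[[id]], nest)
    base
  }
  jsonlite::write_json(nest(1L), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
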