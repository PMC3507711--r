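# Shared fixtures and independent oracles. Oracles deliberately take
# different computational routes from the package code they check.

# -- tiny fixed schemas ------------------------------------------------------

toy_schema <- function() {
  pca_schema(
    tibble::tibble(
      name = c("age", "gender"),
      kind = c("numeric", "nominal"),
      domain = list(c(0, 120), c("F", "M"))
    ),
    target = list(name = "outcome", kind = "nominal", labels = c("no", "yes"))
  )
}

toy_table <- function() {
  patient_table(
    tibble::tibble(
      age = c(34, 51, 70),
      gender = c("F", "M", "F"),
      outcome = c("no", "yes", "no")
    ),
    toy_schema()
  )
}

# all-nominal schema realising the three-attribute worked traversal
fig_rule_schema <- function() {
  dom <- c("v1", "v2", "v3")
  pca_schema(
    tibble::tibble(name = c("x1", "x2", "x3"), kind = "nominal",
      domain = list(dom, dom, dom)),
    target = list(name = "target", kind = "nominal", labels = c("t1", "t2"))
  )
}

fig_rule_table <- function() {
  g <- expand.grid(x1 = c("v1", "v2", "v3"), x2 = c("v1", "v2", "v3"),
    x3 = c("v1", "v2", "v3"), stringsAsFactors = FALSE)
  g$target <- ifelse(g$x1 == "v1" & g$x2 == "v1" & g$x3 == "v1", "t2", "t1")
  patient_table(g, fig_rule_schema())
}

# -- random mixed-type tables ------------------------------------------------

random_mixed_schema <- function(n_num, n_nom, labels = c("neg", "pos")) {
  doms <- lapply(seq_len(n_nom), function(i) {
    paste0("l", seq_len(sample(2:4, 1)))
  })
  name_of <- function(stem, k) if (k > 0) paste0(stem, seq_len(k)) else character(0)
  pca_schema(
    tibble::tibble(
      name = c(name_of("num", n_num), name_of("nom", n_nom)),
      kind = rep(c("numeric", "nominal"), c(n_num, n_nom)),
      domain = c(replicate(n_num, c(-100, 100), simplify = FALSE), doms)
    ),
    target = list(name = "cls", kind = "nominal", labels = labels)
  )
}

random_mixed_table <- function(n, schema, minority_rate = 0.25) {
  attrs <- schema$attributes
  df <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(attrs))) {
    df[[attrs$name[i]]] <- if (attrs$kind[i] == "numeric") {
      round(stats::runif(n, -50, 50), 3)
    } else {
      sample(attrs$domain[[i]], n, replace = TRUE)
    }
  }
  labels <- schema$target$labels
  prob <- if (length(labels) == 2) c(1 - minority_rate, minority_rate) else NULL
  df[[schema$target$name]] <- sample(labels, n, replace = TRUE, prob = prob)
  # guarantee both classes
  df[[schema$target$name]][1] <- labels[1]
  df[[schema$target$name]][2] <- labels[2]
  patient_table(df, schema)
}

# -- brute-force neighbour oracle -------------------------------------------
# Full n x n HEOM distance matrix via stats::dist on range-scaled numerics
# plus per-attribute overlap sums: a different route from the C++ scan.

heom_matrix_oracle <- function(data, schema) {
  attrs <- schema$attributes
  n <- nrow(data)
  d2 <- matrix(0, n, n)
  for (i in seq_len(nrow(attrs))) {
    v <- data[[attrs$name[i]]]
    if (attrs$kind[i] == "numeric") {
      rng <- diff(range(as.numeric(v)))
      if (rng > 0) {
        d2 <- d2 + as.matrix(stats::dist(as.numeric(v) / rng))^2
      }
    } else {
      d2 <- d2 + outer(as.character(v), as.character(v), `!=`)
    }
  }
  sqrt(d2)
}

dirty_ids_oracle <- function(data, schema, minority_label, k) {
  dm <- heom_matrix_oracle(data, schema)
  y <- as.character(data[[schema$target$name]])
  row_id <- data$.row_id
  dirty <- integer(0)
  for (i in which(y == minority_label)) {
    d <- dm[i, ]
    d[i] <- Inf
    kth <- sort(d)[k]
    nbr <- which(d <= kth + 1e-12)
    dirty <- union(dirty, row_id[nbr[y[nbr] != minority_label]])
  }
  sort(dirty)
}

# -- textbook gain-ratio oracle ---------------------------------------------

entropy_oracle <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p)) / log(2)
}

gain_ratio_oracle <- function(data, attribute, schema) {
  y <- as.character(data[[schema$target$name]])
  h <- entropy_oracle(table(y))
  kind <- schema$attributes$kind[schema$attributes$name == attribute]
  x <- data[[attribute]]
  n <- length(y)
  score_split <- function(groups) {
    sizes <- vapply(groups, length, integer(1))
    cond <- sum(vapply(seq_along(groups), function(g) {
      sizes[g] / n * entropy_oracle(table(y[groups[[g]]]))
    }, numeric(1)))
    gain <- h - cond
    si <- entropy_oracle(sizes)
    if (gain <= 1e-12 || si <= 1e-12) 0 else gain / si
  }
  if (kind == "nominal") {
    score_split(split(seq_len(n), as.character(x)))
  } else {
    xs <- sort(unique(as.numeric(x)))
    if (length(xs) < 2) return(0)
    cuts <- (xs[-1] + xs[-length(xs)]) / 2
    max(vapply(cuts, function(thr) {
      score_split(list(which(x <= thr), which(x > thr)))
    }, numeric(1)))
  }
}

# tiny learner predicting a constant label, for degenerate-pipeline checks
constant_learner <- function(label) {
  list(name = "constant", fit = function(data, schema, seed = 1L) {
    structure(list(label = label), class = "pcat_constant_clf")
  })
}

predict.pcat_constant_clf <- function(object, newdata, ...) {
  rep(object$label, nrow(newdata))
}
registerS3method("predict", "pcat_constant_clf", predict.pcat_constant_clf)

# deterministic injected base learner for auditing the boosting recursion
fixed_member <- function(predictions) {
  structure(list(pred = predictions), class = "pcat_fixed_clf")
}

predict.pcat_fixed_clf <- function(object, newdata, ...) {
  object$pred[seq_len(nrow(newdata))]
}
registerS3method("predict", "pcat_fixed_clf", predict.pcat_fixed_clf)
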