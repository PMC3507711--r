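test_that("entropy matches closed forms", {
  expect_equal(entropy(c(10, 0)), 0)
  expect_equal(entropy(c(5, 5)), 1)
  expect_equal(entropy(c(9, 5)), 0.9403, tolerance = 1e-4)
  expect_equal(entropy(c(9, 5)),
    -(9 / 14) * log2(9 / 14) - (5 / 14) * log2(5 / 14))
  expect_error(entropy(c(0, 0)), class = "pcatree_entropy_error")
})

test_that("gain ratio handles degenerate and perfect splits", {
  sch <- pca_schema(
    tibble::tibble(name = c("a", "b"), kind = "nominal",
      domain = list(c("u", "v"), c("u", "v"))),
    list(name = "cls", kind = "nominal", labels = c("n", "p")))
  d <- patient_table(tibble::tibble(
    a = rep("u", 8),
    b = rep(c("u", "v"), each = 4),
    cls = rep(c("n", "p"), each = 4)), sch)
  expect_equal(gain_ratio(d, "a")$score, 0)     # constant attribute
  gb <- gain_ratio(d, "b")
  expect_equal(gb$gain, 1)                      # perfect binary split
  expect_equal(gb$split_info, 1)
  expect_equal(gb$score, 1)
  expect_error(gain_ratio(d, "zz"), class = "pcatree_unknown_attribute")
})

test_that("gain ratio equals an independently coded textbook computation", {
  set.seed(11)
  for (i in 1:15) {
    sch <- random_mixed_schema(2, 2)
    d <- random_mixed_table(30, sch)
    for (a in sch$attributes$name) {
      expect_equal(gain_ratio(d, a)$score, gain_ratio_oracle(d, a, sch),
        tolerance = 1e-10, label = paste("attr", a, "draw", i))
    }
  }
})

test_that("a pure-target table grows a single leaf", {
  sch <- toy_schema()
  d <- patient_table(tibble::tibble(
    age = c(10, 20, 30), gender = c("F", "M", "F"),
    outcome = c("no", "no", "no")), sch)
  tr <- grow_tree(d, tree_params(), sch)
  expect_equal(glance(tr)$node_count, 1L)
  expect_equal(predict_tree(tr, d), rep("no", 3))
})

test_that("the worked nominal traversal yields t2 and its printed rule", {
  d <- fig_rule_table()
  tr <- grow_tree(d, tree_params(min_leaf = 1))
  expect_equal(predict_tree(tr,
    data.frame(x1 = "v1", x2 = "v1", x3 = "v1")), "t2")
  # traversal semantics for an unrelated example: lands in a t1 leaf
  expect_equal(predict_tree(tr,
    data.frame(x1 = "v1", x2 = "v2", x3 = "v3")), "t1")
  rules <- tree_to_rules(tr)
  t2_rule <- rules[rules$class == "t2", ]
  expect_equal(nrow(t2_rule), 1L)
  cc <- t2_rule$conditions[[1]]
  expect_setequal(cc$attribute, c("x1", "x2", "x3"))
  expect_true(all(cc$op == "is" & cc$value == "v1"))
  expect_match(t2_rule$text, "then target is t2")
  # training rows classified back to their own labels (separable, min_leaf 1)
  expect_equal(predict_tree(tr, d), d$target)
})

test_that("resubstitution accuracy never falls below the majority baseline", {
  set.seed(23)
  for (i in 1:8) {
    sch <- random_mixed_schema(2, 2)
    d <- random_mixed_table(60, sch)
    tr <- grow_tree(d, tree_params(), sch)
    acc <- mean(predict_tree(tr, d) == d$cls)
    base <- max(table(d$cls)) / nrow(d)
    expect_gte(acc, base - 1e-12)
  }
})

test_that("rule lists are exhaustive, exclusive, and agree with traversal", {
  set.seed(37)
  sch <- random_mixed_schema(2, 2)
  d <- random_mixed_table(80, sch)
  tr <- grow_tree(d, tree_params(min_leaf = 1), sch)
  rules <- tree_to_rules(tr)
  expect_equal(nrow(rules), glance(tr)$n_leaves)
  probe <- random_mixed_table(1000, sch)
  via_tree <- predict_tree(tr, probe)
  via_rules <- pcatree:::predict_rules(rules, probe, tr)
  expect_false(anyNA(via_rules))  # exhaustive
  expect_equal(via_rules, via_tree)
})

test_that("growth is deterministic for fixed inputs, including subsampling", {
  set.seed(41)
  sch <- random_mixed_schema(3, 2)
  d <- random_mixed_table(80, sch)
  t1 <- grow_tree(d, tree_params(), sch)
  t2 <- grow_tree(d, tree_params(), sch)
  expect_identical(t1$nodes, t2$nodes)
  set.seed(99); s1 <- grow_tree(d, tree_params(attribute_subsample = 2), sch)
  set.seed(99); s2 <- grow_tree(d, tree_params(attribute_subsample = 2), sch)
  expect_identical(s1$nodes, s2$nodes)
})

test_that("pruning never grows the tree and keeps the no-pessimism limit", {
  # single leaf unchanged
  sch <- toy_schema()
  leaf <- grow_tree(patient_table(tibble::tibble(
    age = c(1, 2), gender = c("F", "M"), outcome = c("no", "no")), sch))
  expect_identical(prune_tree(leaf)$nodes, leaf$nodes)

  # cf -> 1 on noiseless separable data leaves the tree unchanged
  d <- fig_rule_table()
  tr <- grow_tree(d, tree_params(min_leaf = 1))
  expect_equal(glance(prune_tree(tr, 1 - 1e-9))$node_count,
    glance(tr)$node_count)

  # noisy data, cf = 0.25: monotone node-count reduction across seeds
  for (s in 1:20) {
    set.seed(s)
    sch2 <- random_mixed_schema(3, 1)
    d2 <- random_mixed_table(100, sch2)
    g <- grow_tree(d2, tree_params(min_leaf = 1), sch2)
    p <- prune_tree(g, 0.25)
    expect_lte(glance(p)$node_count, glance(g)$node_count)
    # pruned tree still predicts for every row
    expect_length(predict_tree(p, d2), 100L)
  }
})

test_that("trees serialise to nested JSON with consistent leaf distributions", {
  d <- fig_rule_table()
  tr <- grow_tree(d, tree_params(min_leaf = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$attribute, "x1")
  expect_length(obj$children, 3L)
  # root distribution covers all 27 training rows
  expect_equal(sum(unlist(obj$distribution)), 27)
})
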