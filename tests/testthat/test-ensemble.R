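test_that("identity-sample bagging with M = 1 equals a single tree", {
  set.seed(3)
  sch <- random_mixed_schema(2, 2)
  d <- random_mixed_table(60, sch)
  ens <- bagging_fit(d, M = 1, seed = 5, schema = sch, bootstrap = FALSE,
    prune = FALSE)
  single <- grow_tree(d, tree_params(), sch)
  expect_identical(ens$members[[1]]$nodes, single$nodes)
  probe <- random_mixed_table(200, sch)
  expect_equal(ensemble_predict(ens, probe), predict_tree(single, probe))
})

test_that("bagging produces M members and is seed-reproducible", {
  set.seed(4)
  sch <- random_mixed_schema(2, 1)
  d <- random_mixed_table(50, sch)
  ens <- bagging_fit(d, M = 12, seed = 7, schema = sch)
  expect_length(ens$members, 12L)
  expect_equal(ens$weights, rep(1, 12))
  ens2 <- bagging_fit(d, M = 12, seed = 7, schema = sch)
  expect_identical(lapply(ens$members, `[[`, "nodes"),
    lapply(ens2$members, `[[`, "nodes"))
  probe <- random_mixed_table(100, sch)
  expect_identical(ensemble_predict(ens, probe), ensemble_predict(ens2, probe))
})

test_that("member i is reproducible from seed + i and bootstraps behave like theory", {
  set.seed(6)
  sch <- random_mixed_schema(2, 1)
  d <- random_mixed_table(64, sch)
  n <- nrow(d)
  seed <- 31L
  ens <- bagging_fit(d, M = 30, seed = seed, schema = sch, prune = FALSE)
  fracs <- numeric(30)
  for (i in seq_len(30)) {
    set.seed(seed + i)
    idx <- sample.int(n, n, replace = TRUE)
    rebuilt <- grow_tree(d[idx, , drop = FALSE], tree_params(), sch)
    expect_identical(ens$members[[i]]$nodes, rebuilt$nodes,
      label = sprintf("member %d", i))
    fracs[i] <- length(unique(idx)) / n
  }
  # expected distinct fraction 1 - (1 - 1/n)^n ~ 0.632
  expect_lt(abs(mean(fracs) - (1 - exp(-1))), 0.03)
})

test_that("weighted majority votes match an explicit tally, ties to schema order", {
  set.seed(8)
  sch <- random_mixed_schema(2, 1, labels = c("aa", "bb", "cc"))
  d <- random_mixed_table(90, sch)
  d$cls <- sample(c("aa", "bb", "cc"), 90, TRUE)
  d <- patient_table(as.data.frame(d)[, -1], sch)
  ens <- bagging_fit(d, M = 9, seed = 2, schema = sch)
  probe <- random_mixed_table(150, sch)
  pred <- ensemble_predict(ens, probe)
  member_preds <- vapply(ens$members, function(m) predict_tree(m, probe),
    character(nrow(probe)))
  labels <- c("aa", "bb", "cc")
  tally_pred <- apply(member_preds, 1, function(v) {
    counts <- vapply(labels, function(l) sum(v == l), numeric(1))
    labels[which.max(counts)]  # which.max: first maximum = schema order
  })
  expect_equal(pred, unname(tally_pred))

  # explicit tie: two single-leaf members voting for different labels
  pure_a <- grow_tree(patient_table(tibble::tibble(
    num1 = c(1, 2), num2 = c(1, 2), nom1 = sch$attributes$domain[[3]][1],
    cls = "bb"), sch), schema = sch)
  pure_b <- grow_tree(patient_table(tibble::tibble(
    num1 = c(1, 2), num2 = c(1, 2), nom1 = sch$attributes$domain[[3]][1],
    cls = "cc"), sch), schema = sch)
  tie <- pcatree:::new_pcat_ensemble(list(pure_a, pure_b), c(1, 1),
    "bagging", 1L, sch, tree_params())
  expect_equal(ensemble_predict(tie, probe[1, ]), "bb")  # earliest label wins
  expect_error(ensemble_predict(
    pcatree:::new_pcat_ensemble(list(), numeric(0), "bagging", 1L, sch,
      tree_params()), probe), class = "pcatree_tree_error")
})

test_that("member order does not change ensemble predictions", {
  set.seed(9)
  sch <- random_mixed_schema(2, 1)
  d <- random_mixed_table(70, sch)
  ens <- bagging_fit(d, M = 7, seed = 3, schema = sch)
  probe <- random_mixed_table(120, sch)
  perm <- ens
  ord <- c(4, 1, 7, 2, 6, 3, 5)
  perm$members <- ens$members[ord]
  perm$weights <- ens$weights[ord]
  expect_equal(ensemble_predict(perm, probe), ensemble_predict(ens, probe))
})

test_that("separable data gives one perfect boosting member with zero error", {
  d <- fig_rule_table()
  ens <- adaboost_fit(d, M = 10, params = tree_params(min_leaf = 1), seed = 1,
    prune = FALSE)
  expect_length(ens$members, 1L)
  expect_equal(ensemble_predict(ens, d), d$target)
  expect_gt(ens$weights[1], 0)
})

test_that("the boosting weight recursion matches a hand-computed trace", {
  # 10 rows; members injected so every quantity is a closed form
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(0, 100))),
    list(name = "cls", kind = "nominal", labels = c("n", "p")))
  d <- patient_table(tibble::tibble(x = 1:10,
    cls = rep(c("n", "p"), each = 5)), sch)
  truth <- d$cls
  # round 1 errs on rows 1-2; round 2 errs on rows 3-4; round 3 on 5-6
  plans <- list(replace(truth, 1:2, c("p", "p")),
                replace(truth, 3:4, c("p", "p")),
                replace(truth, 5:6, c("p", "n")))
  hook <- function(data, w, round) fixed_member(plans[[round]])
  ens <- adaboost_fit(d, M = 3, seed = 1, schema = sch, base_fit = hook)

  # independent oracle: AdaBoost.M1 weight recursion
  w <- rep(1 / 10, 10)
  alpha <- numeric(3)
  for (t in 1:3) {
    miss <- plans[[t]] != truth
    eps <- sum(w[miss])
    alpha[t] <- log((1 - eps) / eps)
    beta <- eps / (1 - eps)
    w[!miss] <- w[!miss] * beta
    w <- w / sum(w)
  }
  expect_equal(ens$weights, alpha, tolerance = 1e-12)
  expect_length(ens$members, 3L)
  # round 1: eps = 0.2 -> alpha = log(4)
  expect_equal(ens$weights[1], log(4))
})

test_that("boosting stops and warns when the base learner cannot beat chance", {
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(0, 100))),
    list(name = "cls", kind = "nominal", labels = c("n", "p")))
  d <- patient_table(tibble::tibble(x = 1:10,
    cls = rep(c("n", "p"), each = 5)), sch)
  hook <- function(data, w, round) fixed_member(rep("p", 10))  # eps = 0.5
  expect_warning(ens <- adaboost_fit(d, M = 5, schema = sch, base_fit = hook),
    "chance")
  expect_length(ens$members, 1L)
})

test_that("bagging beats a single tree on held-out coherent-scenario data", {
  accs <- vapply(1:20, function(s) {
    train <- gen_scenario2d("coherent", 120, 30, seed = s)
    test <- gen_scenario2d("coherent", 120, 30, seed = s + 500)
    sch <- table_schema(train)
    single <- prune_tree(grow_tree(train, tree_params(), sch))
    bag <- bagging_fit(train, M = 15, seed = s, schema = sch)
    c(single = mean(predict_tree(single, test) == test$class),
      bag = mean(ensemble_predict(bag, test) == test$class))
  }, numeric(2))
  expect_gte(mean(accs["bag", ]), mean(accs["single", ]) - 0.005)
})

test_that("ensembles serialise to a manifest plus member files", {
  set.seed(10)
  sch <- random_mixed_schema(1, 1)
  d <- random_mixed_table(40, sch)
  ens <- bagging_fit(d, M = 3, seed = 1, schema = sch)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^member_"), 3L)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_members, 3L)
})
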