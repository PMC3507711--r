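test_that("HEOM distance has identity, symmetry and the overlap unit", {
  sch <- toy_schema()
  a <- list(age = 30, gender = "F")
  b <- list(age = 30, gender = "M")
  expect_equal(heom_distance(a, a, sch), 0)
  expect_equal(heom_distance(a, b, sch), 1)  # one nominal mismatch
  expect_equal(heom_distance(a, b, sch), heom_distance(b, a, sch))
  # numeric term is range-normalised
  c1 <- list(age = 90, gender = "F")
  expect_equal(heom_distance(a, c1, sch, ranges = c(age = 120)), 60 / 120)
  # mixed: sqrt(overlap^2 + (dx/range)^2)
  d1 <- list(age = 90, gender = "M")
  expect_equal(heom_distance(a, d1, sch, ranges = c(age = 120)),
    sqrt(1 + 0.25))
})

test_that("HEOM equals a term-wise recomputation on random mixed rows", {
  set.seed(14)
  sch <- random_mixed_schema(3, 3)
  d <- random_mixed_table(20, sch)
  ranges <- vapply(paste0("num", 1:3),
    function(nm) diff(range(d[[nm]])), numeric(1))
  for (trial in 1:20) {
    ij <- sample(20, 2)
    got <- heom_distance(d[ij[1], ], d[ij[2], ], sch, ranges = ranges)
    s <- 0
    for (nm in paste0("num", 1:3)) {
      s <- s + ((d[[nm]][ij[1]] - d[[nm]][ij[2]]) / ranges[[nm]])^2
    }
    for (nm in paste0("nom", 1:3)) {
      s <- s + (d[[nm]][ij[1]] != d[[nm]][ij[2]])
    }
    expect_equal(got, sqrt(s))
  }
})

test_that("the 1-D toy dirty set is the two close majority points", {
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(-100, 100))),
    list(name = "cls", kind = "nominal", labels = c("maj", "min")))
  d <- patient_table(tibble::tibble(
    x = c(0, 0.1, 0.2, 10, 11, 12),
    cls = c("min", rep("maj", 5))), sch)
  rep2 <- find_dirty(d, "min", k = 2, schema = sch)
  expect_equal(rep2$dirty_ids, c(1L, 2L))  # rows at 0.1 and 0.2
  cl <- clean_training_set(d, "min", k = 2, schema = sch)
  expect_equal(nrow(cl$table), 4L)
  expect_equal(sum(cl$table$cls == "min"), 1L)
  expect_equal(cl$table$x, c(0, 10, 11, 12))
})

test_that("minority-only neighbourhoods yield an empty dirty set", {
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(-100, 100))),
    list(name = "cls", kind = "nominal", labels = c("maj", "min")))
  d <- patient_table(tibble::tibble(
    x = c(0, 0.2, 0.4, 50, 51, 52, 53),
    cls = c("min", "min", "min", rep("maj", 4))), sch)
  rep3 <- find_dirty(d, "min", k = 2, schema = sch)
  expect_length(rep3$dirty_ids, 0L)
  cl <- clean_training_set(d, "min", k = 2, schema = sch)
  expect_equal(as.data.frame(cl$table), as.data.frame(d))
})

test_that("find_dirty equals the all-pairs brute force on random mixed tables", {
  set.seed(77)
  for (trial in 1:25) {
    sch <- random_mixed_schema(sample(1:3, 1), sample(1:3, 1))
    d <- random_mixed_table(sample(30:120, 1), sch, minority_rate = 0.2)
    for (k in c(1, 3, 5)) {
      got <- find_dirty(d, "pos", k = k, schema = sch)
      want <- dirty_ids_oracle(d, sch, "pos", k)
      expect_identical(got$dirty_ids, want,
        label = sprintf("trial %d k %d", trial, k))
      # bookkeeping invariants hold on every run
      cl <- clean_training_set(d, "pos", k = k, schema = sch)
      expect_equal(nrow(cl$table), nrow(d) - length(got$dirty_ids))
      expect_equal(sum(cl$table$cls == "pos"), sum(d$cls == "pos"))
    }
  }
})

test_that("ties at the k-th distance include all tied rows", {
  sch <- pca_schema(
    tibble::tibble(name = "x", kind = "numeric", domain = list(c(-100, 100))),
    list(name = "cls", kind = "nominal", labels = c("maj", "min")))
  # two majority rows exactly equidistant at the k = 1 radius
  d <- patient_table(tibble::tibble(
    x = c(0, 1, -1, 30, 40),
    cls = c("min", "maj", "maj", "maj", "maj")), sch)
  r1 <- find_dirty(d, "min", k = 1, schema = sch)
  expect_equal(r1$dirty_ids, c(1L, 2L))
})

test_that("re-cleaning only surfaces newly exposed neighbours", {
  set.seed(55)
  for (s in 1:5) {
    d <- gen_scenario2d("sparse", 80, 20, seed = s)
    sch <- table_schema(d)
    first <- clean_training_set(d, "minority", 3, sch)
    second <- find_dirty(first$table, "minority", 3, sch)
    # nothing removed twice, and second-pass dirty rows were invisible
    # (not dirty) in the first pass
    expect_length(intersect(second$dirty_ids, first$report$dirty_ids), 0L)
    exposed <- setdiff(second$neighbor_lists$neighbor_row_id,
      first$report$neighbor_lists$neighbor_row_id)
    expect_true(all(second$dirty_ids %in% exposed))
  }
})

test_that("select_k scores a grid like an exhaustive re-evaluation and breaks ties low", {
  d <- gen_scenario2d("sparse", 90, 30, seed = 21)
  sch <- table_schema(d)
  sel <- select_k(d, k_candidates = c(1, 3, 5), minority_label = "minority",
    validation_repeats = 3, seed = 17, schema = sch)
  expect_true(sel$k %in% c(1, 3, 5))
  expect_equal(nrow(sel$scores), 9L)
  # oracle: replay each (k, split) with the public single-k path
  for (r in 1:3) {
    set.seed(17 + r)
    y <- as.character(d$class)
    train_idx <- sort(unlist(lapply(split(seq_len(nrow(d)), y), function(ix) {
      sample(ix, max(1, round(length(ix) * 2 / 3)))
    }), use.names = FALSE))
    val_idx <- setdiff(seq_len(nrow(d)), train_idx)
    train <- d[train_idx, ]; attr(train, "pca_schema") <- sch
    for (kk in c(1, 3, 5)) {
      cleaned <- clean_training_set(train, "minority", kk, sch)$table
      model <- prune_tree(grow_tree(cleaned, schema = sch))
      pred <- predict_tree(model, d[val_idx, ])
      cm <- confusion_matrix(y[val_idx], pred, c("majority", "minority"))
      want <- pcatree:::minority_f_score(cm, "minority")
      got <- sel$scores$f_score[sel$scores$k == kk & sel$scores$repeat_id == r]
      expect_equal(got, want, label = sprintf("k %d repeat %d", kk, r))
    }
  }
  # grid means decide; ties go to the smallest k
  means <- tapply(sel$scores$f_score, sel$scores$k, mean)
  expect_equal(sel$k, as.integer(min(names(means)[means == max(means)])))

  # single candidate short-circuits
  expect_equal(select_k(d, k_candidates = 5, schema = sch)$k, 5L)
})

test_that("under-sampling balances classes without touching the minority", {
  d <- gen_scenario2d("sparse", 81, 19, seed = 2)
  u <- undersample(d, seed = 4)
  expect_equal(as.integer(table(u$class)), c(19L, 19L))
  expect_identical(u$.row_id[u$class == "minority"],
    d$.row_id[d$class == "minority"])
  bal <- gen_scenario2d("sparse", 25, 25, seed = 2)
  expect_equal(as.data.frame(undersample(bal, 1)), as.data.frame(bal))
})

test_that("over-sampling replicates minority rows up to the majority count", {
  d <- gen_scenario2d("sparse", 81, 19, seed = 3)
  o <- oversample(d, seed = 4)
  expect_equal(as.integer(table(o$class)), c(81L, 81L))
  expect_equal(nrow(o), 162L)
  # replicates are value-identical copies of original minority rows
  extra <- o[o$.row_id > max(d$.row_id), ]
  expect_equal(nrow(extra), 62L)
  orig_min <- d[d$class == "minority", c("x1", "x2")]
  for (i in seq_len(nrow(extra))) {
    expect_true(any(orig_min$x1 == extra$x1[i] & orig_min$x2 == extra$x2[i]))
  }
  bal <- gen_scenario2d("sparse", 25, 25, seed = 2)
  expect_equal(as.data.frame(oversample(bal, 1)), as.data.frame(bal))
})

test_that("cleaning reports serialise to JSON", {
  d <- gen_scenario2d("sparse", 40, 10, seed = 6)
  rep6 <- find_dirty(d, "minority", 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cleaning_report(rep6, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$k, 3L)
  expect_equal(sort(obj$dirty_ids), as.integer(rep6$dirty_ids))
})
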