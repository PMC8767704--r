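split_is_leaf_exclusive <- function(split, manifest) {
  tr <- unique(manifest$leaf_id[manifest$image_id %in% split$train_ids])
  te <- unique(manifest$leaf_id[manifest$image_id %in% split$test_ids])
  length(intersect(tr, te)) == 0L
}

test_that("group_by_leaf partitions the candidate ids", {
  m <- grid_manifest()
  ids <- m$image_id[1:50]
  g <- group_by_leaf(m, ids)
  expect_identical(sort(unlist(g, use.names = FALSE)), sort(ids))
  expect_length(group_by_leaf(m, character()), 0L)
})

test_that("make_split sends round(0.2 * L) leaf groups to test", {
  m <- grid_manifest()
  # pick exactly 10 leaves
  leaves10 <- unique(m$leaf_id)[1:10]
  ids <- m$image_id[m$leaf_id %in% leaves10]
  s <- make_split(m, ids, test_fraction = 0.2, seed = 3)
  te_leaves <- unique(m$leaf_id[m$image_id %in% s$test_ids])
  tr_leaves <- unique(m$leaf_id[m$image_id %in% s$train_ids])
  expect_length(te_leaves, 2L)
  expect_length(tr_leaves, 8L)
  expect_true(split_is_leaf_exclusive(s, m))
  # determinism and row-order invariance
  s2 <- make_split(m, ids, test_fraction = 0.2, seed = 3)
  expect_identical(sort(s$test_ids), sort(s2$test_ids))
  mperm <- as_manifest(as.data.frame(m)[sample(nrow(m)), ])
  s3 <- make_split(mperm, ids, test_fraction = 0.2, seed = 3)
  expect_identical(sort(s$test_ids), sort(s3$test_ids))
  expect_error(make_split(m, m$image_id[m$leaf_id == leaves10[1]]),
               "at least 2 leaf groups")
})

test_that("extra_train_ids join train but never test", {
  m <- grid_manifest()
  l3 <- m$image_id[m$leaf_number == 3L]
  l4 <- m$image_id[m$leaf_number == 4L]
  s <- make_split(m, l3, seed = 1, extra_train_ids = l4, name = "L3L4/L3")
  expect_true(all(m$leaf_number[m$image_id %in% s$test_ids] == 3L))
  expect_true(all(l4 %in% s$train_ids))
  expect_true(split_is_leaf_exclusive(s, m))
})

test_that("each factor yields its six named splits, all leaf-exclusive", {
  m <- grid_manifest()
  expected <- list(
    leaf_number = c("L3L4/L3", "L3L4/L4", "L3/L3", "L4/L4", "L3/L4", "L4/L3"),
    year = c("Y1Y2/Y1", "Y1Y2/Y2", "Y1/Y1", "Y2/Y2", "Y1/Y2", "Y2/Y1"),
    environment = c("GHFD/GH", "GHFD/FD", "GH/GH", "FD/FD", "GH/FD", "FD/GH"))
  for (factor in names(expected)) {
    sps <- make_factor_splits(m, factor, seed = 2)
    expect_identical(names(sps), expected[[factor]])
    for (s in sps) expect_true(split_is_leaf_exclusive(s, m))
  }
  # inter-environment split: test side is exactly all FD images
  sps <- make_factor_splits(m, "environment", seed = 2)
  expect_setequal(sps[["GH/FD"]]$test_ids, m$image_id[m$environment == "FD"])
  expect_setequal(sps[["GH/FD"]]$train_ids, m$image_id[m$environment == "GH"])
  # mixed-split train is at least as large as the whole-split train
  whole <- make_split(m, seed = 2)
  expect_gte(length(sps[["GHFD/GH"]]$train_ids), length(whole$train_ids))
})

test_that("inter-year splits reduce to genotypes and scores common to both years", {
  m <- grid_manifest()
  sps <- make_factor_splits(m, "year", seed = 4)
  s <- sps[["Y1/Y2"]]
  tr <- m[m$image_id %in% s$train_ids, ]
  te <- m[m$image_id %in% s$test_ids, ]
  expect_true(all(tr$year == "Y1"))
  expect_true(all(te$year == "Y2"))
  # Y2-only classes ("2" and "5") are excluded from both sides
  expect_false(any(c("2", "5") %in% c(tr$score, te$score)))
  expect_identical(sort(unique(tr$score)), sort(unique(te$score)))
  expect_identical(s$class_set, leafhair:::sort_classes(unique(tr$score)))
  expect_length(s$class_set, 7L)
  # only genotypes grown in both years survive
  g1 <- unique(m$genotype[m$year == "Y1"]); g2 <- unique(m$genotype[m$year == "Y2"])
  expect_true(all(unique(c(tr$genotype, te$genotype)) %in% intersect(g1, g2)))
  # the reverse split uses the same candidate list
  expect_setequal(sps[["Y2/Y1"]]$train_ids, s$test_ids)
  expect_setequal(sps[["Y2/Y1"]]$test_ids, s$train_ids)
})

test_that("k-fold pairs resample the parent train side leaf-exclusively", {
  m <- grid_manifest()
  whole <- make_split(m, seed = 5)
  folds <- kfold_pairs(m, whole, k = 10, seed = 6)
  expect_length(folds, 10L)
  n_total <- nrow(m)
  for (f in folds) {
    expect_setequal(c(f$validation_ids, f$fold_train_ids), whole$train_ids)
    tr <- unique(m$leaf_id[m$image_id %in% f$fold_train_ids])
    va <- unique(m$leaf_id[m$image_id %in% f$validation_ids])
    expect_length(intersect(tr, va), 0L)
    # 20-80 of an 80% parent: ~16% / ~64% of the whole dataset
    expect_lt(abs(length(f$validation_ids) / n_total - 0.16), 0.02)
    expect_lt(abs(length(f$fold_train_ids) / n_total - 0.64), 0.03)
  }
  expect_length(kfold_pairs(m, whole, k = 1, seed = 1), 1L)
  expect_error(kfold_pairs(m, whole, k = 2, val_fraction = 1.2), "val_fraction")
})

test_that("split_report tabulates sizes, coverage and flags problems", {
  m <- grid_manifest()
  whole <- make_split(m, seed = 7)
  rep <- split_report(whole, m)
  expect_true(rep$leaf_exclusive)
  expect_equal(rep$train_fraction, 0.8, tolerance = 0.05)
  expect_false(rep$empty_test)
  sps <- make_factor_splits(m, "year", seed = 7)
  rep_y <- split_report(sps[["Y1/Y2"]], m)
  expect_true(rep_y$class_sets_equal)
  expect_identical(rep_y$n_common_classes, 7L)
  empty <- leafhair:::new_split("broken", m$image_id, character(), 1L)
  expect_true(split_report(empty, m)$empty_test)
})

test_that("splits and folds round-trip through JSON", {
  m <- grid_manifest()
  s <- make_split(m, seed = 8, name = "whole")
  p <- withr::local_tempfile(fileext = ".json")
  write_split(s, p)
  s2 <- read_split(p)
  expect_identical(s2$train_ids, s$train_ids)
  expect_identical(s2$test_ids, s$test_ids)
  expect_identical(s2$name, s$name)
  f <- kfold_pairs(m, s, k = 1, seed = 9)[[1]]
  pf <- withr::local_tempfile(fileext = ".json")
  write_split(f, pf)
  f2 <- read_split(pf)
  expect_identical(f2$validation_ids, f$validation_ids)
  expect_identical(f2$fold_index, f$fold_index)
})
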