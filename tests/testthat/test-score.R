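# brute-force oracle for the leaf-assignment rule: most common class,
# smallest rank among ties (independent of the package implementation)
oracle_assign <- function(labels) {
  ranks <- match(labels, score_labels()) - 1L
  tab <- table(ranks)
  tied <- as.integer(names(tab)[tab == max(tab)])
  score_labels()[min(tied) + 1L]
}

test_that("image accuracy is the plain fraction correct", {
  ps <- prediction_set(paste0("i", 1:4), c("3", "3", "4", "4"),
                       c("3", "3", "4", "3"))
  expect_equal(image_accuracy(ps), 0.75)
  perm <- sample(4)
  ps2 <- prediction_set(ps$image_id[perm], ps$true[perm], ps$predicted[perm])
  expect_equal(image_accuracy(ps2), 0.75)
  expect_error(image_accuracy(ps[0, ]), "empty")
})

test_that("FIA is restricted to first images with per-leaf denominator", {
  m <- toy_manifest()
  # a1 and b1 are the first images; corrupt only non-first predictions
  ps <- prediction_set(m$image_id, m$score, c("3", "1", "1", "4/4+", "1", "1"))
  expect_equal(first_image_accuracy(ps, m), 1)
  ps2 <- prediction_set(m$image_id, m$score, c("3", "3", "3", "4", "4/4+", "4/4+"))
  expect_equal(first_image_accuracy(ps2, m), 0.5)
  # a leaf missing its first image among predictions is an error
  expect_error(first_image_accuracy(ps[-1, ], m), "is_first")
})

test_that("leaf accuracy applies mode-with-smallest-on-tie", {
  m <- toy_manifest()
  # unique mode
  ps <- prediction_set(m$image_id, m$score,
                       c("4", "4", "4+", "4/4+", "4/4+", "5"))
  la <- leaf_accuracy(ps, m)
  expect_identical(la$per_leaf$assigned,
                   c("4", "4/4+"))
  expect_equal(la$leaf_accuracy, 0.5)  # leafA true 3, leafB true 4/4+
  # two-way tie: {3,3,4,4} -> 3 (smallest score of the tied pair)
  m4 <- as_manifest(rbind(as.data.frame(m),
    data.frame(image_id = "a4", leaf_id = "leafA", genotype = "LINE-X",
               score = "3", leaf_number = 3L, year = "Y1", environment = "GH",
               site = "N", vein_index = 2L, position_index = 2L,
               is_first = FALSE, image_path = "a4.png")))
  ps4 <- prediction_set(c("a1", "a2", "a3", "a4"), rep("3", 4),
                        c("3", "3", "4", "4"))
  expect_identical(leaf_accuracy(ps4, m4)$per_leaf$assigned, "3")
  # three-way tie {3/4, 4, 4+} -> 3/4
  ps3 <- prediction_set(c("a1", "a2", "a3"), rep("3", 3), c("3/4", "4", "4+"))
  expect_identical(leaf_accuracy(ps3, m)$per_leaf$assigned, "3/4")
})

test_that("tie rule matches brute-force enumeration over all multisets", {
  # all prediction multisets of size 1..5 over 3 classes
  classes <- c("3", "3/4", "4")
  for (n in 1:5) {
    combos <- expand.grid(rep(list(classes), n), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      labels <- unlist(combos[i, ], use.names = FALSE)
      expect_identical(leafhair:::modal_smallest(labels), oracle_assign(labels))
    }
  }
})

test_that("normalized confusion rows behave", {
  true <- c(rep("1", 10), rep("2", 10))
  pred <- c(rep("1", 8), rep("2", 2), rep("1", 1), rep("2", 9))
  cm <- normalized_confusion(true, pred)
  expect_equal(unname(cm["1", ]), c(0.8, 0.2))
  expect_equal(unname(cm["2", ]), c(0.1, 0.9))
  expect_equal(unname(rowSums(cm)), c(1, 1))
  # perfect predictions give an identity pattern
  cmp <- normalized_confusion(true, true)
  expect_equal(unname(diag(cmp)), c(1, 1))
  # absent class rows are zero and flagged
  cma <- normalized_confusion(true, pred, classes = c("1", "2", "3"))
  expect_equal(unname(rowSums(cma)), c(1, 1, 0))
  expect_identical(attr(cma, "absent_classes"), "3")
})

test_that("adjacent-error fractions decompose the misprediction fraction", {
  ps <- prediction_set(paste0("i", 1:10), rep("3", 10),
                       c(rep("3", 9), "3/4"))
  expect_equal(unname(adjacent_error_analysis(ps)), c(0.1, 0.1, 0))
  all_ok <- prediction_set("x", "4", "4")
  expect_equal(unname(adjacent_error_analysis(all_ok)), c(0, 0, 0))
  # conservation holds on randomized prediction sets
  withr::with_seed(99, {
    for (trial in 1:1000) {
      n <- sample(1:40, 1)
      ps <- prediction_set(paste0("i", seq_len(n)),
                           sample(score_labels(), n, replace = TRUE),
                           sample(score_labels(), n, replace = TRUE))
      a <- adjacent_error_analysis(ps)
      expect_equal(a[["mispredicted"]], a[["within_one"]] + a[["beyond_one"]])
    }
  })
})

test_that("confusion heat maps render as PNG", {
  cm <- normalized_confusion(c("1", "1", "2"), c("1", "2", "2"))
  p <- withr::local_tempfile(fileext = ".png")
  confusion_heatmap_png(cm, p, cell = 4L)
  img <- png::readPNG(p)
  expect_identical(dim(img), c(8L, 8L, 3L))
  # a 0 cell is white, a 1 cell is the darkest
  expect_equal(img[1, 1, 1], 1 - 0.85 * 0.5, tolerance = 0.01)
})

test_that("accuracy metrics are invariant to image-id relabeling", {
  m <- toy_manifest()
  ps <- prediction_set(m$image_id, m$score, c("3", "1", "3", "4/4+", "4", "4/4+"))
  r1 <- accuracy_report(ps, m)
  m2 <- m; map <- stats::setNames(paste0("z", 1:6), m$image_id)
  m2$image_id <- unname(map[m$image_id])
  m2$image_path <- paste0(m2$image_id, ".png")
  ps2 <- prediction_set(unname(map[ps$image_id]), ps$true, ps$predicted)
  r2 <- accuracy_report(ps2, as_manifest(m2))
  expect_equal(r1$IA, r2$IA)
  expect_equal(r1$FIA, r2$FIA)
  expect_equal(r1$LA, r2$LA)
})
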