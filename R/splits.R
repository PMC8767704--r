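# ---------------------------------------------------------------------
# Dataset split grammar.
#
# The atomic unit of splitting is the leaf group: all images of a
# physical leaf go to the same side of any split, which prevents
# image-level leakage between train and test (images of one leaf are
# near-duplicates).  Split names follow the "TRAIN/TEST" convention
# (e.g. "L3L4/L3", "Y1/Y2", "GH/FD", "whole").
# ---------------------------------------------------------------------

new_split <- function(name, train_ids, test_ids, seed,
                      class_set = NULL) {
  if (length(intersect(train_ids, test_ids)))
    stop("internal error: train/test id overlap in split ", name)
  structure(list(name = name, train_ids = train_ids, test_ids = test_ids,
                 seed = as.integer(seed), class_set = class_set),
            class = "leafhair_split")
}

#' @export
print.leafhair_split <- function(x, ...) {
  cat(sprintf("<split %s: %d train / %d test images, seed %d%s>\n",
              x$name, length(x$train_ids), length(x$test_ids), x$seed,
              if (!is.null(x$class_set))
                paste0(", classes {", paste(x$class_set, collapse = ","), "}")
              else ""))
  invisible(x)
}

#' Group candidate images by leaf
#'
#' @param manifest A manifest.
#' @param candidate_ids Subset of `manifest$image_id` (defaults to all).
#' @return Named list mapping `leaf_id` to the character image ids of
#'   that leaf among the candidates; a partition of `candidate_ids`.
#' @export
group_by_leaf <- function(manifest, candidate_ids = manifest$image_id) {
  stopifnot(all(candidate_ids %in% manifest$image_id))
  sel <- manifest[manifest$image_id %in% candidate_ids, ]
  split(sel$image_id, sel$leaf_id)
}

#' Leaf-group-exclusive train/test split
#'
#' Groups the candidate images by leaf, randomly selects
#' `round(test_fraction * L_n)` of the `L_n` leaf groups as the test
#' set (rounding half up), and places the remaining candidate images —
#' plus any `extra_train_ids` (e.g. all images of the non-test category
#' in a mixed split) — in the training set.  Selection operates on leaf
#' ids sorted lexicographically then shuffled with `seed`, so the split
#' is invariant to manifest row order.
#'
#' @param manifest A manifest.
#' @param candidate_ids Candidate image ids to be partitioned.
#' @param test_fraction Fraction of leaf groups sent to test (in (0,1),
#'   default 0.2).
#' @param seed Integer seed.
#' @param extra_train_ids Image ids appended to the train side; must not
#'   share any leaf with the candidates.
#' @param name Split name.
#' @return A `leafhair_split`.
#' @export
make_split <- function(manifest, candidate_ids = manifest$image_id,
                       test_fraction = 0.2, seed = 1L,
                       extra_train_ids = character(), name = "whole") {
  stopifnot(test_fraction > 0, test_fraction < 1)
  groups <- group_by_leaf(manifest, candidate_ids)
  if (length(groups) < 2L)
    stop("need at least 2 leaf groups to split, got ", length(groups))
  extra_leaves <- unique(manifest$leaf_id[manifest$image_id %in% extra_train_ids])
  if (length(intersect(extra_leaves, names(groups))))
    stop("extra_train_ids share leaf groups with the candidate set")
  leaf_ids <- sort(names(groups), method = "radix")
  n_test <- floor(test_fraction * length(leaf_ids) + 0.5)  # round half up
  n_test <- max(1L, min(n_test, length(leaf_ids) - 1L))
  shuffled <- withr::with_seed(as.integer(seed), sample(leaf_ids))
  test_leaves <- shuffled[seq_len(n_test)]
  test_ids <- unlist(groups[test_leaves], use.names = FALSE)
  train_ids <- c(unlist(groups[setdiff(leaf_ids, test_leaves)], use.names = FALSE),
                 extra_train_ids)
  new_split(name, train_ids, test_ids, seed)
}

factor_levels <- function(factor) {
  switch(factor,
    leaf_number = list(col = "leaf_number", levels = c(3L, 4L),
                       tags = c("L3", "L4")),
    year = list(col = "year", levels = c("Y1", "Y2"), tags = c("Y1", "Y2")),
    environment = list(col = "environment", levels = c("GH", "FD"),
                       tags = c("GH", "FD")),
    stop("unknown split factor: ", factor,
         "; one of leaf_number, year, environment"))
}

#' The six named splits of a factor
#'
#' For a two-category factor (leaf number L3/L4, year Y1/Y2, environment
#' GH/FD) generates, in order: the two *mixed* splits `AB/A`, `AB/B`
#' (test on 20% of one category's leaves, train on the rest plus all of
#' the other category), the two *intra* splits `A/A`, `B/B` (train and
#' test within one category), and the two *inter* splits `A/B`, `B/A`
#' (all of one category in train, all of the other in test).
#'
#' For `factor = "year"` the inter splits first reduce the candidate
#' list to images of genotypes present in both years, then drop score
#' classes not present on both sides of the reduced list; the returned
#' splits carry the common class set in `$class_set` (7 classes for the
#' source dataset's composition).  The intra-year splits likewise record
#' the class set present in their year.
#'
#' @param manifest A manifest containing both factor categories.
#' @param factor One of `"leaf_number"`, `"year"`, `"environment"`.
#' @param seed Integer seed (each of the six splits derives its own seed
#'   as `seed + position`).
#' @return Named list of 6 `leafhair_split` objects.
#' @export
make_factor_splits <- function(manifest, factor = c("leaf_number", "year",
                                                    "environment"),
                               seed = 1L) {
  factor <- match.arg(factor)
  fl <- factor_levels(factor)
  vals <- manifest[[fl$col]]
  present <- fl$levels %in% vals
  if (!all(present))
    stop("factor category absent from manifest: ", fl$tags[!present])
  ids <- list(manifest$image_id[vals == fl$levels[1]],
              manifest$image_id[vals == fl$levels[2]])
  names(ids) <- fl$tags
  A <- fl$tags[1]; B <- fl$tags[2]
  splits <- list()

  # mixed: AB/A, AB/B
  for (i in 1:2) {
    te <- fl$tags[i]; other <- fl$tags[3 - i]
    splits[[paste0(A, B, "/", te)]] <- make_split(
      manifest, ids[[te]], 0.2, seed + i, extra_train_ids = ids[[other]],
      name = paste0(A, B, "/", te))
  }
  # intra: A/A, B/B
  for (i in 1:2) {
    te <- fl$tags[i]
    s <- make_split(manifest, ids[[te]], 0.2, seed + 2L + i,
                    name = paste0(te, "/", te))
    if (factor == "year")
      s$class_set <- sort_classes(unique(manifest$score[vals == fl$levels[i]]))
    splits[[paste0(te, "/", te)]] <- s
  }
  # inter: A/B, B/A
  if (factor == "year") {
    red <- reduce_interyear(manifest)
    for (i in 1:2) {
      tr <- fl$tags[i]; te <- fl$tags[3 - i]
      splits[[paste0(tr, "/", te)]] <- new_split(
        paste0(tr, "/", te), red$ids[[tr]], red$ids[[te]], seed + 4L + i,
        class_set = red$class_set)
    }
  } else {
    for (i in 1:2) {
      tr <- fl$tags[i]; te <- fl$tags[3 - i]
      splits[[paste0(tr, "/", te)]] <- new_split(
        paste0(tr, "/", te), ids[[tr]], ids[[te]], seed + 4L + i)
    }
  }
  splits
}

sort_classes <- function(x) {
  lv <- score_labels()
  lv[lv %in% normalize_score_label(x)]
}

# inter-year reduction: keep images of genotypes grown in both years,
# then keep only score classes present in both reduced year subsets
reduce_interyear <- function(manifest) {
  g1 <- unique(manifest$genotype[manifest$year == "Y1"])
  g2 <- unique(manifest$genotype[manifest$year == "Y2"])
  keep_g <- intersect(g1, g2)
  sel <- manifest[manifest$genotype %in% keep_g, ]
  s1 <- unique(sel$score[sel$year == "Y1"])
  s2 <- unique(sel$score[sel$year == "Y2"])
  common <- sort_classes(intersect(s1, s2))
  sel <- sel[sel$score %in% common, ]
  list(ids = list(Y1 = sel$image_id[sel$year == "Y1"],
                  Y2 = sel$image_id[sel$year == "Y2"]),
       class_set = common)
}

#' Repeated validation-train resampling of a parent split's train set
#'
#' Re-samples the parent split's training leaf groups `k` times
#' independently (not a disjoint partition: the protocol's "randomly
#' sampled k times" with the stated 16%/64% whole-dataset coverage
#' implies independent 20-80% pairs) into leaf-group-exclusive
#' validation / fold-train pairs.
#'
#' @param manifest A manifest.
#' @param parent_split A `leafhair_split` whose train side is resampled.
#' @param k Number of pairs (>= 1, default 10).
#' @param val_fraction Fraction of leaf groups per validation portion
#'   (in (0,1), default 0.2).
#' @param seed Integer seed.
#' @return List of `k` `leafhair_fold` objects with fields `fold_index`,
#'   `validation_ids`, `fold_train_ids`.
#' @export
kfold_pairs <- function(manifest, parent_split, k = 10L, val_fraction = 0.2,
                        seed = 1L) {
  stopifnot(k >= 1, val_fraction > 0, val_fraction < 1)
  lapply(seq_len(k), function(i) {
    s <- make_split(manifest, parent_split$train_ids, val_fraction,
                    seed = seed + i, name = sprintf("fold%02d", i))
    structure(list(fold_index = i, validation_ids = s$test_ids,
                   fold_train_ids = s$train_ids, seed = s$seed),
              class = "leafhair_fold")
  })
}

#' Tabulated summary and integrity report of a split
#'
#' Verifies leaf-group exclusivity, reports train/test sizes, the train
#' fraction, per-class image counts on both sides, train-vs-test class
#' coverage, and per-category counts over leaf number, year and
#' environment.  An empty side is reported as an error flag rather than
#' an exception.
#'
#' @param split A `leafhair_split`.
#' @param manifest The manifest the split was drawn from.
#' @return A `leafhair_split_report` list.
#' @export
split_report <- function(split, manifest) {
  tr <- manifest[manifest$image_id %in% split$train_ids, ]
  te <- manifest[manifest$image_id %in% split$test_ids, ]
  leak <- intersect(unique(tr$leaf_id), unique(te$leaf_id))
  tab <- function(m) list(
    by_class = table(score_factor(m$score)),
    by_leaf_number = table(m$leaf_number),
    by_year = table(m$year),
    by_environment = table(m$environment))
  cls_tr <- sort_classes(unique(tr$score))
  cls_te <- sort_classes(unique(te$score))
  structure(list(
    name = split$name,
    n_train = nrow(tr), n_test = nrow(te),
    n_train_leaves = length(unique(tr$leaf_id)),
    n_test_leaves = length(unique(te$leaf_id)),
    train_fraction = nrow(tr) / max(1L, nrow(tr) + nrow(te)),
    leaf_exclusive = length(leak) == 0L,
    leaking_leaves = leak,
    empty_train = nrow(tr) == 0L, empty_test = nrow(te) == 0L,
    train_classes = cls_tr, test_classes = cls_te,
    class_sets_equal = identical(cls_tr, cls_te),
    n_common_classes = length(intersect(cls_tr, cls_te)),
    train = tab(tr), test = tab(te)),
    class = "leafhair_split_report")
}

#' @export
print.leafhair_split_report <- function(x, ...) {
  cat(sprintf("<split report %s: %d train (%.1f%%) / %d test images; %s%s>\n",
              x$name, x$n_train, 100 * x$train_fraction, x$n_test,
              if (x$leaf_exclusive) "leaf-exclusive" else "LEAF LEAKAGE",
              if (x$empty_test) "; EMPTY TEST" else ""))
  invisible(x)
}

#' Serialize splits and fold pairs as JSON
#'
#' @param x A `leafhair_split` or `leafhair_fold`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_split()` returns the object.
#' @export
write_split <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(o$fold_index))
    structure(list(fold_index = o$fold_index,
                   validation_ids = as.character(o$validation_ids),
                   fold_train_ids = as.character(o$fold_train_ids),
                   seed = as.integer(o$seed)),
              class = "leafhair_fold")
  else
    new_split(o$name, as.character(o$train_ids), as.character(o$test_ids),
              o$seed, class_set = o$class_set)
}
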