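#' A set of aligned predictions
#'
#' Holds one (image id, true class, predicted class) triple per
#' evaluated image.  Labels are normalised to the canonical scale.
#'
#' @param image_id Character vector of unique image ids.
#' @param true,predicted Score labels (aliases allowed).
#' @param split_name Name of the evaluated split.
#' @return A `leafhair_predictions` data.frame.
#' @export
prediction_set <- function(image_id, true, predicted, split_name = "") {
  if (anyDuplicated(image_id)) stop("duplicate image_id in prediction set")
  if (length(true) != length(image_id) || length(predicted) != length(image_id))
    stop("image_id, true and predicted must have equal length")
  out <- data.frame(image_id = as.character(image_id),
                    true = normalize_score_label(true),
                    predicted = normalize_score_label(predicted))
  attr(out, "split_name") <- split_name
  class(out) <- c("leafhair_predictions", "data.frame")
  out
}

#' Image accuracy (IA)
#'
#' Fraction of images whose predicted score equals the ground truth.
#'
#' @param preds A [prediction_set()] (non-empty).
#' @return A fraction in `[0, 1]`.
#' @export
image_accuracy <- function(preds) {
  if (nrow(preds) == 0L) stop("empty prediction set")
  mean(preds$predicted == preds$true)
}

#' First image accuracy (FIA)
#'
#' Image accuracy restricted to each test leaf's single First Image (the
#' most proximal image: vein 1, position 1, `is_first` in the manifest);
#' the denominator is the number of test leaves.  Every evaluated leaf
#' must contribute exactly one `is_first` entry.
#'
#' @param preds A [prediction_set()].
#' @param manifest The manifest resolving image ids to leaves.
#' @return A fraction in `[0, 1]`.
#' @export
first_image_accuracy <- function(preds, manifest) {
  m <- manifest[match(preds$image_id, manifest$image_id), ]
  if (anyNA(m$image_id)) stop("prediction image_id(s) not found in manifest")
  nfirst <- tapply(m$is_first, m$leaf_id, sum)
  bad <- names(nfirst)[nfirst != 1L]
  if (length(bad))
    stop("leaf/leaves without exactly one is_first entry among predictions: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  mean(preds$predicted[m$is_first] == preds$true[m$is_first])
}

# modal class with smallest-rank tie-break over a vector of labels
modal_smallest <- function(labels) {
  r <- score_rank(labels)
  counts <- table(r)
  top <- as.integer(names(counts)[counts == max(counts)])
  score_labels()[min(top) + 1L]
}

#' Leaf accuracy (LA) and per-leaf assigned scores
#'
#' Assigns each test leaf the most common predicted score among its
#' test-side images; when several scores are predicted by equally many
#' images, the smallest score (lowest rank) among the tied ones is
#' assigned.  LA is the fraction of leaves whose assigned score equals
#' the leaf's true score.
#'
#' @param preds A [prediction_set()].
#' @param manifest The manifest resolving image ids to leaves.
#' @return List with `leaf_accuracy`, and `per_leaf`: a data.frame of
#'   `leaf_id`, `true`, `assigned`, `n_images`.
#' @export
leaf_accuracy <- function(preds, manifest) {
  m <- manifest[match(preds$image_id, manifest$image_id), ]
  if (anyNA(m$image_id)) stop("prediction image_id(s) not found in manifest")
  if (nrow(preds) == 0L) stop("empty prediction set")
  leaves <- unique(m$leaf_id)
  per <- do.call(rbind, lapply(leaves, function(lf) {
    sel <- m$leaf_id == lf
    data.frame(leaf_id = lf,
               true = preds$true[sel][1],
               assigned = modal_smallest(preds$predicted[sel]),
               n_images = sum(sel))
  }))
  list(leaf_accuracy = mean(per$assigned == per$true), per_leaf = per)
}

#' Row-normalized confusion matrix
#'
#' Rows are indexed by true class, columns by predicted class, over the
#' canonical scale restricted to `classes`; each row is divided by its
#' count.  Rows for absent classes are all-zero and flagged in the
#' `"absent_classes"` attribute.
#'
#' @param true,predicted Score label vectors (e.g. columns of a
#'   [prediction_set()], or per-leaf assignments).
#' @param classes Class labels indexing the matrix (default: all classes
#'   present in either vector).
#' @return A square matrix with rows summing to 1 (or 0 for absent
#'   classes).
#' @export
normalized_confusion <- function(true, predicted,
                                 classes = sort_classes(unique(c(true, predicted)))) {
  if (length(true) == 0L) stop("empty input")
  true <- factor(normalize_score_label(true), levels = classes)
  predicted <- factor(normalize_score_label(predicted), levels = classes)
  cm <- table(true, predicted)
  n <- rowSums(cm)
  out <- unclass(cm)
  out[n > 0, ] <- out[n > 0, , drop = FALSE] / n[n > 0]
  attr(out, "absent_classes") <- classes[n == 0]
  out
}

#' Adjacent-class error analysis
#'
#' Decomposes the misprediction fraction by ordinal distance: the
#' fraction of images mispredicted at all, the fraction predicted into
#' one of the two neighbouring classes (|rank difference| = 1), and the
#' fraction predicted two or more classes away.  By construction
#' `mispredicted = within_one + beyond_one`.
#'
#' @param preds A [prediction_set()].
#' @return Named numeric vector `c(mispredicted, within_one,
#'   beyond_one)`.
#' @export
adjacent_error_analysis <- function(preds) {
  if (nrow(preds) == 0L) stop("empty prediction set")
  d <- abs(score_rank(preds$predicted) - score_rank(preds$true))
  c(mispredicted = mean(d > 0),
    within_one = mean(d == 1),
    beyond_one = mean(d >= 2))
}

#' Full accuracy report for one evaluation
#'
#' Bundles IA, FIA, LA, the three row-normalized confusion matrices
#' (per image, per first image, per leaf assignment) and the
#' adjacent-class error fractions.
#'
#' @param preds A [prediction_set()].
#' @param manifest The manifest resolving image ids to leaves.
#' @return A `leafhair_report` list.
#' @export
accuracy_report <- function(preds, manifest) {
  m <- manifest[match(preds$image_id, manifest$image_id), ]
  la <- leaf_accuracy(preds, manifest)
  adj <- adjacent_error_analysis(preds)
  classes <- sort_classes(unique(c(preds$true, preds$predicted)))
  first <- m$is_first
  structure(list(
    split_name = attr(preds, "split_name"),
    IA = image_accuracy(preds),
    FIA = first_image_accuracy(preds, manifest),
    LA = la$leaf_accuracy,
    per_leaf = la$per_leaf,
    confusion_IA = normalized_confusion(preds$true, preds$predicted, classes),
    confusion_FIA = normalized_confusion(preds$true[first], preds$predicted[first],
                                         classes),
    confusion_LA = normalized_confusion(la$per_leaf$true, la$per_leaf$assigned,
                                        classes),
    adjacent_error_fraction = adj[["within_one"]],
    off_by_more_fraction = adj[["beyond_one"]],
    mispredicted_fraction = adj[["mispredicted"]]),
    class = "leafhair_report")
}

#' @export
print.leafhair_report <- function(x, ...) {
  cat(sprintf("<accuracy report%s: IA %.4f, FIA %.4f, LA %.4f (off-by-1 %.4f, beyond %.4f)>\n",
              if (nzchar(x$split_name)) paste0(" ", x$split_name) else "",
              x$IA, x$FIA, x$LA, x$adjacent_error_fraction,
              x$off_by_more_fraction))
  invisible(x)
}

#' Serialize an accuracy report
#'
#' JSON for the scalar metrics and row-normalized matrices; optionally
#' CSV files for the confusion matrices alongside.
#'
#' @param report A `leafhair_report`.
#' @param path Output JSON path.
#' @param csv_matrices Also write `<path>_confusion_{IA,FIA,LA}.csv`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv_matrices = FALSE) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  payload <- list(split_name = report$split_name, IA = report$IA,
                  FIA = report$FIA, LA = report$LA,
                  adjacent_error_fraction = report$adjacent_error_fraction,
                  off_by_more_fraction = report$off_by_more_fraction,
                  mispredicted_fraction = report$mispredicted_fraction,
                  confusion_IA = report$confusion_IA,
                  confusion_FIA = report$confusion_FIA,
                  confusion_LA = report$confusion_LA)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (csv_matrices) {
    base <- tools::file_path_sans_ext(path)
    for (nm in c("confusion_IA", "confusion_FIA", "confusion_LA"))
      utils::write.csv(report[[nm]], paste0(base, "_", nm, ".csv"))
  }
  invisible(path)
}

#' Render a confusion matrix as a PNG heat map
#'
#' A minimal dependency-free heat map: cells scale from white (0) to a
#' deep blue (1), upscaled by an integer factor per cell.
#'
#' @param cm A row-normalized confusion matrix.
#' @param path Output PNG path.
#' @param cell Pixels per matrix cell.
#' @return `path`, invisibly.
#' @export
confusion_heatmap_png <- function(cm, path, cell = 24L) {
  v <- pmin(pmax(as.matrix(cm), 0), 1)
  up <- v[rep(seq_len(nrow(v)), each = cell), rep(seq_len(ncol(v)), each = cell)]
  img <- array(0, c(nrow(up), ncol(up), 3))
  img[, , 1] <- 1 - 0.85 * up
  img[, , 2] <- 1 - 0.60 * up
  img[, , 3] <- 1 - 0.15 * up
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(img, path)
  invisible(path)
}

#' Test-time Gaussian-noise robustness sweep
#'
#' Re-evaluates a trained model on the test images under additive
#' Gaussian noise applied after resize (before normalisation), for every
#' (sigma, p) cell of the grid.  Rows with `sigma = 0` or `p = 0` equal
#' the clean evaluation exactly.
#'
#' @param model A list with `extractor` and `head` (e.g. from
#'   [train_model()]'s result or [load_checkpoint()]).
#' @param manifest The manifest.
#' @param test_ids Image ids to evaluate.
#' @param sigmas,probabilities Numeric grids.
#' @param augment The evaluation [augment_config()] (for target size and
#'   normalisation statistics).
#' @param seed Integer seed for the noise draws.
#' @param images Optional pre-loaded named list of `[0,1]` image arrays
#'   (bypasses PNG reads).
#' @return data.frame with columns `sigma`, `p`, `IA`, `FIA`, `LA`.
#' @export
noise_robustness_sweep <- function(model, manifest, test_ids,
                                   sigmas = c(0, 0.05, 0.1),
                                   probabilities = 1,
                                   augment = augment_config(),
                                   seed = 1L, images = NULL) {
  stopifnot(all(sigmas >= 0), all(probabilities >= 0 & probabilities <= 1))
  sel <- manifest[manifest$image_id %in% test_ids, ]
  if (is.null(images)) {
    images <- lapply(sel$image_path, read_image_array)
    names(images) <- sel$image_id
  }
  resized <- lapply(images[sel$image_id], resize_image, target = augment$target_size)
  grid <- expand.grid(sigma = sigmas, p = probabilities)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sg <- grid$sigma[i]; pp <- grid$p[i]
    preds <- withr::with_seed(as.integer(seed) + i, {
      noised <- lapply(resized, function(im)
        gaussian_noise(im, sg, pp, clip_range = c(0, 1)))
      predict_images(model, noised, augment, already_resized = TRUE)
    })
    ps <- prediction_set(sel$image_id, sel$score, preds,
                         sprintf("noise sigma=%g p=%g", sg, pp))
    la <- leaf_accuracy(ps, manifest)
    data.frame(sigma = sg, p = pp,
               IA = image_accuracy(ps),
               FIA = first_image_accuracy(ps, manifest),
               LA = la$leaf_accuracy)
  })
  do.call(rbind, rows)
}

#' Read an image file into a `[0, 1]` H x W x 3 array
#'
#' @param path PNG or JPEG file.
#' @return Numeric array.
#' @export
read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  im <- if (ext %in% c("jpg", "jpeg")) jpeg::readJPEG(path) else png::readPNG(path)
  if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3L))
  if (dim(im)[3] > 3L) im <- im[, , 1:3, drop = FALSE]
  im
}

# predict class labels for a named list of [0,1] images
predict_images <- function(model, images, augment, already_resized = FALSE,
                           batch_size = 32L) {
  classes <- model$classes
  if (is.null(classes)) classes <- score_labels()
  prepped <- lapply(images, function(im) {
    if (!already_resized) im <- resize_image(im, augment$target_size)
    normalize_image(im, augment$normalize_mean, augment$normalize_std)
  })
  n <- length(prepped)
  out <- character(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    logits <- net_forward(model$extractor, model$head, prepped[idx])
    out[idx] <- classes[max.col(logits, ties.method = "first")]
  }
  out
}
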