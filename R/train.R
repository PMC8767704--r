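# ---------------------------------------------------------------------
# Optimizers.  State lives in the layer environments next to the
# parameters themselves (fields m_W, v_W, ... per parameter).
# ---------------------------------------------------------------------

optimizer_names <- function() c("Adam", "AdamW", "RMSProp", "SGD")

new_optimizer <- function(name, lr, weight_decay = 0.01) {
  if (!name %in% optimizer_names())
    stop("unsupported optimizer ", sQuote(name), "; one of: ",
         paste(optimizer_names(), collapse = ", "))
  env <- new.env(parent = emptyenv())
  env$name <- name; env$lr <- lr; env$t <- 0L
  env$beta1 <- 0.9; env$beta2 <- 0.999; env$eps <- 1e-8
  env$alpha <- 0.99              # RMSProp smoothing
  env$weight_decay <- weight_decay  # AdamW only (decoupled)
  env
}

opt_update_param <- function(opt, ly, pname) {
  g <- ly[[paste0("d", pname)]]
  if (is.null(g)) return(invisible())
  x <- ly[[pname]]
  switch(opt$name,
    SGD = { x <- x - opt$lr * g },
    RMSProp = {
      vkey <- paste0("v_", pname)
      v <- if (is.null(ly[[vkey]])) g * 0 else ly[[vkey]]
      v <- opt$alpha * v + (1 - opt$alpha) * g^2
      ly[[vkey]] <- v
      x <- x - opt$lr * g / (sqrt(v) + opt$eps)
    },
    Adam = , AdamW = {
      mkey <- paste0("m_", pname); vkey <- paste0("v_", pname)
      m <- if (is.null(ly[[mkey]])) g * 0 else ly[[mkey]]
      v <- if (is.null(ly[[vkey]])) g * 0 else ly[[vkey]]
      m <- opt$beta1 * m + (1 - opt$beta1) * g
      v <- opt$beta2 * v + (1 - opt$beta2) * g^2
      ly[[mkey]] <- m; ly[[vkey]] <- v
      mhat <- m / (1 - opt$beta1^opt$t)
      vhat <- v / (1 - opt$beta2^opt$t)
      if (opt$name == "AdamW" && pname == "W")
        x <- x - opt$lr * opt$weight_decay * x
      x <- x - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    })
  ly[[pname]] <- x
  ly[[paste0("d", pname)]] <- NULL
  invisible()
}

opt_step <- function(opt, layers) {
  opt$t <- opt$t + 1L
  for (ly in layers)
    for (p in c("W", "b", "gamma", "beta"))
      if (!is.null(ly[[p]])) opt_update_param(opt, ly, p)
  invisible()
}

#' Training configuration
#'
#' @param optimizer One of `"Adam"` (default, the selected optimizer),
#'   `"AdamW"`, `"RMSProp"`, `"SGD"`.
#' @param learning_rate Positive learning rate; default `1e-4`, the
#'   protocol's untuned default.  (Desk-scale training of the `"tiny"`
#'   backbone from scratch typically uses `1e-3`; see the vignette.)
#' @param epochs Number of passes over the training set (>= 1; default
#'   10 at test scale, 30 at full scale).
#' @param batch_size Minibatch size (default 16 at test scale, 32 full
#'   scale).
#' @param n_runs Independent runs per experiment (default 5); run `r`
#'   uses seed `seed + r`.
#' @param seed Base seed.
#' @param augmentation An [augment_config()] applied to training images
#'   only; evaluation always uses resize + normalize.
#' @param network A [network_config()].
#' @param weight_averaging If `TRUE` (default), evaluate with a Polyak
#'   (exponential moving) average of the weights (decay 0.99 per step)
#'   instead of the raw final-step weights.  This is an optimizer-level
#'   variance reduction, not model selection: no validation data and no
#'   early stopping are involved, and it markedly stabilises short
#'   (10-epoch) from-scratch runs of the tiny backbone.
#' @return A `leafhair_train_config`.
#' @export
train_config <- function(optimizer = "Adam", learning_rate = 1e-4,
                         epochs = 10L, batch_size = 16L, n_runs = 5L,
                         seed = 1L,
                         augmentation = augment_config(target_size = 64L),
                         network = network_config("tiny"),
                         weight_averaging = TRUE) {
  if (!optimizer %in% optimizer_names())
    stop("unsupported optimizer ", sQuote(optimizer), "; one of: ",
         paste(optimizer_names(), collapse = ", "))
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, n_runs >= 1)
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 augmentation = augmentation, network = network,
                 weight_averaging = isTRUE(weight_averaging)),
            class = "leafhair_train_config")
}

ema_params <- function(ly) {
  switch(ly$type, conv = c("W", "b"), bn = c("gamma", "beta"),
         linear = c("W", "b"), character())
}

# bias-corrected exponential moving average (as in Adam's moment
# estimates): short runs average the trajectory instead of being
# dominated by the initial weights
ema_update <- function(layers, decay) {
  for (ly in layers) for (p in ema_params(ly)) {
    if (is.null(ly[[p]])) next
    key <- paste0("ema_", p)
    prev <- if (is.null(ly[[key]])) 0 else ly[[key]]
    ly[[key]] <- decay * prev + (1 - decay) * ly[[p]]
  }
  invisible()
}

ema_apply <- function(layers, decay, t) {
  corr <- 1 - decay^t
  for (ly in layers) for (p in ema_params(ly)) {
    key <- paste0("ema_", p)
    if (!is.null(ly[[key]])) { ly[[p]] <- ly[[key]] / corr; ly[[key]] <- NULL }
  }
  invisible()
}

load_image_cache <- function(manifest, ids, base_size) {
  sel <- manifest[match(ids, manifest$image_id), ]
  imgs <- lapply(sel$image_path, function(p)
    resize_image(read_image_array(p), base_size))
  names(imgs) <- sel$image_id
  imgs
}

# per-image stochastic training transform operating on the cached
# base-size image (already resized to intermediate or target size)
train_transform <- function(cfg_aug, has_crop) {
  ops <- setdiff(cfg_aug$ops, c("resize", "normalize", "random_crop"))
  target <- cfg_aug$target_size
  function(im) {
    if (has_crop) {
      slack <- cfg_aug$intermediate_size - target
      ox <- if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
      oy <- if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
      im <- im[oy + seq_len(target), ox + seq_len(target), , drop = FALSE]
    }
    for (op in ops) {
      im <- switch(op,
        rv_flip = rv_flip(im, cfg_aug$flip_p),
        rh_flip = rh_flip(im, cfg_aug$flip_p),
        random_rotation = random_rotation(im, cfg_aug$rotation_range,
                                          fill = cfg_aug$normalize_mean),
        gaussian_noise = gaussian_noise(im, cfg_aug$noise_sigma, cfg_aug$noise_p))
    }
    normalize_image(im, cfg_aug$normalize_mean, cfg_aug$normalize_std)
  }
}

#' Train a model on one split
#'
#' Minimises multi-class cross-entropy between prediction vectors and
#' ground-truth classes over the split's training images (augmentation
#' applied per epoch), then evaluates on the test side with the
#' deterministic resize + normalize transform.  The class set is
#' inferred from the classes present in the training images; a class
#' present only in the test set is recorded as a warning in the result
#' (its images can never be predicted correctly).  An id-set audit
#' verifies after every epoch that no test image (nor any image of a
#' test leaf) entered the training set.
#'
#' @param manifest A manifest whose `image_path`s exist.
#' @param split A `leafhair_split`.
#' @param config A [train_config()].
#' @param run_index Run number (the run seed is `config$seed +
#'   run_index`).
#' @param image_cache Optional pre-loaded named list of `[0,1]` arrays
#'   at original resolution keyed by image id (bypasses PNG reads).
#' @return A `leafhair_run` list: `run_index`, `seed`, `extractor`,
#'   `head`, `classes`, `loss_trace` (length `epochs`), `report` (an
#'   [accuracy_report()]), `warnings`, `train_size`.
#' @export
train_model <- function(manifest, split, config = train_config(),
                        run_index = 1L, image_cache = NULL) {
  stopifnot(inherits(split, "leafhair_split"))
  train_ids <- split$train_ids
  test_ids <- split$test_ids
  if (length(train_ids) == 0L) stop("split has an empty training set")
  run_seed <- config$seed + as.integer(run_index)

  tr <- manifest[match(train_ids, manifest$image_id), ]
  te <- manifest[match(test_ids, manifest$image_id), ]
  classes <- sort_classes(unique(tr$score))
  if (!is.null(split$class_set)) classes <- split$class_set
  warnings <- character()
  missing_cls <- setdiff(unique(te$score), classes)
  if (length(missing_cls)) {
    warnings <- c(warnings, paste0(
      "class(es) present in test but absent in train: ",
      paste(missing_cls, collapse = ", "),
      "; predictions are restricted to the training classes"))
  }

  aug <- config$augmentation
  has_crop <- "random_crop" %in% aug$ops
  base_size <- if (has_crop) aug$intermediate_size else aug$target_size
  cache_at <- function(ids, size) {
    if (is.null(image_cache)) return(load_image_cache(manifest, ids, size))
    out <- lapply(image_cache[ids], resize_image, target = size)
    names(out) <- ids
    out
  }
  train_imgs <- cache_at(train_ids, base_size)
  test_imgs <- cache_at(test_ids, aug$target_size)

  n_classes <- length(classes)
  targets_all <- match(tr$score, classes)
  keep <- !is.na(targets_all)  # train-side images of classes outside class_set
  if (any(!keep)) {
    warnings <- c(warnings, paste0(sum(!keep), " training image(s) outside ",
                                   "the split's class set were dropped"))
  }
  transform <- train_transform(aug, has_crop)

  net_cfg <- config$network
  net_cfg$n_classes <- n_classes
  result <- withr::with_seed(run_seed, {
    extractor <- build_feature_extractor(net_cfg,
                                         seed = sample.int(2^31 - 1, 1))
    head <- build_classifier(feature_dim(extractor), n_classes,
                             init = net_cfg$head_init,
                             seed = sample.int(2^31 - 1, 1))
    opt <- new_optimizer(config$optimizer, config$learning_rate)
    tlayers <- c(trainable_layers(extractor$layers), list(head))
    idx_pool <- which(keep)
    loss_trace <- numeric(config$epochs)
    test_leaves <- unique(te$leaf_id)
    for (epoch in seq_len(config$epochs)) {
      order <- sample(idx_pool)
      total <- 0; nb <- 0L
      for (start in seq(1L, length(order), by = config$batch_size)) {
        bi <- order[start:min(length(order), start + config$batch_size - 1L)]
        xb <- array(0, c(aug$target_size, aug$target_size, 3L, length(bi)))
        for (j in seq_along(bi))
          xb[, , , j] <- transform(train_imgs[[bi[j]]])
        ce <- cross_entropy(forward_train(extractor, head, xb), targets_all[bi])
        backward_train(extractor, head, ce$dlogits)
        opt_step(opt, tlayers)
        if (config$weight_averaging) ema_update(tlayers, 0.99)
        total <- total + ce$loss; nb <- nb + 1L
      }
      loss_trace[epoch] <- total / nb
      # leakage audit: training pool must touch no test image or test leaf
      audit_ids <- train_ids[idx_pool]
      if (length(intersect(audit_ids, test_ids)) ||
          length(intersect(unique(manifest$leaf_id[manifest$image_id %in% audit_ids]),
                           test_leaves)))
        stop("leakage audit failed at epoch ", epoch)
    }
    if (config$weight_averaging) ema_apply(tlayers, 0.99, opt$t)
    model <- list(extractor = extractor, head = head, classes = classes)
    pred <- predict_images(model, test_imgs, aug, already_resized = TRUE)
    ps <- prediction_set(te$image_id, te$score, pred,
                         split_name = split$name)
    report <- accuracy_report(ps, manifest)
    list(run_index = as.integer(run_index), seed = run_seed,
         extractor = extractor, head = head, classes = classes,
         loss_trace = loss_trace, report = report, warnings = warnings,
         train_size = sum(keep))
  })
  class(result) <- "leafhair_run"
  result
}

#' @export
print.leafhair_run <- function(x, ...) {
  cat(sprintf("<run %d (seed %d): train size %d, final loss %.4f, IA %.4f, FIA %.4f, LA %.4f>\n",
              x$run_index, x$seed, x$train_size, x$loss_trace[length(x$loss_trace)],
              x$report$IA, x$report$FIA, x$report$LA))
  invisible(x)
}

#' Multi-run experiment with mean/min/max aggregation
#'
#' Trains `config$n_runs` independent runs (seeds `seed + 1 ..
#' seed + n_runs`) on each provided split and aggregates IA, FIA and LA
#' into mean, min and max per split, plus the training-set size.
#'
#' @param manifest A manifest.
#' @param splits A named list of `leafhair_split`s (or a single split).
#' @param config A [train_config()].
#' @param image_cache Optional pre-loaded image list shared across runs.
#' @return List with `runs` (per split) and `summary`: a data.frame with
#'   one row per split and columns `split`, `train_size`, and
#'   `{IA,FIA,LA}_{mean,min,max}`.
#' @export
run_experiment <- function(manifest, splits, config = train_config(),
                           image_cache = NULL) {
  if (inherits(splits, "leafhair_split")) splits <- stats::setNames(list(splits), splits$name)
  all_runs <- list()
  rows <- lapply(names(splits), function(nm) {
    runs <- lapply(seq_len(config$n_runs), function(r)
      train_model(manifest, splits[[nm]], config, run_index = r,
                  image_cache = image_cache))
    all_runs[[nm]] <<- runs
    met <- function(f) vapply(runs, function(r) r$report[[f]], numeric(1))
    ia <- met("IA"); fia <- met("FIA"); la <- met("LA")
    data.frame(split = nm, train_size = runs[[1]]$train_size,
               IA_mean = mean(ia), IA_min = min(ia), IA_max = max(ia),
               FIA_mean = mean(fia), FIA_min = min(fia), FIA_max = max(fia),
               LA_mean = mean(la), LA_min = min(la), LA_max = max(la))
  })
  list(runs = all_runs, summary = do.call(rbind, rows))
}
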