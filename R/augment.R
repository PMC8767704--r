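#' ImageNet channel statistics
#'
#' Channel means and standard deviations of the ImageNet corpus, the
#' default normalisation statistics because the feature extractor is
#' (optionally) initialised from ImageNet-pretrained weights.
#'
#' @return Numeric vector of length 3 (R, G, B).
#' @export
imagenet_mean <- function() c(0.485, 0.456, 0.406)

#' @rdname imagenet_mean
#' @export
imagenet_std <- function() c(0.229, 0.224, 0.225)

# 1-D bilinear interpolation matrix mapping a length-`n_in` axis to
# `n_out` samples (pixel-centre convention)
interp_matrix <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  x0 <- floor(src)
  f <- src - x0
  x0 <- pmin(pmax(x0, 1L), n_in)
  x1 <- pmin(x0 + 1L, n_in)
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), x0)] <- A[cbind(seq_len(n_out), x0)] + (1 - f)
  A[cbind(seq_len(n_out), x1)] <- A[cbind(seq_len(n_out), x1)] + f
  A
}

#' Resize an image to a square by plain down/up-sampling
#'
#' Bilinear resampling that stretches to `target x target` without
#' preserving aspect ratio, mirroring the pipeline's Resize step
#' (2560 x 1920 inputs are resized to 448 x 448).
#'
#' @param image `H x W x 3` numeric array.
#' @param target Output side in pixels (> 0).
#' @return `target x target x 3` array.
#' @export
resize_image <- function(image, target = 448L) {
  if (target <= 0) stop("`target` must be positive")
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("`image` must be H x W x 3")
  if (d[1] == target && d[2] == target) return(image)
  Ah <- interp_matrix(target, d[1])
  Aw <- t(interp_matrix(target, d[2]))
  out <- array(0, dim = c(target, target, 3L))
  for (ch in 1:3) out[, , ch] <- Ah %*% image[, , ch] %*% Aw
  out
}

#' Normalise an image with per-channel statistics
#'
#' `(x - mean_c) / std_c` per channel; defaults are the ImageNet
#' statistics of the pretraining corpus.
#'
#' @param image `H x W x 3` array on the `[0, 1]` scale.
#' @param mean,std Numeric length-3 channel statistics; `std` entries
#'   must be non-zero.
#' @return Normalised array (unbounded scale).
#' @export
normalize_image <- function(image, mean = imagenet_mean(), std = imagenet_std()) {
  if (any(std == 0)) stop("normalisation std must be non-zero")
  for (ch in 1:3) image[, , ch] <- (image[, , ch] - mean[ch]) / std[ch]
  image
}

#' Random vertical / horizontal flips
#'
#' With probability `p` the rows (`rv_flip`, vertical flip) or columns
#' (`rh_flip`, horizontal flip) are reversed; otherwise the image is
#' returned unchanged.  Uses the session RNG.
#'
#' @param image `H x W x 3` array.
#' @param p Flip probability in `[0, 1]` (default 0.5, the value selected
#'   after a probability sweep in the source protocol).
#' @return Possibly flipped image.
#' @export
rv_flip <- function(image, p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  if (stats::runif(1) < p) image[rev(seq_len(dim(image)[1])), , , drop = FALSE] else image
}

#' @rdname rv_flip
#' @export
rh_flip <- function(image, p = 0.5) {
  stopifnot(p >= 0, p <= 1)
  if (stats::runif(1) < p) image[, rev(seq_len(dim(image)[2])), , drop = FALSE] else image
}

#' Random crop after an intermediate resize
#'
#' Resizes to `intermediate x intermediate`, then extracts a
#' `target x target` window at an integer offset drawn uniformly from
#' `[0, intermediate - target]^2` (512 -> 448 in the full-scale
#' pipeline).  `intermediate == target` degenerates to plain resize.
#'
#' @param image `H x W x 3` array.
#' @param intermediate Intermediate square side (>= `target`).
#' @param target Output square side.
#' @return `target x target x 3` array.
#' @export
random_crop <- function(image, intermediate = 512L, target = 448L) {
  if (intermediate < target)
    stop("`intermediate` (", intermediate, ") must be >= `target` (", target, ")")
  im <- resize_image(image, intermediate)
  slack <- intermediate - target
  ox <- if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
  oy <- if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
  im[oy + seq_len(target), ox + seq_len(target), , drop = FALSE]
}

#' Random rotation about the image centre
#'
#' Rotates by an angle drawn uniformly from `[-max_deg, +max_deg]`
#' degrees of arc, with bilinear resampling; output has the same
#' dimensions and exposed corners are filled with a constant per-channel
#' fill value (default: the dataset/pretraining channel means, so no
#' artificial black-corner cue is injected).
#'
#' @param image `H x W x 3` array.
#' @param max_deg Maximum absolute rotation angle in degrees (>= 0;
#'   default 30).
#' @param fill Length-3 per-channel fill value.
#' @param angle Optional forced angle in degrees (bypasses the RNG; used
#'   for testing inverse pairs).
#' @return Rotated image.
#' @export
random_rotation <- function(image, max_deg = 30, fill = imagenet_mean(),
                            angle = NULL) {
  stopifnot(max_deg >= 0)
  if (is.null(angle)) angle <- stats::runif(1, -max_deg, max_deg)
  if (angle == 0) return(image)
  d <- dim(image)
  H <- d[1]; W <- d[2]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- rep(seq_len(H), times = W) - cy
  gx <- rep(seq_len(W), each = H) - cx
  # inverse mapping: sample the source at the back-rotated coordinate
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  valid <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
  out <- array(0, dim = d)
  i00 <- (x0 - 1) * H + y0
  for (ch in 1:3) {
    m <- image[, , ch]
    v <- rep(fill[ch], H * W)
    vi <- i00[valid]
    v[valid] <- m[vi] * (1 - fx[valid]) * (1 - fy[valid]) +
      m[vi + H] * fx[valid] * (1 - fy[valid]) +
      m[vi + 1] * (1 - fx[valid]) * fy[valid] +
      m[vi + H + 1] * fx[valid] * fy[valid]
    out[, , ch] <- v
  }
  out
}

#' Additive Gaussian (white) noise
#'
#' With probability `p`, adds i.i.d. zero-mean Gaussian noise of standard
#' deviation `sigma` to every channel, clipped to the valid intensity
#' range.  Used both as an optional training augmentation and as the
#' test-time perturbation of the noise-robustness harness.
#'
#' @param image Numeric image array.
#' @param sigma Noise standard deviation in the image's intensity units
#'   (>= 0).
#' @param p Probability of applying noise.
#' @param clip_range Valid intensity range to clip to.
#' @return Possibly noised image.
#' @export
gaussian_noise <- function(image, sigma, p = 1, clip_range = c(0, 1)) {
  stopifnot(sigma >= 0, p >= 0, p <= 1)
  if (sigma == 0 || stats::runif(1) >= p) return(image)
  image <- image + array(stats::rnorm(length(image), 0, sigma), dim = dim(image))
  pmin(pmax(image, clip_range[1]), clip_range[2])
}

#' Augmentation configuration and composition
#'
#' `augment_config()` describes the Data Augmentation module: the
#' deterministic `resize` and `normalize` steps are always present;
#' optional stochastic techniques (`rv_flip`, `rh_flip`, `random_crop`,
#' `random_rotation`, `gaussian_noise`) are listed in application order.
#' When `random_crop` is listed it subsumes the plain resize (resize to
#' `intermediate_size` then crop to `target_size`); it is applied before
#' flips, matching the combined-technique ordering of the source
#' pipeline.  Evaluation uses resize + normalize only (no test-time
#' augmentation).
#'
#' `compose_augmentation()` turns a config into a single
#' `function(image)` emitting `target_size x target_size x 3` float
#' arrays; it consumes the session RNG, so wrap calls in
#' [withr::with_seed()] for reproducibility.
#'
#' @param ops Character vector of optional stochastic op names (possibly
#'   empty), drawn from the set above; `"resize"`/`"normalize"` may be
#'   listed but are implied.
#' @param target_size Output side in pixels (default 448).
#' @param intermediate_size Intermediate side for `random_crop` (default
#'   512; must be >= `target_size`).
#' @param flip_p Flip probability (default 0.5).
#' @param rotation_range Max rotation in degrees (default 30).
#' @param noise_sigma,noise_p Gaussian-noise parameters.
#' @param normalize_mean,normalize_std Channel statistics.
#' @return `augment_config()`: a `leafhair_augment_config`;
#'   `compose_augmentation()`: a function.
#' @export
augment_config <- function(ops = character(), target_size = 448L,
                           intermediate_size = 512L, flip_p = 0.5,
                           rotation_range = 30, noise_sigma = 0.05,
                           noise_p = 1,
                           normalize_mean = imagenet_mean(),
                           normalize_std = imagenet_std()) {
  known <- c("resize", "normalize", "rv_flip", "rh_flip", "random_crop",
             "random_rotation", "gaussian_noise")
  bad <- setdiff(ops, known)
  if (length(bad))
    stop("unknown augmentation op(s): ", paste(sQuote(bad), collapse = ", "),
         "; known ops: ", paste(known, collapse = ", "))
  stopifnot(flip_p >= 0, flip_p <= 1, noise_p >= 0, noise_p <= 1,
            rotation_range >= 0, noise_sigma >= 0)
  if (intermediate_size < target_size)
    stop("intermediate_size must be >= target_size")
  structure(list(ops = ops, target_size = as.integer(target_size),
                 intermediate_size = as.integer(intermediate_size),
                 flip_p = flip_p, rotation_range = rotation_range,
                 noise_sigma = noise_sigma, noise_p = noise_p,
                 normalize_mean = normalize_mean,
                 normalize_std = normalize_std),
            class = "leafhair_augment_config")
}

#' @rdname augment_config
#' @param config A `leafhair_augment_config`.
#' @export
compose_augmentation <- function(config) {
  stopifnot(inherits(config, "leafhair_augment_config"))
  ops <- setdiff(config$ops, c("resize", "normalize"))
  has_crop <- "random_crop" %in% ops
  ops <- setdiff(ops, "random_crop")
  function(image) {
    im <- if (has_crop)
      random_crop(image, config$intermediate_size, config$target_size)
    else
      resize_image(image, config$target_size)
    for (op in ops) {
      im <- switch(op,
        rv_flip = rv_flip(im, config$flip_p),
        rh_flip = rh_flip(im, config$flip_p),
        random_rotation = random_rotation(im, config$rotation_range,
                                          fill = config$normalize_mean),
        gaussian_noise = gaussian_noise(im, config$noise_sigma, config$noise_p))
    }
    normalize_image(im, config$normalize_mean, config$normalize_std)
  }
}

#' The evaluation-time transform: resize + normalize only
#'
#' @param config A `leafhair_augment_config`.
#' @return A deterministic `function(image)`.
#' @export
evaluation_transform <- function(config) {
  compose_augmentation(augment_config(
    ops = character(), target_size = config$target_size,
    normalize_mean = config$normalize_mean,
    normalize_std = config$normalize_std))
}
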