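#' Configuration for the synthetic leaf-image generator
#'
#' The generator emulates the structure of the abaxial leaf-microscopy
#' dataset: a horizontal mid-vein whose two ends are always cut by the
#' left and right image borders (never top/bottom), bright hair strokes
#' (sunlight-reflecting trichomes) anchored on or near the vein, 9-15
#' images per leaf taken as 3-5 positions along each of 3 veins, and
#' per-(year, environment) style shifts (global brightness and background
#' clutter) so that inter-environment splits face a genuine domain gap.
#'
#' Hairiness classes are realised purely as monotone stroke density and
#' stroke length: expected stroke count is
#' `hair_density_base * density_mult[rank + 1] * image_width / 256`,
#' strictly increasing in rank with rank 0 ("1", glabrous) at exactly 0.
#'
#' The default image size is the test-scale 256 x 192 (an
#' aspect-preserving 1/10 of the source instrument's 2560 x 1920); the
#' full size is available by overriding `image_width`/`image_height`.
#'
#' @param image_width,image_height Image size in pixels (min 32).
#' @param images_per_leaf_range Inclusive integer interval, within
#'   `[1, 50]`, from which the per-leaf image count is drawn uniformly.
#' @param plants_per_genotype Plants imaged per genotype x condition.
#' @param leaf_numbers Leaf positions imaged per plant (L3/L4).
#' @param hair_density_base Expected strokes at unit density multiplier
#'   for a 256-px-wide image.
#' @param density_mult Strictly increasing multiplier per rank 0..8;
#'   first element must be 0 (glabrous).
#' @param hair_length_base Stroke length scale in pixels (at 256 width).
#' @param count_cv Lognormal coefficient of variation of the per-image
#'   stroke count around its class mean.
#' @param style_shift Named list of per-environment global brightness
#'   offsets and clutter counts, and a per-year brightness offset.
#' @param noise_sigma Per-pixel Gaussian texture noise, intensity units
#'   in `[0, 1]`.
#' @param seed Integer master seed for [generate_dataset()].
#' @return A `leafhair_synth_config` list.
#' @export
synth_config <- function(image_width = 256L, image_height = 192L,
                         images_per_leaf_range = c(9L, 15L),
                         plants_per_genotype = 10L,
                         leaf_numbers = c(3L, 4L),
                         hair_density_base = 10,
                         density_mult = c(0, 1, 2.2, 3.8, 5.8, 8.4, 11.5, 15, 19),
                         hair_length_base = 20,
                         count_cv = 0.04,
                         style_shift = list(
                           GH = list(brightness = 0.06, clutter = 0),
                           FD = list(brightness = -0.03, clutter = 40),
                           Y1 = 0, Y2 = 0.02),
                         noise_sigma = 0.02,
                         seed = 1L) {
  if (image_width < 32L || image_height < 32L)
    stop("degenerate image dimensions (< 32 px): ",
         image_width, " x ", image_height)
  r <- as.integer(images_per_leaf_range)
  if (length(r) != 2L || r[1] > r[2] || r[1] < 1L || r[2] > 50L)
    stop("images_per_leaf_range must be an interval within [1, 50]")
  if (length(density_mult) != 9L || any(diff(density_mult) <= 0))
    stop("density_mult must be 9 strictly increasing values (one per rank)")
  if (density_mult[1] != 0)
    stop("density_mult[1] must be 0: rank 0 is the glabrous class")
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 images_per_leaf_range = r,
                 plants_per_genotype = as.integer(plants_per_genotype),
                 leaf_numbers = as.integer(leaf_numbers),
                 hair_density_base = hair_density_base,
                 density_mult = density_mult,
                 hair_length_base = hair_length_base,
                 count_cv = count_cv,
                 style_shift = style_shift,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "leafhair_synth_config")
}

# smooth 1-D random profile, used for vein curvature and background texture
smooth_profile <- function(n, knots = 6, amplitude = 1) {
  k <- stats::runif(knots, -1, 1) * amplitude
  stats::spline(seq(0, 1, length.out = knots), k, n = n)$y
}

# accumulate bilinear splats of continuous points (x, y) into an H x W mask
splat <- function(mask, x, y, w) {
  H <- nrow(mask); W <- ncol(mask)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ix <- c(x0, x0 + 1, x0, x0 + 1)
  iy <- c(y0, y0, y0 + 1, y0 + 1)
  ww <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
          w * (1 - fx) * fy, w * fx * fy)
  ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H & ww > 0
  if (!any(ok)) return(mask)
  idx <- (ix[ok] - 1L) * H + iy[ok]
  acc <- rowsum(ww[ok], idx)
  ii <- as.integer(rownames(acc))
  mask[ii] <- mask[ii] + acc[, 1L]
  mask
}

# vein centre line: enters at x = 0 and exits at x = W-1, 0 < y < H-1
vein_curve <- function(W, H) {
  y <- H / 2 + smooth_profile(W, knots = 5, amplitude = 0.12 * H)
  pmin(pmax(y, 0.12 * H), 0.88 * H)
}

#' Render one synthetic leaf image
#'
#' Draws a green textured background (style-shifted by year and
#' environment), one mid-vein crossing the full image width, and bright
#' hair strokes anchored near the vein, with stroke count and length
#' increasing with the score's rank.  Consumes the R session RNG stream;
#' wrap in [withr::with_seed()] (as [generate_dataset()] does) for
#' reproducibility.
#'
#' @param score A score label or `leafhair_score`.
#' @param style List with elements `year` ("Y1"/"Y2") and `environment`
#'   ("GH"/"FD").
#' @param config A [synth_config()].
#' @return An `image_height x image_width x 3` array in `[0, 1]` with
#'   attributes `stroke_count` (integer) and `stroke_fraction` (fraction
#'   of pixels covered by hair strokes), the generator's ground-truth
#'   render log.
#' @export
render_leaf_image <- function(score, style = list(year = "Y1", environment = "GH"),
                              config = synth_config()) {
  rank <- score_rank(score)
  W <- config$image_width; H <- config$image_height
  env_style <- config$style_shift[[style$environment]]
  bright <- env_style$brightness + config$style_shift[[style$year]]

  # background: green base + low-frequency texture + grain
  base <- c(0.22, 0.46, 0.20) + bright
  tex <- outer(smooth_profile(H, 7, 0.05), rep(1, W)) +
    outer(rep(1, H), smooth_profile(W, 7, 0.05))
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] + tex
  img <- img + array(stats::rnorm(H * W * 3, 0, config$noise_sigma), dim = c(H, W, 3))

  # field images carry extra dark clutter (debris, soil specks)
  if (env_style$clutter > 0) {
    nc <- stats::rpois(1, env_style$clutter)
    if (nc > 0) {
      cm <- matrix(0, H, W)
      cm <- splat(cm, stats::runif(nc, 2, W - 2), stats::runif(nc, 2, H - 2),
                  rep(1.2, nc))
      cmix <- pmin(cm, 1)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.5 * cmix)
    }
  }

  # mid-vein band crossing left and right borders
  vy <- vein_curve(W, H)
  vein_w <- max(2, 0.015 * H)
  offs <- seq(-vein_w, vein_w, by = 0.5)
  vmask <- splat(matrix(0, H, W),
                 rep(seq_len(W) - 0.0001, times = length(offs)),
                 rep(vy, times = length(offs)) + rep(offs, each = W),
                 rep(0.6 * exp(-(offs / vein_w)^2), each = W))
  vmix <- pmin(vmask, 1)
  vein_col <- base * 1.25 + 0.05
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - vmix) + vein_col[ch] * vmix

  # hair strokes: bright curved segments anchored on/near the vein
  mu <- config$hair_density_base * config$density_mult[rank + 1L] * W / 256
  count <- if (mu == 0) 0L else
    max(0L, as.integer(round(mu * exp(stats::rnorm(1, 0, config$count_cv)))))
  smask <- matrix(0, H, W)
  if (count > 0) {
    len <- config$hair_length_base * (0.6 + 0.08 * rank) * W / 256
    x0 <- stats::runif(count, 1, W - 1)
    y0 <- vy[ceiling(x0)] + stats::rnorm(count, 0, 2.5 * vein_w)
    ang <- stats::runif(count, 0, 2 * pi)
    l <- len * stats::runif(count, 0.7, 1.3)
    curv <- stats::rnorm(count, 0, 0.25)
    nt <- max(4L, ceiling(3 * max(l)))
    t <- seq(0, 1, length.out = nt)
    Tm <- matrix(t, nt, count)
    A <- Tm * matrix(curv, nt, count, byrow = TRUE) +
      matrix(ang, nt, count, byrow = TRUE)
    R <- Tm * matrix(l, nt, count, byrow = TRUE)
    xs <- matrix(x0, nt, count, byrow = TRUE) + R * cos(A)
    ys <- matrix(y0, nt, count, byrow = TRUE) + R * sin(A)
    smask <- splat(smask, as.vector(xs), as.vector(ys),
                   rep(0.8, nt * count))
  }
  smix <- pmin(smask, 1)
  hair_col <- c(0.95, 0.97, 0.88)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - smix) + hair_col[ch] * smix

  img <- pmin(pmax(img, 0), 1)
  attr(img, "stroke_count") <- count
  attr(img, "stroke_fraction") <- mean(smix > 0.5)
  img
}

#' Genotype specs for the generator
#'
#' @param colorname De-identified genotype name.
#' @param score Score label for the genotype.
#' @param years Subset of `c("Y1", "Y2")` (at least one).
#' @param environments Subset of `c("GH", "FD")` (at least one).
#' @param site `"N"` or `"C"`.
#' @return A `leafhair_genotype_spec` list.
#' @export
genotype_spec <- function(colorname, score, years = "Y1",
                          environments = "GH", site = "N") {
  stopifnot(length(years) >= 1, all(years %in% c("Y1", "Y2")),
            length(environments) >= 1, all(environments %in% c("GH", "FD")),
            site %in% c("N", "C"))
  structure(list(colorname = colorname,
                 score = normalize_score_label(score),
                 years = years, environments = environments, site = site),
            class = "leafhair_genotype_spec")
}

#' Default genotype panel: one genotype per score class
#'
#' Nine single-condition genotypes spanning all 9 ranks — the
#' "well-separated classes" panel used by the desk-scale training tests.
#'
#' @param years,environments Conditions applied to every genotype.
#' @return List of [genotype_spec()]s.
#' @export
default_panel <- function(years = "Y1", environments = "GH") {
  names9 <- c("Pink", "Charcoal", "Purple", "White", "Yellow",
              "Green", "Blue", "Turquoise", "Brown")
  lapply(seq_along(names9), function(i)
    genotype_spec(names9[i], score_labels()[i], years, environments))
}

#' Generate a labelled synthetic dataset
#'
#' For every genotype x year x environment x leaf-number x plant
#' combination, generates one leaf group with a uniformly drawn number of
#' images in `images_per_leaf_range`, distributed over 3 veins in
#' proximal-to-distal order; the vein-1/position-1 image is the leaf's
#' single `is_first` image.  Deterministic for a fixed `config$seed`
#' (byte-identical manifests and images).
#'
#' @param specs List of [genotype_spec()]s (non-empty).
#' @param config A [synth_config()].
#' @param out_dir Output directory for PNG images, the manifest
#'   (`manifest.csv`) and the ground-truth render log
#'   (`render_log.csv`).
#' @param write_images If `FALSE`, skip rendering and PNG writing (fast
#'   metadata-only mode for split/bookkeeping tests); the render log is
#'   then absent.
#' @return The manifest, with the render log data.frame attached as
#'   attribute `"render_log"` when images were written.
#' @export
generate_dataset <- function(specs, config = synth_config(),
                             out_dir = tempfile("leafhair_synth_"),
                             write_images = TRUE) {
  if (length(specs) == 0) stop("`specs` must be non-empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  withr::with_seed(config$seed, {
    rows <- list(); log <- list()
    leaf_counter <- 0L
    for (sp in specs) for (yr in sp$years) for (env in sp$environments)
      for (ln in config$leaf_numbers) for (pl in seq_len(config$plants_per_genotype)) {
        leaf_counter <- leaf_counter + 1L
        leaf_id <- sprintf("%s_%s_%s_L%d_p%02d", sp$colorname, yr, env, ln, pl)
        k <- sample(seq(config$images_per_leaf_range[1],
                        config$images_per_leaf_range[2]), 1L)
        vein <- sort(rep(1:3, length.out = k))
        pos <- stats::ave(seq_len(k), vein, FUN = seq_along)
        ids <- sprintf("%s_v%d_i%d", leaf_id, vein, pos)
        paths <- file.path(out_dir, paste0(ids, ".png"))
        for (j in seq_len(k)) {
          if (write_images) {
            im <- render_leaf_image(sp$score, list(year = yr, environment = env),
                                    config)
            png::writePNG(array(im, dim = dim(im)), paths[j])
            log[[length(log) + 1L]] <- data.frame(
              image_id = ids[j],
              true_rank = score_rank(sp$score),
              stroke_count = attr(im, "stroke_count"),
              stroke_fraction = attr(im, "stroke_fraction"))
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = ids, leaf_id = leaf_id, genotype = sp$colorname,
          score = sp$score, leaf_number = ln, year = yr, environment = env,
          site = sp$site, vein_index = vein, position_index = pos,
          is_first = vein == 1L & pos == 1L, image_path = paths)
      }
    manifest <- as_manifest(do.call(rbind, rows))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    if (write_images) {
      render_log <- do.call(rbind, log)
      utils::write.csv(render_log, file.path(out_dir, "render_log.csv"),
                       row.names = FALSE)
      attr(manifest, "render_log") <- render_log
    }
    manifest
  })
}

#' Per-class mean stroke-pixel fraction of a synthetic dataset
#'
#' Sanity harness over the generator's ground-truth render log: returns
#' the mean fraction of hair-stroke pixels per score class present, which
#' must be strictly increasing in rank for a valid configuration (the
#' monotone visual signal the classifier learns).
#'
#' @param manifest A manifest returned by [generate_dataset()] (with its
#'   `"render_log"` attribute), or one whose images live next to a
#'   `render_log.csv`.
#' @return Named numeric vector (one entry per class present, ascending
#'   rank order) of mean stroke-pixel fractions.
#' @export
class_separability_check <- function(manifest) {
  log <- attr(manifest, "render_log")
  if (is.null(log)) {
    dirs <- unique(dirname(manifest$image_path))
    cand <- file.path(dirs, "render_log.csv")
    cand <- cand[file.exists(cand)]
    if (!length(cand))
      stop("no ground-truth render log: manifest is not a synthetic ",
           "dataset generated by generate_dataset() with write_images = TRUE")
    log <- do.call(rbind, lapply(cand, utils::read.csv))
  }
  log <- log[log$image_id %in% manifest$image_id, ]
  ranks <- sort(unique(log$true_rank))
  out <- vapply(ranks, function(r) mean(log$stroke_fraction[log$true_rank == r]),
                numeric(1))
  names(out) <- score_labels()[ranks + 1L]
  out
}
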