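test_that("config validation catches degenerate settings", {
  expect_error(synth_config(image_width = 16), "degenerate image dimensions")
  expect_error(synth_config(images_per_leaf_range = c(9, 60)), "within \\[1, 50\\]")
  expect_error(synth_config(images_per_leaf_range = c(15, 9)), "interval")
  expect_error(synth_config(density_mult = rep(1, 9)), "strictly increasing")
  expect_error(synth_config(density_mult = c(0.1, 1:8)), "glabrous")
})

test_that("rendering: glabrous has zero strokes, density is monotone in rank", {
  cfg <- synth_config(image_width = 128L, image_height = 96L)
  im0 <- withr::with_seed(1, render_leaf_image("1", config = cfg))
  expect_identical(attr(im0, "stroke_count"), 0L)
  expect_equal(attr(im0, "stroke_fraction"), 0)
  expect_identical(dim(im0), c(96L, 128L, 3L))
  expect_true(all(im0 >= 0 & im0 <= 1))
  # same seed stream: higher rank draws strictly more strokes
  im3 <- withr::with_seed(2, render_leaf_image("3", config = cfg))
  im9 <- withr::with_seed(2, render_leaf_image("5+", config = cfg))
  expect_gt(attr(im9, "stroke_count"), attr(im3, "stroke_count"))
  expect_gt(attr(im9, "stroke_fraction"), attr(im3, "stroke_fraction"))
})

test_that("the mid-vein crosses the left/right borders, never top/bottom", {
  withr::with_seed(3, {
    for (i in 1:20) {
      vy <- leafhair:::vein_curve(128, 96)
      expect_length(vy, 128L)           # defined at x = 0 .. W-1 inclusive
      expect_true(all(vy > 0 & vy < 95))  # 0 < y < H-1 everywhere
    }
  })
})

test_that("generate_dataset produces the promised leaf/image structure", {
  cfg <- synth_config(image_width = 64L, image_height = 48L,
                      plants_per_genotype = 3L, seed = 7L)
  specs <- default_panel()[c(1, 5)]  # 2 genotypes x 1 year x 1 env
  out <- withr::local_tempdir()
  m <- generate_dataset(specs, cfg, out)
  # 2 genotypes x 2 leaf numbers x 3 plants = 12 leaf groups
  groups <- leaf_groups(m)
  expect_length(groups, 12L)
  sizes <- lengths(groups)
  expect_true(all(sizes >= 9 & sizes <= 15))
  expect_equal(sum(m$is_first), 12)
  first <- m[m$is_first, ]
  expect_true(all(first$vein_index == 1L & first$position_index == 1L))
  expect_true(all(file.exists(m$image_path)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_error(generate_dataset(list(), cfg), "non-empty")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- synth_config(image_width = 48L, image_height = 48L,
                      plants_per_genotype = 1L, seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(default_panel()[c(2, 8)], cfg, d1)
  m2 <- generate_dataset(default_panel()[c(2, 8)], cfg, d2)
  expect_identical(as.data.frame(m1)[setdiff(names(m1), "image_path")],
                   as.data.frame(m2)[setdiff(names(m2), "image_path")])
  for (i in seq_len(nrow(m1)))
    expect_identical(readBin(m1$image_path[i], "raw", 1e6),
                     readBin(m2$image_path[i], "raw", 1e6))
})

test_that("leaf count follows the closed-form grid arithmetic", {
  # leaves = 2 leaf numbers x sum over genotypes of (plants x conditions)
  cfg <- synth_config(image_width = 48L, image_height = 48L,
                      plants_per_genotype = 2L, seed = 3L)
  specs <- list(genotype_spec("Pink", "1", years = c("Y1", "Y2"),
                              environments = c("GH", "FD")),
                genotype_spec("Brown", "5+", years = "Y2",
                              environments = "GH"))
  m <- generate_dataset(specs, cfg, withr::local_tempdir(),
                        write_images = FALSE)
  expected <- 2 * (2 * 4 + 2 * 1)  # leaf numbers x plants x conditions
  expect_length(unique(m$leaf_id), expected)
})

test_that("class separability is monotone and scales with density", {
  cfg <- synth_config(image_width = 96L, image_height = 72L,
                      plants_per_genotype = 1L,
                      images_per_leaf_range = c(3L, 3L), seed = 5L)
  m <- generate_dataset(default_panel(), cfg, withr::local_tempdir())
  frac <- class_separability_check(m)
  expect_length(frac, 9L)
  expect_true(all(diff(frac) > 0))
  expect_equal(unname(frac[1]), 0)
  # doubled density approximately doubles low-occupancy coverage
  lo <- synth_config(image_width = 96L, image_height = 72L,
                     plants_per_genotype = 2L, hair_density_base = 2,
                     images_per_leaf_range = c(4L, 4L), seed = 6L)
  hi <- lo; hi$hair_density_base <- 4
  mlo <- generate_dataset(default_panel()[3], lo, withr::local_tempdir())
  mhi <- generate_dataset(default_panel()[3], hi, withr::local_tempdir())
  flo <- class_separability_check(mlo)[["3"]]
  fhi <- class_separability_check(mhi)[["3"]]
  expect_equal(fhi / flo, 2, tolerance = 0.25)
  # a manifest without render logs is rejected
  expect_error(class_separability_check(toy_manifest()), "render log")
})
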